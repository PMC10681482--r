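#' @importFrom methods is new show validObject
NULL

setMethod("show", "QtlMap", function(object) {
  l <- object@loci
  cat("QtlMap:", nrow(l), "diallelic loci on", length(unique(l$linkageGroup)),
      "linkage group(s)\n")
  cat("  effects: ", sprintf("%.4g", min(l$effect)), "..",
      sprintf("%.4g", max(l$effect)),
      "  init freq: ", sprintf("%.3f", min(l$initFreq)), "..",
      sprintf("%.3f", max(l$initFreq)), "\n", sep = "")
})

setMethod("show", "GeneticSetup", function(object) {
  cat("GeneticSetup:", nLoci(object), "QTL,", nrow(object@hap1), "founders\n")
  cat(sprintf("  VA target %.5g, realized %.5g (mean %.4g); h2 = %.2f\n",
              object@vaTarget, object@realizedVa, object@realizedMean,
              object@h2))
  cat("  converged:", object@converged, "in", object@iterations, "restart(s)\n")
})

setMethod("show", "ForestStand", function(object) {
  tr <- object@trees
  alive <- tr$status == "alive"
  cat(sprintf("ForestStand: %.2f ha (%d x %d pixels of %g m), site index %g m\n",
              object@areaHa, object@nx, object@ny, object@pixelSize,
              object@siteIndex))
  cat(sprintf("  stand age %g, cycle %d, phase %s\n", object@standAge,
              object@cycle, object@phase))
  cat(sprintf("  trees: %d registered, %d alive (%d recruited)\n",
              nrow(tr), sum(alive), sum(alive & tr$recruited)))
})

setMethod("show", "Scenario", function(object) {
  cat("Scenario", object@name, "\n")
  print(object@interventions, row.names = FALSE)
})

setMethod("show", "DisturbanceRegime", function(object) {
  cat("DisturbanceRegime:", object@kind, "\n")
  if (object@kind != "none")
    cat(sprintf("  Weibull(%g, %g)%s; crown-modifier exponent %g\n",
                object@shapeLow, object@scaleLow,
                if (object@probHigh > 0)
                  sprintf(" + Weibull(%g, %g) with prob %.3f",
                          object@shapeHigh, object@scaleHigh, object@probHigh)
                else "", object@theta))
})

setMethod("show", "SimRun", function(object) {
  cat("SimRun:", object@config@scenario@name, "/",
      object@config@regime@kind, "disturbance /",
      if (object@config@variation)
        paste0(object@config@nQtl, " QTL") else "no variation", "\n")
  cat(sprintf("  %d annual records over %d cycle(s)%s\n",
              nrow(object@records), nrow(object@cycles),
              if (object@collapse) " [COLLAPSED]" else ""))
  if (!is.na(object@h0))
    cat(sprintf("  evolutionary rate H0 = %.3f haldanes\n", object@h0))
})
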