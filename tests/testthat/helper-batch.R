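# Shared simulation batch for the acceptance checks: one 1.1-ha stand
# (105 m x 105 m, 2800 stems/ha at age 25, site index 20), 50-QTL default
# genetic setup, all seven scenarios under the none and medium disturbance
# regimes (10 replicates each). Computed once per test session;
# only the slim outputs (annual records, cycle summaries, H0) are retained
# so the batch fits comfortably in memory.

.batchCache <- new.env(parent = emptyenv())

batchConfig <- function(scenarioName, regime, dynamicsSeed,
                        variation = TRUE, nQtl = 50, setupSeed = 11,
                        nCycles = 4) {
  simConfig(width = 105, height = 105, initialDensity = 2800,
            initialAge = 25, siteIndex = 20,
            scenario = scenarioName, regime = regime,
            variation = variation, nQtl = nQtl, nCycles = nCycles,
            setupSeed = setupSeed, inventorySeed = 2,
            dynamicsSeed = dynamicsSeed)
}

slimRun <- function(cfg) {
  run <- suppressWarnings(runSimulation(cfg))
  out <- list(records = annualRecords(run), cycles = cycleSummaries(run),
              h0 = run@h0, collapse = run@collapse)
  rm(run)
  out
}

scenarioBatch <- function() {
  if (!is.null(.batchCache$runs)) return(.batchCache$runs)
  scens <- c("U-long", "U-short", "B-long", "B-short", "E-low",
             "E-delayed", "E-relaxed")
  runs <- list()
  for (sc in scens) {
    runs[[sc]] <- list(
      none = lapply(100 + 1:10, function(s)
        slimRun(batchConfig(sc, "none", s))),
      medium = lapply(200 + 1:10, function(s)
        slimRun(batchConfig(sc, "medium", s))))
    gc(FALSE)
  }
  .batchCache$runs <- runs
  runs
}

meanH0 <- function(runs) mean(vapply(runs, `[[`, numeric(1), "h0"))
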