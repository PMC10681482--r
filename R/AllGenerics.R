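#' Number of trees in a stand or registry
#'
#' @param x a [ForestStand-class].
#' @param ... passed to methods; `aliveOnly = TRUE` restricts to alive trees.
#' @return integer count.
#' @export
setGeneric("nTrees", function(x, ...) standardGeneric("nTrees"))

#' Tree registry accessor
#'
#' @param x a [ForestStand-class].
#' @param ... `aliveOnly`, `recruitedOnly` logical filters.
#' @return the tree registry as a data.frame.
#' @export
setGeneric("treeRegistry", function(x, ...) standardGeneric("treeRegistry"))

#' Stand area in hectares
#' @param x a [ForestStand-class].
#' @export
setGeneric("standArea", function(x) standardGeneric("standArea"))

#' Number of QTL in a map or setup
#' @param x a [QtlMap-class] or [GeneticSetup-class].
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' Per-locus absolute allelic effects
#' @param x a [QtlMap-class] or [GeneticSetup-class].
#' @export
setGeneric("lociEffects", function(x) standardGeneric("lociEffects"))

#' Per-locus initial frequencies of the increasing allele
#' @param x a [QtlMap-class] or [GeneticSetup-class].
#' @export
setGeneric("lociFrequencies", function(x) standardGeneric("lociFrequencies"))

#' Annual records of a run
#' @param x a [SimRun-class].
#' @return data.frame with one row per executed process year.
#' @export
setGeneric("annualRecords", function(x) standardGeneric("annualRecords"))

#' Per-cycle summaries of a run
#' @param x a [SimRun-class].
#' @export
setGeneric("cycleSummaries", function(x) standardGeneric("cycleSummaries"))

#' Run summary (H0, collapse flag, seeds, scenario identifiers)
#' @param x a [SimRun-class].
#' @return a named list.
#' @export
setGeneric("runSummary", function(x) standardGeneric("runSummary"))

setMethod("nTrees", "ForestStand", function(x, aliveOnly = FALSE, ...) {
  if (aliveOnly) sum(x@trees$status == "alive") else nrow(x@trees)
})

setMethod("treeRegistry", "ForestStand",
  function(x, aliveOnly = FALSE, recruitedOnly = FALSE, ...) {
    tr <- x@trees
    keep <- rep(TRUE, nrow(tr))
    if (aliveOnly) keep <- keep & tr$status == "alive"
    if (recruitedOnly) keep <- keep & tr$recruited
    tr[keep, , drop = FALSE]
  })

setMethod("standArea", "ForestStand", function(x) x@areaHa)

setMethod("nLoci", "QtlMap", function(x) nrow(x@loci))
setMethod("nLoci", "GeneticSetup", function(x) nrow(x@map@loci))
setMethod("lociEffects", "QtlMap", function(x) x@loci$effect)
setMethod("lociEffects", "GeneticSetup", function(x) x@map@loci$effect)
setMethod("lociFrequencies", "QtlMap", function(x) x@loci$initFreq)
setMethod("lociFrequencies", "GeneticSetup", function(x) x@map@loci$initFreq)

setMethod("annualRecords", "SimRun", function(x) x@records)
setMethod("cycleSummaries", "SimRun", function(x) x@cycles)

setMethod("runSummary", "SimRun", function(x) {
  list(
    scenario = x@config@scenario@name,
    disturbance = x@config@regime@kind,
    nQtl = if (x@config@variation) x@config@nQtl else 0,
    variation = x@config@variation,
    setupSeed = x@config@setupSeed,
    inventorySeed = x@config@inventorySeed,
    dynamicsSeed = x@config@dynamicsSeed,
    collapse = x@collapse,
    h0 = x@h0,
    selectionDifferentials = x@cycles$selDiff
  )
})
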