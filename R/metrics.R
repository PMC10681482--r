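## evolutionary-rate and dendrometric summary statistics

#' Evolutionary rate in haldanes
#'
#' |mean_end - mean_start| / sqrt((var_start + var_end) / 2) / nGen: the
#' average change of the trait per generation in units of the pooled
#' within-population phenotypic standard deviation sampled at the two ends of
#' the interval.
#'
#' @param meanStart,meanEnd trait means at the two ends.
#' @param varStart,varEnd within-population trait variances at the two ends.
#' @param nGen number of generations in the interval.
#' @return the rate in haldanes.
#' @examples
#' evolutionaryRateH0(0, 0.2, 0.01, 0.01, 4)  # 0.5
#' @export
evolutionaryRateH0 <- function(meanStart, meanEnd, varStart, varEnd, nGen) {
  stopifnot(nGen >= 1)
  pooled <- (varStart + varEnd) / 2
  if (!is.finite(pooled) || pooled <= 0)
    stop("H0 is undefined: pooled variance must be positive")
  abs(meanEnd - meanStart) / sqrt(pooled) / nGen
}

#' Quadratic mean diameter
#'
#' The diameter of the tree of mean squared diameter: sqrt(mean(dbh^2)).
#'
#' @param dbh diameters (cm) of the alive trees.
#' @return QMD in cm.
#' @export
quadraticMeanDiameter <- function(dbh) {
  if (!length(dbh)) stop("QMD is undefined for an empty population")
  sqrt(mean(dbh^2))
}

#' Cumulative timber production
#'
#' Within a cycle, production = standing volume + the volumes of all trees
#' that died or were removed since the cycle start, per hectare. The quantity
#' is non-decreasing within a cycle: a death or removal moves volume between
#' the two terms without changing the sum at that instant.
#'
#' @param standingVolume current standing volume (m^3).
#' @param removedVolume summed volume (m^3) of trees dead/removed since cycle
#'   start, measured at their death/removal time.
#' @param areaHa stand area (ha).
#' @return cumulative production in m^3/ha.
#' @export
cumulativeProduction <- function(standingVolume, removedVolume, areaHa) {
  (standingVolume + removedVolume) / areaHa
}

#' Per-cycle selection differential on vigor
#'
#' Mean genotypic vigor of the seed trees minus the mean genotypic vigor of
#' the population at the start of the cycle.
#'
#' @param seedTreeGv genotypic values of the seed trees.
#' @param cycleStartGv genotypic values of the cycle-start population.
#' @return selection differential (cm y^-1).
#' @export
selectionDifferential <- function(seedTreeGv, cycleStartGv) {
  mean(seedTreeGv) - mean(cycleStartGv)
}

## stem volumes (m^3) of given registry rows from stored dimensions
.treeVolumes <- function(trees, rows, growth) {
  growth@formFactor * pi * (trees$dbh[rows] / 200)^2 * trees$height[rows]
}
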