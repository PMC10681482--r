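## the two mortality processes: selective self-thinning against the carrying
## capacity of each pixel, and non-selective stochastic disturbance with
## density-dependent local modulation

#' Self-thinning parameter constructor
#'
#' Defaults: classic Reineke slope 1.6; the intercept is calibrated jointly
#' with the basal-area-increment coefficient so that self-thinning starts at
#' stand age ~43 in an unthinned stand initialized at 2800 stems/ha, age 25.
#'
#' @param reinekeK,reinekeB maximum-density line Nmax = reinekeK * Cg^(-reinekeB)
#'   (stems/ha, Cg in cm).
#' @param rdiMax maximum relative density index.
#' @return a [SelfThinningParams-class].
#' @export
selfThinningParams <- function(reinekeK = 1.75e6, reinekeB = 1.6, rdiMax = 1) {
  new("SelfThinningParams", reinekeK = reinekeK, reinekeB = reinekeB,
      rdiMax = rdiMax)
}

## removal prefix within one pixel: smallest trees (ties by id) removed one by
## one while RDI > rdiMax; returns positions (into the supplied vectors) of
## the removed trees. Vectorized as a cumulative scan over the dbh-ascending
## order, which is exactly equivalent to the one-by-one loop.
.selfThinPixel <- function(dbh, id, pxAreaHa, st) {
  n <- length(dbh)
  o <- order(dbh, id)
  c2 <- (pi * dbh[o])^2
  tot <- sum(c2)
  j <- 0:(n - 1L)                      # number removed so far
  nLeft <- n - j
  sumLeft <- tot - c(0, cumsum(c2))[1:n]
  cg <- sqrt(sumLeft / nLeft)
  rdi <- (nLeft / pxAreaHa) * cg^st@reinekeB / st@reinekeK
  stopPos <- which(rdi <= st@rdiMax)
  k <- if (length(stopPos)) stopPos[1L] - 1L else n
  if (k == 0L) integer(0) else o[seq_len(k)]
}

#' Density-dependent self-thinning of a stand
#'
#' In every pixel whose relative density index N/Nmax(Cg) exceeds the maximum,
#' the alive tree with the smallest dbh (ties broken by id) is removed and the
#' quadratic mean circumference and RDI are recomputed, until RDI falls at or
#' below the maximum. Removed trees are flagged `dead_selfthinning`.
#'
#' @param stand a [ForestStand-class].
#' @param params a [SelfThinningParams-class].
#' @return list with the updated `stand` and `removedIds`.
#' @export
selfThinning <- function(stand, params = selfThinningParams()) {
  tr <- stand@trees
  use <- which(tr$status == "alive" & tr$recruited)
  if (!length(use)) return(list(stand = stand, removedIds = integer(0)))
  pxAreaHa <- stand@pixelSize^2 / 1e4
  ## quick screen: only pixels over capacity need the removal scan
  px <- tr$pixel[use]
  c2 <- (pi * tr$dbh[use])^2
  agg <- rowsum(cbind(1, c2), px, reorder = FALSE)
  n <- agg[, 1L]
  cg <- sqrt(agg[, 2L] / n)
  rdi <- (n / pxAreaHa) * cg^params@reinekeB / params@reinekeK
  hot <- as.integer(rownames(agg))[rdi > params@rdiMax]
  removed <- integer(0)
  if (length(hot)) {
    byPx <- split(use[px %in% hot], px[px %in% hot])
    for (i in byPx) {
      sel <- .selfThinPixel(tr$dbh[i], tr$id[i], pxAreaHa, params)
      removed <- c(removed, tr$id[i][sel])
    }
  }
  stand <- .markStatus(stand, removed, "dead_selfthinning")
  list(stand = stand, removedIds = removed)
}

#' Disturbance regime constructor
#'
#' Defaults follow the regime definitions: `medium` has a long-run mean
#' potential mortality of ~2% per year (Weibull shape 1.5, scale 0.0222);
#' `severe` mixes a frequent low-mortality component (shape 1.5, scale 0.0443,
#' mean ~4%) with a 5-fold rarer high-mortality component (shape 3, scale
#' 0.582, mean ~52%), for a long-run mean of ~12%.
#'
#' @param kind "none", "medium" or "severe".
#' @param shapeLow,scaleLow,shapeHigh,scaleHigh,probHigh optional explicit
#'   Weibull parameterization.
#' @param theta exponent of the local crown modifier.
#' @return a [DisturbanceRegime-class].
#' @export
disturbanceRegime <- function(kind = c("none", "medium", "severe"),
                              shapeLow = NULL, scaleLow = NULL,
                              shapeHigh = 3, scaleHigh = 0.582,
                              probHigh = NULL, theta = 1) {
  kind <- match.arg(kind)
  if (is.null(shapeLow))
    shapeLow <- switch(kind, none = 1, medium = 1.5, severe = 1.5)
  if (is.null(scaleLow))
    scaleLow <- switch(kind, none = 0, medium = 0.0222, severe = 0.0443)
  if (is.null(probHigh))
    probHigh <- switch(kind, none = 0, medium = 0, severe = 1 / 6)
  new("DisturbanceRegime", kind = kind, shapeLow = shapeLow,
      scaleLow = scaleLow, shapeHigh = shapeHigh, scaleHigh = scaleHigh,
      probHigh = probHigh, theta = theta)
}

#' Draw the annual potential stand mortality rate
#'
#' One draw for the whole stand: 0 under the `none` regime; a single Weibull
#' draw under `medium`; under `severe`, the low-mortality component with
#' probability 5/6 and the high-mortality component otherwise. Draws are
#' clipped to \[0, 1\].
#'
#' @param regime a [DisturbanceRegime-class].
#' @param n number of draws.
#' @return potential mortality rate(s) in \[0, 1\].
#' @export
drawPotentialMortalityRate <- function(regime, n = 1) {
  if (regime@kind == "none") return(rep(0, n))
  high <- runif(n) < regime@probHigh
  r <- numeric(n)
  if (any(!high))
    r[!high] <- rweibull(sum(!high), regime@shapeLow, regime@scaleLow)
  if (any(high))
    r[high] <- rweibull(sum(high), regime@shapeHigh, regime@scaleHigh)
  pmin(pmax(r, 0), 1)
}

#' Apply a disturbance event to a stand
#'
#' The potential rate is reduced per pixel according to the summed crown
#' height: effective rate = rate * (S_p / S_ref)^theta (capped at the
#' potential rate), with S_p the sum of crown heights of the pixel's alive
#' recruited trees and S_ref the maximum over pixels this year. Each tree then
#' dies independently with its pixel's effective rate — mortality is neutral
#' with respect to size and genotype within a pixel. Deaths are flagged
#' `dead_disturbance`.
#'
#' @param stand a [ForestStand-class].
#' @param potentialRate the stand-level potential mortality rate in \[0, 1\].
#' @param regime a [DisturbanceRegime-class] (for theta).
#' @return list with the updated `stand` and `removedIds`.
#' @export
applyDisturbance <- function(stand, potentialRate,
                             regime = disturbanceRegime("medium")) {
  stopifnot(potentialRate >= 0, potentialRate <= 1)
  tr <- stand@trees
  use <- which(tr$status == "alive" & tr$recruited)
  if (!length(use) || potentialRate == 0)
    return(list(stand = stand, removedIds = integer(0)))
  np <- stand@nx * stand@ny
  sp <- numeric(np)
  agg <- rowsum(tr$crownHeight[use], tr$pixel[use], reorder = FALSE)
  sp[as.integer(rownames(agg))] <- agg[, 1L]
  sref <- max(sp)
  eff <- if (sref > 0) pmin(potentialRate * (sp / sref)^regime@theta,
                            potentialRate) else rep(0, np)
  die <- runif(length(use)) < eff[tr$pixel[use]]
  removed <- tr$id[use][die]
  stand <- .markStatus(stand, removed, "dead_disturbance")
  list(stand = stand, removedIds = removed)
}
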