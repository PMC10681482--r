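## deterministic small-world fixtures for tests and documentation examples:
## miniature stands with hand-checkable diameters and exact-arithmetic
## genetic setups; fixtures never read external files

#' Miniature deterministic stand
#'
#' Builds a small stand with a fixed diameter pattern per pixel, for oracle
#' tests: diameters are laid out deterministically ("staircase" repeats the
#' supplied pattern; "equal" repeats its first value) and trees are placed on
#' a regular sub-grid inside each pixel, so the fixture replays bit-identically
#' with no random draws.
#'
#' @param nPixelsX,nPixelsY pixel grid dimensions.
#' @param treesPerPixel trees placed in each pixel.
#' @param dbhPattern diameters (cm) recycled over the trees of each pixel.
#' @param age tree age in years (recruited founders).
#' @param pixelSize pixel edge (m).
#' @param siteIndex site index (m at 50 years).
#' @return a [ForestStand-class].
#' @examples
#' st <- miniStand(1, 1, 5, dbhPattern = c(10, 20, 30, 40, 50))
#' pixelDendrometrics(st)
#' @export
miniStand <- function(nPixelsX = 2, nPixelsY = 2, treesPerPixel = 5,
                      dbhPattern = c(10, 20, 30, 40, 50), age = 40,
                      pixelSize = 15, siteIndex = 20) {
  stopifnot(nPixelsX >= 1, nPixelsY >= 1, treesPerPixel >= 1)
  stand <- makeStand(nPixelsX * pixelSize, nPixelsY * pixelSize, pixelSize,
                     siteIndex)
  np <- nPixelsX * nPixelsY
  n <- np * treesPerPixel
  ## regular sub-grid inside each pixel (k x k, k = ceiling(sqrt(trees)))
  k <- ceiling(sqrt(treesPerPixel))
  sub <- expand.grid(i = seq_len(k), j = seq_len(k))[seq_len(treesPerPixel), ]
  px <- rep(seq_len(np), each = treesPerPixel)
  colIx <- (px - 1L) %% nPixelsX
  rowIx <- (px - 1L) %/% nPixelsX
  tr <- .emptyTrees(n)
  tr$id <- seq_len(n)
  tr$x <- (colIx + (sub$i - 0.5) / k) * pixelSize
  tr$y <- (rowIx + (sub$j - 0.5) / k) * pixelSize
  tr$pixel <- .pixelOf(tr$x, tr$y, pixelSize, stand@nx)
  stopifnot(all(tr$pixel == px))
  tr$cohort <- 1L
  tr$age <- age
  tr$dbh <- rep_len(dbhPattern, treesPerPixel)[
    rep(seq_len(treesPerPixel), times = np)]
  tr$recruited <- TRUE
  stand@trees <- tr
  stand@hap1 <- matrix(0L, n, 0)
  stand@hap2 <- matrix(0L, n, 0)
  stand@standAge <- age
  gp <- growthParams()
  .updateDimensions(stand, gp)
}

#' Hand-specified genetic setup (bypassing the optimizer)
#'
#' Builds a [GeneticSetup-class] from explicit effects and frequencies, for
#' exact-arithmetic genetic tests. Founder haplotypes may be supplied
#' explicitly; by default the founder set is empty and `vaTarget` is set to
#' the Hardy-Weinberg additive variance of the map.
#'
#' @param effects absolute allelic effects.
#' @param freqs initial frequencies of the increasing allele.
#' @param hap1,hap2 optional explicit founder haplotype matrices.
#' @param h2 heritability used for the environmental variance split.
#' @return a [GeneticSetup-class].
#' @examples
#' gs <- twoLocusSetup(c(0.05, 0.03), c(0.5, 0.5))
#' hweAdditiveVariance(gs@map)
#' @export
twoLocusSetup <- function(effects = c(0.05, 0.03), freqs = c(0.5, 0.5),
                          hap1 = NULL, hap2 = NULL, h2 = 0.3) {
  map <- qtlMap(effects, freqs)
  L <- nLoci(map)
  if (is.null(hap1)) hap1 <- matrix(0L, 0, L)
  if (is.null(hap2)) hap2 <- matrix(0L, 0, L)
  va <- hweAdditiveVariance(map)
  gv <- if (nrow(hap1)) genotypicValue(hap1, hap2, map) else numeric(0)
  new("GeneticSetup", map = map, vaTarget = va, meanTarget = 0, h2 = h2,
      veFixed = va * (1 - h2) / h2, veStep = 0,
      realizedVa = if (length(gv) >= 2) var(gv) else NA_real_,
      realizedMean = if (length(gv)) mean(gv) else NA_real_,
      hap1 = hap1, hap2 = hap2, converged = TRUE, iterations = 0)
}
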