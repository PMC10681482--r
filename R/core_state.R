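## core spatial/demographic state: stand, pixel grid, tree registry,
## synthetic initial-inventory generator

.pixelOf <- function(x, y, pixelSize, nx) {
  1L + as.integer(floor(x / pixelSize)) + nx * as.integer(floor(y / pixelSize))
}

.emptyTrees <- function(n = 0L) {
  data.frame(
    id = integer(n), x = numeric(n), y = numeric(n), pixel = integer(n),
    cohort = integer(n), age = numeric(n), dbh = numeric(n),
    height = numeric(n), crownHeight = numeric(n),
    gv = numeric(n), envFixed = numeric(n), coneEffect = numeric(n),
    motherId = rep(NA_integer_, n), fatherId = rep(NA_integer_, n),
    status = rep("alive", n), recruited = rep(FALSE, n))
}

#' Create an empty forest stand
#'
#' One rectangular, environmentally homogeneous parcel tiled by square pixels.
#' The extent must be an exact multiple of the pixel size on both axes so the
#' grid tiles the stand.
#'
#' @param width,height stand extent in meters (default 210 x 210 m = 4.41 ha).
#' @param pixelSize pixel edge in meters (default 15).
#' @param siteIndex dominant height in meters at the reference age of 50 years.
#' @return a [ForestStand-class] with an empty tree registry.
#' @examples
#' st <- makeStand(105, 105, siteIndex = 20)
#' standArea(st)
#' @export
makeStand <- function(width = 210, height = 210, pixelSize = 15,
                      siteIndex = 20) {
  if (width <= 0 || height <= 0) stop("stand extent must be positive")
  nx <- width / pixelSize
  ny <- height / pixelSize
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9)
    stop("stand extent must be an exact multiple of the pixel size")
  new("ForestStand",
      width = width, height = height, pixelSize = pixelSize,
      nx = as.integer(round(nx)), ny = as.integer(round(ny)),
      areaHa = width * height / 1e4, siteIndex = siteIndex,
      trees = .emptyTrees(), hap1 = matrix(0L, 0, 0), hap2 = matrix(0L, 0, 0),
      map = NULL, standAge = 0, cycle = 1L, phase = "growth-phase")
}

## truncated-normal draws by inverse CDF: count of RNG consumptions is
## deterministic (one uniform per tree), which keeps replay bit-identical
.rtnorm <- function(n, mean, sd, lower) {
  pLow <- pnorm((lower - mean) / sd)
  u <- pLow + runif(n) * (1 - pLow)
  mean + sd * qnorm(u)
}

## closed-form mean of the truncated normal (lower truncation only)
.tnormMean <- function(mean, sd, lower) {
  a <- (lower - mean) / sd
  mean + sd * dnorm(a) / (1 - pnorm(a))
}

#' Generate a synthetic initial tree inventory
#'
#' Places `round(density * area)` trees uniformly at random in the stand and
#' draws their diameters from the initial-diameter distribution, a normal
#' truncated at `minDbh` (the expected distribution of diameters at
#' recruitment age given stand density is a calibration input; the default is
#' 7 cm +/- 25% at age 25 under 2800 stems/ha). Trees are founders: they have
#' no parents and no genotypes yet.
#'
#' @param stand a [ForestStand-class] with an empty registry.
#' @param density initial density, stems per hectare.
#' @param age initial cohort age in years (must be at least the recruitment
#'   age; 25 by default).
#' @param meanDbh,cvDbh,minDbh parameters of the initial-diameter distribution
#'   (cm).
#' @return the stand with the founder cohort registered and `standAge` set.
#' @examples
#' st <- generateInventory(makeStand(), density = 2800, age = 25)
#' nTrees(st)  # 12348 trees on 4.41 ha
#' @export
generateInventory <- function(stand, density, age = 25,
                              meanDbh = 7, cvDbh = 0.25, minDbh = 0.5) {
  if (density <= 0) stop("density must be positive")
  if (stand@areaHa <= 0) stop("stand area must be positive")
  n <- as.integer(round(density * stand@areaHa))
  x <- runif(n, 0, stand@width)
  y <- runif(n, 0, stand@height)
  dbh <- .rtnorm(n, meanDbh, cvDbh * meanDbh, minDbh)
  tr <- .emptyTrees(n)
  tr$id <- seq_len(n)
  tr$x <- x; tr$y <- y
  tr$pixel <- .pixelOf(x, y, stand@pixelSize, stand@nx)
  tr$cohort <- 1L
  tr$age <- age
  tr$dbh <- dbh
  tr$recruited <- TRUE
  stand@trees <- tr
  stand@hap1 <- matrix(0L, n, 0)
  stand@hap2 <- matrix(0L, n, 0)
  stand@standAge <- age
  stand
}

#' Per-pixel dendrometric summaries
#'
#' Computes, from the alive recruited trees of each pixel: stem count N, basal
#' area G (m^2, per pixel), quadratic mean circumference Cg (cm, the root mean
#' square of circumferences), dominant height Hdom (m, mean height of the
#' `round(100 * pixel area in ha)` tallest trees, at least one), and, when
#' self-thinning parameters are supplied, the relative density index RDI.
#' Empty pixels report N = 0, G = 0, Cg = 0, Hdom = 0, RDI = 0.
#'
#' @param stand a [ForestStand-class].
#' @param selfThinning optional [SelfThinningParams-class] to compute RDI.
#' @return data.frame with one row per pixel: `pixel`, `N`, `G`, `Cg`, `Hdom`,
#'   `RDI` (NA when no parameters given).
#' @export
pixelDendrometrics <- function(stand, selfThinning = NULL) {
  np <- stand@nx * stand@ny
  tr <- stand@trees
  use <- tr$status == "alive" & tr$recruited
  px <- tr$pixel[use]
  dbh <- tr$dbh[use]
  h <- tr$height[use]
  pxAreaHa <- stand@pixelSize^2 / 1e4
  ndom <- max(1L, as.integer(round(100 * pxAreaHa)))

  N <- tabulate(px, nbins = np)
  circ2 <- (pi * dbh)^2
  sumC2 <- numeric(np)
  if (length(px)) {
    agg <- rowsum(cbind(circ2, g = pi * (dbh / 200)^2), px, reorder = FALSE)
    idx <- as.integer(rownames(agg))
    sumC2[idx] <- agg[, 1L]
    G <- numeric(np); G[idx] <- agg[, 2L]
  } else G <- numeric(np)
  Cg <- ifelse(N > 0, sqrt(sumC2 / pmax(N, 1L)), 0)

  Hdom <- numeric(np)
  if (length(px)) {
    o <- order(px, -h)
    spx <- px[o]; sh <- h[o]
    rank <- sequence(rle(spx)$lengths)
    top <- rank <= ndom
    aggH <- rowsum(cbind(sh[top], 1), spx[top], reorder = FALSE)
    Hdom[as.integer(rownames(aggH))] <- aggH[, 1L] / aggH[, 2L]
  }
  rdi <- rep(NA_real_, np)
  if (!is.null(selfThinning)) {
    nmax <- selfThinning@reinekeK * ifelse(Cg > 0, Cg^(-selfThinning@reinekeB), Inf)
    rdi <- ifelse(N > 0, (N / pxAreaHa) / nmax, 0)
  }
  data.frame(pixel = seq_len(np), N = N, G = G, Cg = Cg, Hdom = Hdom, RDI = rdi)
}

#' Pixel center coordinates
#'
#' @param stand a [ForestStand-class].
#' @return data.frame `pixel`, `cx`, `cy` (m).
#' @export
pixelCenters <- function(stand) {
  ps <- stand@pixelSize
  ix <- rep(seq_len(stand@nx) - 1L, times = stand@ny)
  iy <- rep(seq_len(stand@ny) - 1L, each = stand@nx)
  data.frame(pixel = seq_len(stand@nx * stand@ny),
             cx = (ix + 0.5) * ps, cy = (iy + 0.5) * ps)
}

## bookkeeping helper: mark trees dead/removed (one-way transition)
.markStatus <- function(stand, ids, status) {
  if (!length(ids)) return(stand)
  i <- match(ids, stand@trees$id)
  stopifnot(!anyNA(i), all(stand@trees$status[i] == "alive"))
  stand@trees$status[i] <- status
  stand
}
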