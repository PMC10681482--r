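## fecundity, seed dispersal to pixel centers, fertility-weighted mating,
## seedling creation with inherited genotypes, and the recruitment transition

#' Fecundity parameter constructor
#'
#' Defaults give a 5-class ordinal cone model monotone in dbh and crown
#' height, with permanent inter-individual and annual inter-tree latent noise,
#' class midpoints of 0/10/50/200/500 cones, 40 viable seeds per cone and a
#' seedling multiplier of 5 — together these land simulated seedling densities
#' in the several-thousands-per-hectare range typical of natural Atlas cedar
#' regeneration, comfortably above the 2800/ha recruitment reset.
#'
#' @param fertilityDbh diameter threshold for fertility (cm).
#' @param coneIntercept,coneDbhSlope,coneCrownSlope latent-score coefficients.
#' @param sdTree,sdYear latent standard deviations (permanent / annual).
#' @param thresholds latent cutpoints (length 4 for 5 classes).
#' @param coneMidpoints cones per class (length 5).
#' @param seedsPerCone mean viable seeds per cone.
#' @param seedlingMultiplier multiplier on established seedlings per pixel.
#' @param selfing may the mother also be the father.
#' @return a [FecundityParams-class].
#' @export
fecundityParams <- function(fertilityDbh = 15, coneIntercept = -2.2,
                            coneDbhSlope = 0.15, coneCrownSlope = 0.05,
                            sdTree = 0.5, sdYear = 0.5,
                            thresholds = c(1, 2, 3, 4),
                            coneMidpoints = c(0, 10, 50, 200, 500),
                            seedsPerCone = 40, seedlingMultiplier = 5,
                            selfing = TRUE) {
  new("FecundityParams", fertilityDbh = fertilityDbh,
      coneIntercept = coneIntercept, coneDbhSlope = coneDbhSlope,
      coneCrownSlope = coneCrownSlope, sdTree = sdTree, sdYear = sdYear,
      thresholds = thresholds, coneMidpoints = coneMidpoints,
      seedsPerCone = seedsPerCone, seedlingMultiplier = seedlingMultiplier,
      selfing = selfing)
}

#' Dispersal kernel constructor
#'
#' 2D exponential-power kernel; the scale follows from the mean dispersal
#' distance through alpha = mean * Gamma(2/s) / Gamma(3/s).
#'
#' @param shape shape s in (0, 1) (0.5 by default: fat-tailed).
#' @param meanDistance mean dispersal distance in meters (240 by default).
#' @return a [DispersalKernel-class].
#' @export
dispersalKernel <- function(shape = 0.5, meanDistance = 240) {
  alpha <- meanDistance * gamma(2 / shape) / gamma(3 / shape)
  new("DispersalKernel", shape = shape, scale = alpha,
      meanDistance = meanDistance)
}

#' Dispersal density at distance r
#'
#' The planar density f(r) = s / (2 pi alpha^2 Gamma(2/s)) exp(-(r/alpha)^s),
#' normalized so that the integral over the plane is 1.
#'
#' @param kernel a [DispersalKernel-class].
#' @param r distances in meters (vectorized).
#' @return density per m^2.
#' @export
kernelDensity <- function(kernel, r) {
  s <- kernel@shape; a <- kernel@scale
  s / (2 * pi * a^2 * gamma(2 / s)) * exp(-(r / a)^s)
}

#' Sample dispersal distances
#'
#' Radial distances follow r = alpha * T^(1/s) with T ~ Gamma(2/s, 1).
#'
#' @param kernel a [DispersalKernel-class].
#' @param n number of draws.
#' @return distances in meters.
#' @export
sampleDispersalDistance <- function(kernel, n) {
  kernel@scale * rgamma(n, shape = 2 / kernel@shape)^(1 / kernel@shape)
}

## fertility predicate: strictly older than recruitment age AND dbh above the
## threshold
.isFertile <- function(age, dbh, recruitmentAge, fertilityDbh) {
  age > recruitmentAge & dbh > fertilityDbh
}

#' Annual female fecundity (viable seeds)
#'
#' Non-fertile trees (age <= recruitment age or dbh <= threshold) produce 0.
#' Fertile trees draw an ordinal cone class: a latent score linear in dbh and
#' crown height plus the tree's permanent effect and a fresh annual draw is
#' cut at the class thresholds; seeds = class midpoint cones * seedsPerCone.
#'
#' @param dbh,crownHeight,age tree attributes (vectorized).
#' @param coneEffect permanent tree-level latent effects (drawn at creation).
#' @param params a [FecundityParams-class].
#' @param recruitmentAge recruitment age in years.
#' @return viable seed counts.
#' @export
femaleFecundity <- function(dbh, crownHeight, age, coneEffect = 0,
                            params = fecundityParams(), recruitmentAge = 25) {
  n <- length(dbh)
  coneEffect <- rep_len(coneEffect, n)
  fertile <- .isFertile(age, dbh, recruitmentAge, params@fertilityDbh)
  latent <- params@coneIntercept + params@coneDbhSlope * dbh +
    params@coneCrownSlope * crownHeight + coneEffect +
    rnorm(n, 0, params@sdYear)
  cls <- 1L + findInterval(latent, params@thresholds)
  seeds <- params@coneMidpoints[cls] * params@seedsPerCone
  ifelse(fertile, seeds, 0)
}

#' Relative male fertility
#'
#' dbh squared for fertile trees (a proxy of pollen production), 0 otherwise.
#'
#' @param dbh,age tree attributes (vectorized).
#' @param params a [FecundityParams-class].
#' @param recruitmentAge recruitment age in years.
#' @return relative fertility index.
#' @export
maleFertility <- function(dbh, age, params = fecundityParams(),
                          recruitmentAge = 25) {
  ifelse(.isFertile(age, dbh, recruitmentAge, params@fertilityDbh), dbh^2, 0)
}

#' Per-mother seed-rain contributions at pixel centers
#'
#' contribution\[m, p\] = seeds_m * f(distance between mother m and the center
#' of pixel p), in seeds per m^2.
#'
#' @param motherX,motherY mother coordinates (m).
#' @param seeds viable seed counts of the mothers.
#' @param centerX,centerY pixel-center coordinates (m).
#' @param kernel a [DispersalKernel-class].
#' @return matrix (mothers x pixels) of expected seed densities.
#' @export
seedRainContributions <- function(motherX, motherY, seeds, centerX, centerY,
                                  kernel = dispersalKernel()) {
  d <- sqrt(outer(motherX, centerX, "-")^2 + outer(motherY, centerY, "-")^2)
  seeds * kernelDensity(kernel, d)
}

#' Generate one year of seedlings
#'
#' For each pixel, the number of established seedlings is
#' round(total seed-rain density at the pixel center * 1 m^2) * multiplier.
#' Each seedling draws its mother proportionally to her contribution at that
#' pixel and its father among all fertile trees proportionally to male
#' fertility (selfing allowed by default); its genotype is one gamete from
#' each parent, its genotypic value is computed immediately, and its fixed
#' environmental term is drawn. Seedlings are unrecruited (age 0, no
#' dendrometrics) and inert until recruitment.
#'
#' @param stand a [ForestStand-class] with the regeneration window open.
#' @param fecundity a [FecundityParams-class].
#' @param kernel a [DispersalKernel-class].
#' @param growth a [GrowthParams-class] (recruitment age).
#' @param veFixed fixed environmental variance for the new trees.
#' @return list with the updated `stand` and `nSeedlings`.
#' @export
generateSeedlings <- function(stand, fecundity = fecundityParams(),
                              kernel = dispersalKernel(),
                              growth = growthParams(), veFixed = 0) {
  tr <- stand@trees
  alive <- which(tr$status == "alive" & tr$recruited)
  fert <- alive[.isFertile(tr$age[alive], tr$dbh[alive],
                           growth@recruitmentAge, fecundity@fertilityDbh)]
  if (!length(fert)) return(list(stand = stand, nSeedlings = 0L))

  seeds <- femaleFecundity(tr$dbh[fert], tr$crownHeight[fert], tr$age[fert],
                           tr$coneEffect[fert], fecundity,
                           growth@recruitmentAge)
  ctr <- pixelCenters(stand)
  contrib <- seedRainContributions(tr$x[fert], tr$y[fert], seeds,
                                   ctr$cx, ctr$cy, kernel)
  density <- colSums(contrib)
  nPerPixel <- as.integer(round(density) * fecundity@seedlingMultiplier)
  nTot <- sum(nPerPixel)
  if (nTot == 0L) return(list(stand = stand, nSeedlings = 0L))

  ## mothers: per pixel, proportional to contribution at that pixel center
  motherRow <- integer(nTot)
  pixelOfSeedling <- rep(seq_along(nPerPixel), nPerPixel)
  off <- 0L
  for (p in which(nPerPixel > 0L)) {
    k <- nPerPixel[p]
    motherRow[off + seq_len(k)] <-
      fert[sample.int(length(fert), k, replace = TRUE, prob = contrib[, p])]
    off <- off + k
  }
  ## fathers: stand-wide, proportional to male fertility
  mf <- maleFertility(tr$dbh[fert], tr$age[fert], fecundity,
                      growth@recruitmentAge)
  if (!fecundity@selfing && length(fert) < 2L)
    return(list(stand = stand, nSeedlings = 0L))
  fatherRow <- fert[sample.int(length(fert), nTot, replace = TRUE, prob = mf)]
  if (!fecundity@selfing) {
    bad <- which(fatherRow == motherRow)
    while (length(bad)) {
      fatherRow[bad] <- fert[sample.int(length(fert), length(bad),
                                        replace = TRUE, prob = mf)]
      bad <- bad[fatherRow[bad] == motherRow[bad]]
    }
  }

  ps <- stand@pixelSize
  px <- pixelOfSeedling
  colIx <- (px - 1L) %% stand@nx
  rowIx <- (px - 1L) %/% stand@nx
  x <- (colIx + runif(nTot)) * ps
  y <- (rowIx + runif(nTot)) * ps

  new <- .emptyTrees(nTot)
  new$id <- max(tr$id) + seq_len(nTot)
  new$x <- x; new$y <- y; new$pixel <- px
  new$cohort <- stand@cycle + 1L
  new$age <- 0
  new$motherId <- tr$id[motherRow]
  new$fatherId <- tr$id[fatherRow]
  new$envFixed <- rnorm(nTot, 0, sqrt(veFixed))
  new$coneEffect <- rnorm(nTot, 0, fecundity@sdTree)

  if (!is.null(stand@map)) {
    g1 <- makeGametes(stand@hap1[motherRow, , drop = FALSE],
                      stand@hap2[motherRow, , drop = FALSE], stand@map)
    g2 <- makeGametes(stand@hap1[fatherRow, , drop = FALSE],
                      stand@hap2[fatherRow, , drop = FALSE], stand@map)
    new$gv <- genotypicValue(g1, g2, stand@map)
    stand@hap1 <- rbind(stand@hap1, g1)
    stand@hap2 <- rbind(stand@hap2, g2)
  } else {
    stand@hap1 <- rbind(stand@hap1, matrix(0L, nTot, 0))
    stand@hap2 <- rbind(stand@hap2, matrix(0L, nTot, 0))
  }
  stand@trees <- rbind(tr, new)
  list(stand = stand, nSeedlings = nTot)
}

#' Recruit the accumulated seedling cohort
#'
#' Closes a regeneration cycle: any remaining adult is removed, all
#' accumulated seedlings jump to the recruitment age with diameters drawn from
#' the initial-diameter distribution independently of genotype, self-thinning
#' regulates over-stocked pixels, and a stand-wide random thinning resets the
#' density to `targetDensity` (no upward adjustment when seedlings are too
#' few — a warning is issued). The cycle index increments and the stand age is
#' set to the recruitment age.
#'
#' @param stand a [ForestStand-class] after the final harvest.
#' @param targetDensity stems/ha after the reset (2800 by default).
#' @param growth,selfThinningPar process parameters.
#' @param meanDbh,cvDbh,minDbh initial-diameter distribution (cm).
#' @return list with the updated `stand`, `nRecruited` (after reset) and
#'   `shortfall` (TRUE when seedlings were fewer than the target).
#' @export
recruitCohort <- function(stand, targetDensity = 2800,
                          growth = growthParams(),
                          selfThinningPar = selfThinningParams(),
                          meanDbh = 7, cvDbh = 0.25, minDbh = 0.5) {
  tr <- stand@trees
  leftover <- tr$id[tr$status == "alive" & tr$recruited]
  stand <- .markStatus(stand, leftover, "removed_harvest")
  tr <- stand@trees
  sdl <- which(tr$status == "alive" & !tr$recruited)
  if (!length(sdl)) stop("no seedlings to recruit: population collapse")
  n <- length(sdl)
  tr$age[sdl] <- growth@recruitmentAge
  tr$dbh[sdl] <- .rtnorm(n, meanDbh, cvDbh * meanDbh, minDbh)
  tr$recruited[sdl] <- TRUE
  stand@trees <- tr
  stand@standAge <- growth@recruitmentAge
  stand@cycle <- stand@cycle + 1L
  stand@phase <- "growth-phase"
  stand <- .updateDimensions(stand, growth)
  stand <- selfThinning(stand, selfThinningPar)$stand
  nAlive <- sum(stand@trees$status == "alive")
  target <- as.integer(round(targetDensity * stand@areaHa))
  shortfall <- nAlive < target
  if (shortfall)
    warning(sprintf(
      "only %d recruits for a target of %d: no upward adjustment", nAlive,
      target))
  stand <- applyThinning(stand, targetDensity, mode = "random")$stand
  list(stand = stand, nRecruited = sum(stand@trees$status == "alive"),
       shortfall = shortfall)
}

## recompute heights, crown heights (and implicitly volumes) of alive
## recruited trees from the pixel dominant diameter and the age-based
## dominant-height curve
.updateDimensions <- function(stand, growth) {
  tr <- stand@trees
  use <- which(tr$status == "alive" & tr$recruited)
  if (!length(use)) return(stand)
  Hdom <- dominantHeight(stand@standAge, stand@siteIndex, growth)
  pxAreaHa <- stand@pixelSize^2 / 1e4
  ndom <- max(1L, as.integer(round(growth@ndomPerHa * pxAreaHa)))
  px <- tr$pixel[use]; dbh <- tr$dbh[use]
  o <- order(px, -dbh)
  rank <- sequence(rle(px[o])$lengths)
  top <- rank <= ndom
  agg <- rowsum(cbind(dbh[o][top], 1), px[o][top], reorder = FALSE)
  ddom <- setNames(agg[, 1L] / agg[, 2L], rownames(agg))
  ## anchor per pixel: h = Hdom * (dbh / Ddom(pixel))^psi
  relD <- dbh / ddom[as.character(px)]
  h <- Hdom * relD^growth@heightExponent
  tr$height[use] <- h
  tr$crownHeight[use] <- growth@crownRatio * h
  stand@trees <- tr
  stand
}
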