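## annual dendrometric growth: dominant-height development, pixel-level
## basal-area increment, linear individual allocation above a circumference
## threshold, vigor adjustment, and derived tree dimensions

#' Growth parameter constructor
#'
#' @param curveK,curveC Chapman-Richards rate/shape of the dominant-height
#'   curve (asymptote solved from the site index at age 50).
#' @param eta,gamma,lowRdiScale stand basal-area-increment coefficients:
#'   dG (m^2 ha^-1 y^-1) = eta * dHdom * G_ha^gamma * (1 - exp(-RDI/lowRdiScale)).
#' @param allocSlope slope of the individual circumference-increment line.
#' @param recruitmentAge years before which trees neither grow nor express
#'   their phenotype.
#' @param heightExponent,crownRatio,formFactor allometric coefficients for
#'   tree height, crown height and stem volume.
#' @param ndomPerHa dominant trees per hectare defining Hdom and the dominant
#'   diameter anchor.
#' @return a [GrowthParams-class].
#' @export
growthParams <- function(curveK = 0.03, curveC = 1.5,
                         eta = 2.6, gamma = 0.3, lowRdiScale = 0.1,
                         allocSlope = 0.01, recruitmentAge = 25,
                         heightExponent = 0.8, crownRatio = 0.6,
                         formFactor = 0.5, ndomPerHa = 100) {
  new("GrowthParams", curveK = curveK, curveC = curveC, eta = eta,
      gamma = gamma, lowRdiScale = lowRdiScale, allocSlope = allocSlope,
      recruitmentAge = recruitmentAge, heightExponent = heightExponent,
      crownRatio = crownRatio, formFactor = formFactor, ndomPerHa = ndomPerHa)
}

#' Dominant height development curve
#'
#' Chapman-Richards curve H(age) = A (1 - exp(-k age))^c with the asymptote A
#' solved so that H(50) equals the site index. Monotone increasing with
#' H(0) = 0.
#'
#' @param age stand age in years (vectorized).
#' @param siteIndex dominant height (m) at age 50.
#' @param params a [GrowthParams-class].
#' @return dominant height in meters.
#' @examples
#' dominantHeight(50, 20)  # 20 by construction
#' @export
dominantHeight <- function(age, siteIndex, params = growthParams()) {
  stopifnot(all(age >= 0))
  k <- params@curveK; cc <- params@curveC
  A <- siteIndex / (1 - exp(-k * 50))^cc
  A * (1 - exp(-k * age))^cc
}

## relative density index of a pixel
.rdi <- function(nPerHa, Cg, st) {
  ifelse(nPerHa > 0 & Cg > 0, nPerHa * Cg^st@reinekeB / st@reinekeK, 0)
}

#' Stand-level annual basal-area increment of a pixel
#'
#' dG = eta * dHdom * G_ha^gamma * s(RDI), expressed per hectare and scaled to
#' the pixel area; dHdom is the current-year increment of the dominant-height
#' curve and s(.) = 1 - exp(-RDI / lowRdiScale) smoothly reduces the increment
#' at very low stocking. Empty pixels get 0.
#'
#' @param N,G,Cg pixel stem count, basal area (m^2, pixel total) and quadratic
#'   mean circumference (cm); vectorized over pixels.
#' @param standAge current stand age (the increment is H(age) - H(age - 1)).
#' @param siteIndex site index (m at 50 years).
#' @param pixelAreaHa pixel area in hectares.
#' @param params a [GrowthParams-class].
#' @param selfThinning a [SelfThinningParams-class] (for RDI).
#' @return basal-area increments in m^2 per pixel per year (>= 0).
#' @export
standBasalAreaIncrement <- function(N, G, Cg, standAge, siteIndex,
                                    pixelAreaHa,
                                    params = growthParams(),
                                    selfThinning = selfThinningParams()) {
  dH <- dominantHeight(standAge, siteIndex, params) -
    dominantHeight(standAge - 1, siteIndex, params)
  Gha <- G / pixelAreaHa
  rdi <- .rdi(N / pixelAreaHa, Cg, selfThinning)
  s <- 1 - exp(-rdi / params@lowRdiScale)
  dG <- params@eta * dH * Gha^params@gamma * s * pixelAreaHa
  ifelse(N > 0, pmax(dG, 0), 0)
}

## summed basal-area increment (m^2) implied by threshold sigma, per group
## circ: circumference (cm); grp: integer group index in 1..nGroups
.allocBA <- function(circ, grp, sigma, m, nGroups) {
  dc <- m * pmax(0, circ - sigma[grp])
  val <- (2 * circ + dc) * dc          # (c+dc)^2 - c^2
  out <- numeric(nGroups)
  agg <- rowsum(val, grp, reorder = FALSE)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out / (4 * pi) * 1e-4
}

## solve, per group (pixel), the circumference threshold sigma such that the
## baseline increments dc = m * max(0, c - sigma) consume exactly the target
## basal-area increment; bisection on a monotone decreasing function
.allocSigma <- function(circ, grp, targetBA, m, nGroups, iters = 60L) {
  lo <- rep(Inf, nGroups); hi <- rep(-Inf, nGroups)
  cmin <- tapply(circ, grp, min); cmax <- tapply(circ, grp, max)
  idx <- as.integer(names(cmin))
  lo[idx] <- cmin; hi[idx] <- cmax
  active <- targetBA > 0 & is.finite(lo)
  if (!any(active)) return(rep(NA_real_, nGroups))
  ## expand lo downward until the target is attainable everywhere
  span <- pmax(hi - lo, 1)
  repeat {
    f <- .allocBA(circ, grp, lo, m, nGroups)
    short <- active & f < targetBA
    if (!any(short)) break
    lo[short] <- lo[short] - span[short]
    span[short] <- 2 * span[short]
  }
  ## invariant: f(lo) >= target >= f(hi); f is decreasing in sigma
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    f <- .allocBA(circ, grp, mid, m, nGroups)
    over <- f >= targetBA
    lo[active & over] <- mid[active & over]
    hi[active & !over] <- mid[active & !over]
  }
  sigma <- (lo + hi) / 2
  sigma[!active] <- NA_real_
  sigma
}

#' Allocate a pixel basal-area increment to individual trees
#'
#' Baseline circumference increments are linear in circumference above a
#' threshold: dc_i = m max(0, c_i - sigma), with sigma solved by bisection so
#' that the summed implied basal-area increments equal `dG` (sigma may fall
#' below the smallest circumference, giving all-positive baseline increments).
#' The final individual diameter increment adds the phenotypic vigor deviation
#' and is floored at zero: max(0, dc_i / pi + vigor_i).
#'
#' @param dG target basal-area increment of the pixel (m^2, >= 0).
#' @param circumference tree circumferences (cm, > 0).
#' @param vigor phenotypic vigor deviations (cm y^-1 of diameter increment).
#' @param params a [GrowthParams-class].
#' @return list with `dDbh` (cm diameter increments), `sigma` (threshold, cm)
#'   and `baselineDCirc` (cm baseline circumference increments).
#' @export
allocateIndividualIncrements <- function(dG, circumference, vigor = 0,
                                         params = growthParams()) {
  stopifnot(dG >= 0, all(circumference > 0))
  if (dG > 0 && length(circumference) == 0L)
    stop("cannot allocate a positive increment with no tree")
  vigor <- rep_len(vigor, length(circumference))
  if (length(circumference) == 0L)
    return(list(dDbh = numeric(0), sigma = NA_real_,
                baselineDCirc = numeric(0)))
  m <- params@allocSlope
  if (dG == 0) {
    dc <- numeric(length(circumference))
    sigma <- NA_real_
  } else {
    grp <- rep(1L, length(circumference))
    sigma <- .allocSigma(circumference, grp, dG, m, 1L)
    got <- .allocBA(circumference, grp, sigma, m, 1L)
    if (abs(got - dG) / dG > 1e-6)
      stop(sprintf(
        "allocation bisection did not converge: target %.6g, achieved %.6g, sigma %.4g",
        dG, got, sigma))
    dc <- m * pmax(0, circumference - sigma)
  }
  list(dDbh = pmax(0, dc / pi + vigor), sigma = unname(sigma),
       baselineDCirc = dc)
}

#' Derived tree dimensions
#'
#' Height follows a monotone height-diameter relation anchored so trees at the
#' pixel dominant diameter reach the dominant height:
#' h = Hdom (dbh / Ddom)^heightExponent. Crown height is a fixed fraction of
#' height and stem volume is form factor * basal area * height.
#'
#' @param dbh diameters (cm).
#' @param Hdom pixel dominant height (m).
#' @param Ddom pixel dominant diameter (cm): mean dbh of the trees defining
#'   Hdom.
#' @param params a [GrowthParams-class].
#' @return list with `height` (m), `crownHeight` (m) and `volume` (m^3).
#' @export
updateTreeDimensions <- function(dbh, Hdom, Ddom, params = growthParams()) {
  stopifnot(Ddom > 0)
  height <- Hdom * (dbh / Ddom)^params@heightExponent
  crownHeight <- params@crownRatio * height
  volume <- params@formFactor * pi * (dbh / 200)^2 * height
  list(height = height, crownHeight = crownHeight, volume = volume)
}
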