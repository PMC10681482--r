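#' @import methods
#' @importFrom stats rbinom rgamma rnorm runif rweibull pgamma qnorm pnorm
#'   dnorm var sd quantile setNames aggregate coef lm
#' @importFrom utils head read.csv write.csv tail
NULL

## status codes for individual trees; transitions are one-way from "alive"
.TREE_STATUS <- c("alive", "dead_selfthinning", "dead_disturbance",
                  "removed_thinning", "removed_harvest")

#' Genetic map of diallelic QTL
#'
#' A `QtlMap` holds, for each diallelic locus controlling vigor, the absolute
#' allelic effect (the "+" allele adds `+effect` to the genotypic value, the
#' alternative allele adds `-effect`; heterozygotes contribute 0 at the locus),
#' the initial frequency of the increasing allele, and the position on a
#' linkage map (group id and position in centimorgans, Haldane mapping).
#'
#' @slot loci data.frame with columns `locus`, `linkageGroup`, `positionCM`,
#'   `effect`, `initFreq`.
#' @export
setClass("QtlMap", representation(loci = "data.frame"))

setValidity("QtlMap", function(object) {
  l <- object@loci
  need <- c("locus", "linkageGroup", "positionCM", "effect", "initFreq")
  if (!all(need %in% names(l)))
    return(paste("loci must have columns:", paste(need, collapse = ", ")))
  if (nrow(l) < 1L) return("a QtlMap needs at least one locus")
  if (any(l$effect < 0)) return("allelic effects must be >= 0")
  if (any(l$initFreq <= 0 | l$initFreq >= 1))
    return("initial allele frequencies must lie strictly in (0, 1)")
  if (any(l$positionCM < 0)) return("map positions must be >= 0 cM")
  ## loci must be sorted within linkage group so adjacency = map adjacency
  o <- order(l$linkageGroup, l$positionCM)
  if (!identical(o, seq_len(nrow(l))))
    return("loci must be ordered by linkage group then map position")
  TRUE
})

#' Genetic setup: QTL map, variance targets and founder genotypes
#'
#' The result of the founder-initialization heuristic: a [QtlMap-class], the
#' target and realized additive variance and genetic mean of the founder
#' population, the heritability decomposition of the environmental variance,
#' and the phased founder haplotypes (rows = founders, columns = loci, values
#' 0/1 with 1 the increasing allele).
#'
#' @slot map [QtlMap-class].
#' @slot vaTarget,realizedVa target and realized additive variance (cm^2 y^-2).
#' @slot meanTarget,realizedMean target and realized genetic mean (cm y^-1).
#' @slot h2 narrow-sense heritability of vigor.
#' @slot veFixed,veStep environmental variance components: a fixed tree-level
#'   component and an inter-step component redrawn annually.
#' @slot hap1,hap2 founder haplotype matrices (integer 0/1).
#' @slot converged logical; FALSE when the restart budget was exhausted.
#' @slot iterations number of restarts used.
#' @export
setClass("GeneticSetup", representation(
  map = "QtlMap",
  vaTarget = "numeric", meanTarget = "numeric", h2 = "numeric",
  veFixed = "numeric", veStep = "numeric",
  realizedVa = "numeric", realizedMean = "numeric",
  hap1 = "matrix", hap2 = "matrix",
  converged = "logical", iterations = "numeric"))

setValidity("GeneticSetup", function(object) {
  if (ncol(object@hap1) != nrow(object@map@loci) ||
      !identical(dim(object@hap1), dim(object@hap2)))
    return("founder haplotype matrices must be n x nLoci and congruent")
  if (object@h2 <= 0 || object@h2 > 1) return("h2 must be in (0, 1]")
  TRUE
})

#' Dendrometric growth parameters
#'
#' Parameters of the distance-independent growth model: a Chapman-Richards
#' dominant-height curve anchored at the site index (dominant height at age
#' 50), a stand-level basal-area-increment equation, and the linear allocation
#' of the stand increment to individual circumference increments above a
#' dynamically solved circumference threshold.
#'
#' Defaults are calibrated to three anchors: dominant height 20 m at age 50
#' for site index 20, onset of self-thinning at stand age ~43 in an unthinned
#' stand starting at 2800 stems/ha at age 25, and seed trees passing the 15 cm
#' fertility diameter well before age 60.
#'
#' @slot curveK,curveC Chapman-Richards rate and shape; the asymptote is
#'   solved so the curve passes through (50, site index).
#' @slot eta,gamma stand basal-area increment: dG/ha = eta * dHdom * G_ha^gamma
#'   * s(RDI) (m^2 ha^-1 y^-1).
#' @slot lowRdiScale scale of the smooth low-stocking reduction
#'   s(RDI) = 1 - exp(-RDI / lowRdiScale).
#' @slot allocSlope slope m of the individual allocation: annual circumference
#'   increment = m * max(0, c - sigma) (cm per cm above threshold).
#' @slot recruitmentAge age (years) below which trees do not grow and the
#'   phenotype has no effect.
#' @slot heightExponent exponent of the height-diameter relation anchored at
#'   the pixel dominant diameter.
#' @slot crownRatio crown height as a fraction of total height.
#' @slot formFactor stem volume = formFactor * basal area * height.
#' @slot ndomPerHa number of dominant trees per hectare used for Hdom.
#' @export
setClass("GrowthParams", representation(
  curveK = "numeric", curveC = "numeric",
  eta = "numeric", gamma = "numeric", lowRdiScale = "numeric",
  allocSlope = "numeric", recruitmentAge = "numeric",
  heightExponent = "numeric", crownRatio = "numeric", formFactor = "numeric",
  ndomPerHa = "numeric"))

setValidity("GrowthParams", function(object) {
  vals <- c(object@curveK, object@curveC, object@eta, object@gamma,
            object@lowRdiScale, object@allocSlope, object@recruitmentAge,
            object@heightExponent, object@crownRatio, object@formFactor,
            object@ndomPerHa)
  if (any(!is.finite(vals)) || any(vals <= 0))
    return("all growth parameters must be positive")
  TRUE
})

#' Self-thinning (carrying capacity) parameters
#'
#' Reineke-type maximum density line: the carrying capacity of a pixel is
#' Nmax = reinekeK * Cg^(-reinekeB) stems per hectare, with Cg the quadratic
#' mean circumference (cm). Self-thinning removes the smallest trees one by
#' one while the relative density index N/Nmax exceeds `rdiMax`.
#'
#' @slot reinekeK intercept of the maximum density line (stems/ha at Cg = 1 cm).
#' @slot reinekeB slope of the maximum density line.
#' @slot rdiMax maximum relative density index, in (0, 1].
#' @export
setClass("SelfThinningParams", representation(
  reinekeK = "numeric", reinekeB = "numeric", rdiMax = "numeric"))

setValidity("SelfThinningParams", function(object) {
  if (object@reinekeK <= 0 || object@reinekeB <= 0)
    return("reinekeK and reinekeB must be positive")
  if (object@rdiMax <= 0 || object@rdiMax > 1)
    return("rdiMax must be in (0, 1]")
  TRUE
})

#' Disturbance regime
#'
#' Annual potential stand mortality rate distribution plus the local crown
#' modifier. `none` draws 0 every year. `medium` draws from a single Weibull
#' with long-run mean ~0.02. `severe` draws from a 5:1 mixture of a
#' low-mortality Weibull (mean ~0.04) and a high-mortality Weibull
#' (mean ~0.52), long-run mean ~0.12. Draws are clipped to [0, 1]. The
#' potential rate is reduced per pixel by (S_p / S_ref)^theta, S_p the summed
#' crown height of the pixel and S_ref the maximum over pixels.
#'
#' @slot kind one of "none", "medium", "severe".
#' @slot shapeLow,scaleLow Weibull of the (only, or low) component.
#' @slot shapeHigh,scaleHigh Weibull of the rare high-mortality component.
#' @slot probHigh probability of drawing the high component.
#' @slot theta exponent of the crown modifier.
#' @export
setClass("DisturbanceRegime", representation(
  kind = "character",
  shapeLow = "numeric", scaleLow = "numeric",
  shapeHigh = "numeric", scaleHigh = "numeric",
  probHigh = "numeric", theta = "numeric"))

setValidity("DisturbanceRegime", function(object) {
  if (!object@kind %in% c("none", "medium", "severe"))
    return("kind must be one of none, medium, severe")
  if (object@probHigh < 0 || object@probHigh > 1)
    return("probHigh must be in [0, 1]")
  TRUE
})

#' Fecundity and regeneration parameters
#'
#' Female fecundity is an ordinal cone-class model: a latent score linear in
#' dbh and crown height plus a permanent tree-level effect and an annual
#' tree-level draw is cut at fixed thresholds into 5 classes with midpoint
#' cone counts; viable seeds = cones * seedsPerCone. Trees are fertile iff
#' age > recruitment age and dbh > fertilityDbh. Male fertility is dbh^2.
#' The number of seedlings established in a pixel each regeneration year is
#' round(seed rain density at the pixel center * 1 m^2) * seedlingMultiplier.
#'
#' @slot fertilityDbh diameter threshold for fertility (cm).
#' @slot coneIntercept,coneDbhSlope,coneCrownSlope latent-score coefficients.
#' @slot sdTree,sdYear standard deviations of the inter-individual (permanent)
#'   and inter-annual (redrawn) latent effects.
#' @slot thresholds latent cutpoints separating the 5 ordinal classes.
#' @slot coneMidpoints cone counts of the 5 classes.
#' @slot seedsPerCone mean viable seeds per cone.
#' @slot seedlingMultiplier user multiplier on established seedlings.
#' @slot selfing logical; may the mother also be drawn as father.
#' @export
setClass("FecundityParams", representation(
  fertilityDbh = "numeric",
  coneIntercept = "numeric", coneDbhSlope = "numeric",
  coneCrownSlope = "numeric", sdTree = "numeric", sdYear = "numeric",
  thresholds = "numeric", coneMidpoints = "numeric",
  seedsPerCone = "numeric", seedlingMultiplier = "numeric",
  selfing = "logical"))

setValidity("FecundityParams", function(object) {
  if (object@fertilityDbh <= 0) return("fertilityDbh must be positive")
  if (object@seedsPerCone <= 0) return("seedsPerCone must be positive")
  if (length(object@coneMidpoints) != length(object@thresholds) + 1L)
    return("need one more cone-class midpoint than thresholds")
  TRUE
})

#' Seed dispersal kernel
#'
#' Two-dimensional exponential-power (fat-tailed) dispersal density
#' f(r) = s / (2 pi alpha^2 Gamma(2/s)) * exp(-(r/alpha)^s), normalized over
#' the plane. The scale alpha is set from the mean dispersal distance:
#' mean = alpha * Gamma(3/s) / Gamma(2/s).
#'
#' @slot shape shape s in (0, 1); small s = fatter tail.
#' @slot scale scale alpha (m), derived from `meanDistance`.
#' @slot meanDistance mean dispersal distance (m).
#' @export
setClass("DispersalKernel", representation(
  shape = "numeric", scale = "numeric", meanDistance = "numeric"))

setValidity("DispersalKernel", function(object) {
  if (object@shape <= 0 || object@shape >= 1)
    return("kernel shape must lie in (0, 1)")
  if (object@scale <= 0) return("kernel scale must be positive")
  TRUE
})

#' Silvicultural scenario
#'
#' A named, ordered schedule of interventions: thinnings to target densities
#' (random, from below, or from above), a seeding cut opening the 3-year
#' regeneration window, and a final harvest removing the seed trees.
#'
#' @slot name scenario name.
#' @slot interventions data.frame with columns `standAge`, `kind`
#'   ("thinning", "seeding_cut", "final_harvest"), `targetDensity` (stems/ha)
#'   and `mode` ("random", "from_below", "from_above").
#' @export
setClass("Scenario", representation(
  name = "character", interventions = "data.frame"))

setValidity("Scenario", function(object) {
  iv <- object@interventions
  need <- c("standAge", "kind", "targetDensity", "mode")
  if (!all(need %in% names(iv)))
    return(paste("interventions must have columns:", paste(need, collapse = ", ")))
  if (is.unsorted(iv$standAge))
    return("interventions must be sorted by stand age")
  if (any(iv$targetDensity < 0)) return("target densities must be >= 0")
  if (!all(iv$kind %in% c("thinning", "seeding_cut", "final_harvest")))
    return("unknown intervention kind")
  n <- nrow(iv)
  if (n < 2L || iv$kind[n - 1L] != "seeding_cut" || iv$kind[n] != "final_harvest")
    return("a scenario must end with a seeding cut followed by a final harvest")
  if (iv$standAge[n] - iv$standAge[n - 1L] != 3)
    return("the final harvest must come 3 years after the seeding cut")
  TRUE
})

#' Spatial and demographic state of a simulated stand
#'
#' One rectangular, environmentally homogeneous even-aged stand, tiled by a
#' regular grid of square pixels. Each pixel behaves as an independent
#' even-aged sub-stand: growth, competition and mortality never read
#' neighboring pixels; pixels interact only through seed and pollen flow
#' during regeneration. The tree registry keeps every tree ever created
#' (founders, seedlings, dead and removed trees) with one-way status
#' transitions from "alive".
#'
#' @slot width,height stand extent (m); origin at the corner, pixel of a tree
#'   is `floor(coord / pixelSize)` per axis (half-open intervals).
#' @slot pixelSize pixel edge (m), 15 by default.
#' @slot nx,ny number of pixel columns / rows.
#' @slot areaHa stand area (ha).
#' @slot siteIndex dominant height (m) at the reference age of 50 years.
#' @slot trees tree registry (one row per tree ever created).
#' @slot hap1,hap2 phased haplotypes aligned with the registry rows.
#' @slot map [QtlMap-class] or NULL for runs without genetic variation.
#' @slot standAge age (years) of the current even-aged cohort.
#' @slot cycle silvicultural cycle index (1-based).
#' @slot phase "growth-phase", "regeneration-window" or "pre-recruitment-wait".
#' @export
setClass("ForestStand", representation(
  width = "numeric", height = "numeric", pixelSize = "numeric",
  nx = "integer", ny = "integer", areaHa = "numeric", siteIndex = "numeric",
  trees = "data.frame", hap1 = "matrix", hap2 = "matrix", map = "ANY",
  standAge = "numeric", cycle = "integer", phase = "character"))

setValidity("ForestStand", function(object) {
  if (object@areaHa <= 0) return("stand area must be positive")
  if (object@nx * object@pixelSize != object@width ||
      object@ny * object@pixelSize != object@height)
    return("the pixel grid must tile the stand extent exactly")
  tr <- object@trees
  if (nrow(tr)) {
    if (!all(tr$status %in% .TREE_STATUS)) return("invalid tree status")
    if (any(tr$dbh < 0, na.rm = TRUE)) return("dbh must be >= 0")
    if (any(tr$age < 0)) return("age must be >= 0")
    alive <- tr$status == "alive"
    px <- .pixelOf(tr$x[alive], tr$y[alive], object@pixelSize, object@nx)
    if (any(px != tr$pixel[alive]))
      return("every alive tree must sit in its containing pixel")
  }
  if (nrow(object@hap1) != nrow(tr) || nrow(object@hap2) != nrow(tr))
    return("haplotype matrices must have one row per registered tree")
  TRUE
})

#' Configuration of a simulation run
#'
#' Bundles stand geometry, genetic architecture targets, the silvicultural
#' scenario, disturbance regime, process parameters and the three named random
#' seeds (genetic setup, inventory, dynamics).
#'
#' @export
setClass("SimConfig", representation(
  width = "numeric", height = "numeric", pixelSize = "numeric",
  siteIndex = "numeric", initialDensity = "numeric", initialAge = "numeric",
  meanDbh = "numeric", cvDbh = "numeric", minDbh = "numeric",
  variation = "logical", nQtl = "numeric", vaTarget = "numeric",
  h2 = "numeric", nLinkageGroups = "numeric",
  scenario = "Scenario", regime = "DisturbanceRegime",
  growth = "GrowthParams", selfThinning = "SelfThinningParams",
  fecundity = "FecundityParams", kernel = "DispersalKernel",
  nCycles = "numeric", recruitDensity = "numeric",
  setupSeed = "numeric", inventorySeed = "numeric", dynamicsSeed = "numeric",
  countRemovalsInProduction = "logical", h0OnPhenotype = "logical"))

#' Result of a simulation run
#'
#' @slot records one row per executed process year (Table-style outputs).
#' @slot cycles one row per completed cycle (selection differentials,
#'   end-of-cycle dendrometrics, mortality ledgers).
#' @slot h0 evolutionary rate in haldanes over the run (NA when undefined).
#' @slot collapse TRUE when the population collapsed before completing the run.
#' @slot finalStand the [ForestStand-class] at the end of the run.
#' @slot config the [SimConfig-class] used.
#' @slot setup the [GeneticSetup-class] used (or NULL without variation).
#' @export
setClass("SimRun", representation(
  records = "data.frame", cycles = "data.frame", h0 = "numeric",
  collapse = "logical", finalStand = "ForestStand", config = "SimConfig",
  setup = "ANY"))
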