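## finite-loci additive quantitative genetics: QTL map construction, the
## founder-initialization heuristic, genotype -> phenotype map, gamete
## formation with Haldane recombination, and population summaries

#' Construct a QTL map
#'
#' Builds the diallelic map for the vigor trait. When `linkageGroup` /
#' `positionCM` are not supplied, loci are spread over `nLinkageGroups` groups
#' in contiguous blocks and placed uniformly over a 100 cM group (a single
#' locus sits at 50 cM).
#'
#' @param effects absolute allelic effects a_l (cm y^-1), one per locus.
#' @param initFreqs initial frequencies of the increasing allele, in (0, 1).
#' @param linkageGroup,positionCM optional explicit map placement.
#' @param nLinkageGroups number of linkage groups for the default layout.
#' @return a [QtlMap-class].
#' @examples
#' qtlMap(effects = c(0.05, 0.03), initFreqs = c(0.5, 0.5))
#' @export
qtlMap <- function(effects, initFreqs, linkageGroup = NULL, positionCM = NULL,
                   nLinkageGroups = 10) {
  n <- length(effects)
  stopifnot(length(initFreqs) == n)
  if (is.null(linkageGroup)) {
    perGroup <- ceiling(n / nLinkageGroups)
    linkageGroup <- rep(seq_len(nLinkageGroups), each = perGroup)[seq_len(n)]
  }
  if (is.null(positionCM)) {
    positionCM <- numeric(n)
    for (g in unique(linkageGroup)) {
      i <- which(linkageGroup == g)
      positionCM[i] <- if (length(i) == 1L) 50 else
        seq(0, 100, length.out = length(i))
    }
  }
  loci <- data.frame(locus = seq_len(n), linkageGroup = linkageGroup,
                     positionCM = positionCM, effect = effects,
                     initFreq = initFreqs)
  loci <- loci[order(loci$linkageGroup, loci$positionCM, loci$locus), ]
  loci$locus <- seq_len(n)
  rownames(loci) <- NULL
  new("QtlMap", loci = loci)
}

#' Genotypic values of vigor
#'
#' Purely additive: the genotypic value is the sum over loci and haplotypes of
#' +a_l for the increasing allele and -a_l for the alternative; heterozygous
#' loci contribute 0 (no dominance).
#'
#' @param hap1,hap2 0/1 haplotype matrices (rows = individuals) or vectors for
#'   a single individual.
#' @param map a [QtlMap-class] matching the genotype length.
#' @return numeric vector of genotypic values (cm y^-1).
#' @export
genotypicValue <- function(hap1, hap2, map) {
  if (is.null(dim(hap1))) hap1 <- matrix(hap1, 1L)
  if (is.null(dim(hap2))) hap2 <- matrix(hap2, 1L)
  a <- map@loci$effect
  if (ncol(hap1) != length(a) || ncol(hap2) != length(a))
    stop("genotype length does not match the QTL map")
  ## dosage d in {0,1,2}: per-locus contribution a*(2d - 2)
  drop((hap1 + hap2 - 1) %*% (2 * a))
}

#' Phenotypic vigor
#'
#' Phenotype = genotypic value + fixed environmental term (drawn once at tree
#' creation) + inter-step environmental term (redrawn annually; 0 in the
#' default setting, making the phenotype constant over a tree's life).
#'
#' @param gv genotypic value(s).
#' @param envFixed fixed environmental term(s).
#' @param envStep inter-step environmental term(s), default 0.
#' @return phenotypic vigor (cm y^-1).
#' @export
phenotypicVigor <- function(gv, envFixed, envStep = 0) gv + envFixed + envStep

#' Expected additive variance of a map under Hardy-Weinberg equilibrium
#'
#' With allelic effects +/- a_l, the allele-substitution effect at a locus is
#' alpha_l = 2 a_l, and the per-locus linkage-equilibrium additive variance is
#' 2 p_l q_l alpha_l^2 = 8 p_l q_l a_l^2 (the variance of a_l (2 d - 2) with
#' dosage d ~ Binomial(2, p_l)).
#'
#' @param map a [QtlMap-class].
#' @return the linkage-equilibrium additive variance (cm^2 y^-2).
#' @export
hweAdditiveVariance <- function(map) {
  p <- map@loci$initFreq
  a <- map@loci$effect
  sum(2 * p * (1 - p) * (2 * a)^2)
}

#' Initialize the genetic setup of a founder population
#'
#' Heuristic restart loop realizing a target additive variance with a finite
#' set of diallelic QTL: (1) per-locus contributions to the variance drawn
#' from a Gamma (shape `shapeContrib`, giving few QTL of large contribution)
#' and normalized to the target; (2) frequencies of the increasing allele
#' drawn from a Gamma (shape `shapeFreq`) and rank-rescaled into
#' (`pMin`, 1 - `pMin`); (3) allelic effects deduced as
#' a_l = sqrt(c_l / (2 p_l q_l)); (4) founder haplotypes drawn per locus as
#' independent Bernoulli(p_l) (linkage equilibrium at the start). Steps repeat
#' until the realized founder variance is within `tol` (relative) of the
#' target and the realized mean within `meanTolFactor * sqrt(vaTarget)` of the
#' target, or `maxIter` restarts are exhausted (the best fit is then returned
#' with `converged = FALSE`; a fit worse than `hardCeiling` raises an error
#' carrying the best setup in its condition data).
#'
#' @param nQtl number of diallelic QTL.
#' @param nFounders number of founder individuals to draw.
#' @param vaTarget target additive variance (cm^2 y^-2).
#' @param meanTarget target genetic mean (cm y^-1), 0 by default (vigor is a
#'   deviation from the baseline growth model).
#' @param h2 narrow-sense heritability; the fixed environmental variance is
#'   vaTarget (1 - h2) / h2 with a null inter-step component.
#' @param tol relative tolerance on the realized variance.
#' @param meanTolFactor absolute mean tolerance in units of sqrt(vaTarget).
#' @param maxIter maximum number of restarts.
#' @param hardCeiling relative variance error beyond which failure is an error.
#' @param pMin frequency clamp bound.
#' @param shapeContrib,shapeFreq Gamma shapes of the two draws.
#' @param nLinkageGroups linkage groups of the default map layout.
#' @return a [GeneticSetup-class] including the founder haplotypes.
#' @examples
#' set.seed(1)
#' gs <- initGeneticSetup(10, nFounders = 2000)
#' gs@realizedVa
#' @export
initGeneticSetup <- function(nQtl, nFounders, vaTarget = 0.0042,
                             meanTarget = 0, h2 = 0.3, tol = 0.02,
                             meanTolFactor = 0.05, maxIter = 1000,
                             hardCeiling = 0.10, pMin = 0.05,
                             shapeContrib = 0.5, shapeFreq = 2,
                             nLinkageGroups = 10) {
  stopifnot(nQtl >= 1, vaTarget > 0, tol > 0, nFounders >= 2)
  meanTol <- meanTolFactor * sqrt(vaTarget)
  best <- NULL
  bestErr <- Inf
  for (it in seq_len(maxIter)) {
    contrib <- rgamma(nQtl, shape = shapeContrib)
    contrib <- contrib / sum(contrib) * vaTarget
    ## rank transform: the Gamma CDF of a Gamma draw is Uniform(0,1)
    p <- pMin + (1 - 2 * pMin) * pgamma(rgamma(nQtl, shape = shapeFreq),
                                        shape = shapeFreq)
    ## allele-substitution effect alpha with contribution c = 2 p q alpha^2;
    ## the absolute allelic effect is half of it (alleles are +a / -a)
    a <- sqrt(contrib / (2 * p * (1 - p))) / 2
    map <- qtlMap(a, p, nLinkageGroups = nLinkageGroups)
    ## map construction may reorder loci; realign a, p
    hap1 <- matrix(rbinom(nFounders * nQtl, 1L,
                          rep(map@loci$initFreq, each = nFounders)),
                   nFounders, nQtl)
    hap2 <- matrix(rbinom(nFounders * nQtl, 1L,
                          rep(map@loci$initFreq, each = nFounders)),
                   nFounders, nQtl)
    gv <- genotypicValue(hap1, hap2, map)
    rVa <- var(gv)
    rMean <- mean(gv)
    errVa <- abs(rVa - vaTarget) / vaTarget
    errMean <- abs(rMean - meanTarget)
    err <- errVa / tol + errMean / meanTol
    if (err < bestErr) {
      bestErr <- err
      best <- list(map = map, hap1 = hap1, hap2 = hap2, rVa = rVa,
                   rMean = rMean, errVa = errVa, it = it)
    }
    if (errVa <= tol && errMean <= meanTol) break
  }
  converged <- best$errVa <= tol && abs(best$rMean - meanTarget) <= meanTol
  setup <- new("GeneticSetup", map = best$map,
               vaTarget = vaTarget, meanTarget = meanTarget, h2 = h2,
               veFixed = vaTarget * (1 - h2) / h2, veStep = 0,
               realizedVa = best$rVa, realizedMean = best$rMean,
               hap1 = best$hap1, hap2 = best$hap2,
               converged = converged, iterations = best$it)
  if (!converged) {
    if (best$errVa > hardCeiling) {
      cond <- structure(
        class = c("silvigen_setup_failure", "error", "condition"),
        list(message = sprintf(
          "genetic setup failed to fit: relative VA error %.3f after %d restarts",
          best$errVa, maxIter), call = sys.call(), best = setup))
      stop(cond)
    }
    warning(sprintf(
      "genetic setup did not converge in %d restarts (best VA error %.3f); returning best fit",
      maxIter, best$errVa))
  }
  setup
}

## per-locus probability that the gamete state switches haplotype relative to
## the previous locus: 0.5 at the start of each linkage group (independent
## assortment), else the Haldane recombination fraction of the map interval
.switchProbs <- function(map) {
  l <- map@loci
  d <- c(Inf, diff(l$positionCM))
  newGroup <- c(TRUE, diff(l$linkageGroup) != 0)
  r <- (1 - exp(-2 * d / 100)) / 2
  r[newGroup] <- 0.5
  r
}

#' Form gametes by Mendelian segregation and recombination
#'
#' For each row, one haplotype is sampled from the parental pair: loci on
#' different linkage groups assort independently; within a group the gamete
#' switches parental haplotype between adjacent loci with the Haldane
#' recombination fraction of the map interval. No mutation.
#'
#' @param hap1,hap2 parental haplotype matrices, one row per gamete to form
#'   (repeat a parent's rows to draw several gametes).
#' @param map the [QtlMap-class].
#' @return a 0/1 matrix of gametes, same shape as the inputs.
#' @examples
#' m <- qtlMap(c(.1, .1), c(.5, .5), linkageGroup = c(1, 1),
#'             positionCM = c(0, 50))
#' g <- makeGametes(matrix(1, 10, 2), matrix(0, 10, 2), m)
#' @export
makeGametes <- function(hap1, hap2, map) {
  if (is.null(dim(hap1))) hap1 <- matrix(hap1, 1L)
  if (is.null(dim(hap2))) hap2 <- matrix(hap2, 1L)
  n <- nrow(hap1)
  L <- nLoci(map)
  stopifnot(ncol(hap1) == L, identical(dim(hap1), dim(hap2)))
  r <- .switchProbs(map)
  out <- matrix(0L, n, L)
  state <- rep(FALSE, n)             # FALSE = copy hap1, TRUE = copy hap2
  for (l in seq_len(L)) {
    state <- xor(state, runif(n) < r[l])
    out[, l] <- ifelse(state, hap2[, l], hap1[, l])
  }
  out
}

#' Nei's expected heterozygosity over the QTL
#'
#' Mean over loci of 2 p (1 - p), with p the sample frequency of the
#' increasing allele. For diallelic loci He lies in [0, 0.5].
#'
#' @param hap1,hap2 haplotype matrices of the population.
#' @return expected heterozygosity (dimensionless).
#' @export
expectedHeterozygosity <- function(hap1, hap2) {
  if (is.null(dim(hap1))) hap1 <- matrix(hap1, 1L)
  if (is.null(dim(hap2))) hap2 <- matrix(hap2, 1L)
  if (nrow(hap1) < 1L) stop("He is undefined for an empty population")
  p <- (colSums(hap1) + colSums(hap2)) / (2 * nrow(hap1))
  mean(2 * p * (1 - p))
}

#' Realized additive genetic variance
#'
#' Sample variance of individual genotypic values; this is the realized
#' genetic variance, including any selection-induced linkage-disequilibrium
#' covariances between loci.
#'
#' @param gv genotypic values of the (alive) population.
#' @return variance (cm^2 y^-2).
#' @export
additiveVariance <- function(gv) {
  if (length(gv) < 2L) stop("additive variance is undefined for < 2 individuals")
  var(gv)
}
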