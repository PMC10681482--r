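test_that("genotypic values are purely additive with no dominance", {
  map <- qtlMap(c(0.05, 0.03, 0.02), c(0.5, 0.4, 0.6))
  ## heterozygous at every locus -> 0
  expect_equal(genotypicValue(c(1, 1, 1), c(0, 0, 0), map), 0)
  ## single locus: (1,1) -> +2a, (0,0) -> -2a
  m1 <- qtlMap(0.05, 0.5)
  expect_equal(genotypicValue(1, 1, m1), 0.10)
  expect_equal(genotypicValue(0, 0, m1), -0.10)
  ## random 50-locus genotypes match a per-allele loop oracle
  set.seed(3)
  m50 <- qtlMap(runif(50, 0.001, 0.05), runif(50, 0.1, 0.9))
  h1 <- matrix(rbinom(20 * 50, 1, 0.5), 20)
  h2 <- matrix(rbinom(20 * 50, 1, 0.5), 20)
  a <- m50@loci$effect
  oracle <- vapply(1:20, function(i)
    sum(ifelse(h1[i, ] == 1, a, -a)) + sum(ifelse(h2[i, ] == 1, a, -a)),
    numeric(1))
  expect_equal(genotypicValue(h1, h2, m50), oracle, tolerance = 1e-12)
  expect_error(genotypicValue(c(1, 0), c(0, 1), m1), "does not match")
})

test_that("phenotype is genotype plus environment with the target variance", {
  expect_equal(phenotypicVigor(0.02, -0.01, 0), 0.01)
  expect_equal(phenotypicVigor(0.02, 0, 0), 0.02)  # no-variation reference
  set.seed(21)
  gs <- initGeneticSetup(50, nFounders = 10000)
  phen <- phenotypicVigor(genotypicValue(gs@hap1, gs@hap2, gs@map),
                          rnorm(10000, 0, sqrt(gs@veFixed)))
  ## VP = VA / h2 = 0.0042 / 0.3 = 0.014
  expect_lt(abs(var(phen) - 0.014) / 0.014, 0.05)
})

test_that("the setup heuristic hits the variance target and is seed-sensitive", {
  set.seed(101)
  gs <- initGeneticSetup(10, nFounders = 3000)
  expect_true(gs@converged)
  expect_lt(abs(gs@realizedVa - 0.0042) / 0.0042, 0.02)
  expect_lt(abs(gs@realizedMean), 0.05 * sqrt(0.0042))
  expect_equal(gs@veFixed, 0.0042 * 0.7 / 0.3)
  set.seed(202)
  gs2 <- initGeneticSetup(10, nFounders = 3000)
  expect_false(isTRUE(all.equal(lociEffects(gs), lociEffects(gs2))))
  expect_false(isTRUE(all.equal(lociFrequencies(gs), lociFrequencies(gs2))))
})

test_that("gametes segregate and recombine per the Haldane map", {
  m1 <- qtlMap(0.01, 0.5)
  ## fully homozygous parent: gamete equals either haplotype
  g <- makeGametes(matrix(1L, 50, 1), matrix(1L, 50, 1), m1)
  expect_true(all(g == 1L))
  ## Mendelian segregation at a heterozygous locus
  set.seed(8)
  n <- 10000
  g <- makeGametes(matrix(1L, n, 1), matrix(0L, n, 1), m1)
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(g) - 0.5), 3 * se)
  ## two loci 50 cM apart in coupling: recombinants at (1 - exp(-1)) / 2
  m2 <- qtlMap(c(0.01, 0.01), c(0.5, 0.5), linkageGroup = c(1, 1),
               positionCM = c(0, 50))
  g2 <- makeGametes(matrix(1L, n, 2), matrix(0L, n, 2), m2)
  recomb <- mean(g2[, 1] != g2[, 2])
  rExp <- (1 - exp(-1)) / 2
  expect_lt(abs(recomb - rExp), 3 * sqrt(rExp * (1 - rExp) / n))
})

test_that("expected heterozygosity matches allele counting and its bounds", {
  ## all loci at p = 0.5 -> 0.5 (diallelic maximum)
  h1 <- rbind(c(1L, 1L), c(0L, 0L))
  h2 <- rbind(c(0L, 1L), c(1L, 0L))
  expect_equal(expectedHeterozygosity(h1, h2), 0.5)
  ## a fixed locus contributes 0
  expect_equal(expectedHeterozygosity(matrix(1L, 4, 1), matrix(1L, 4, 1)), 0)
  ## random 20-individual sample vs a counting oracle
  set.seed(12)
  a <- matrix(rbinom(20 * 5, 1, 0.3), 20)
  b <- matrix(rbinom(20 * 5, 1, 0.3), 20)
  p <- sapply(1:5, function(l) sum(a[, l] + b[, l]) / 40)
  expect_equal(expectedHeterozygosity(a, b), mean(2 * p * (1 - p)),
               tolerance = 1e-12)
  expect_true(expectedHeterozygosity(a, b) >= 0 &&
                expectedHeterozygosity(a, b) <= 0.5)
  expect_error(expectedHeterozygosity(matrix(0L, 0, 2), matrix(0L, 0, 2)),
               "empty")
})

test_that("realized additive variance follows the HWE identity and Bulmer direction", {
  expect_equal(additiveVariance(rep(0.02, 10)), 0)
  expect_error(additiveVariance(0.1), "undefined")
  set.seed(31)
  gs <- initGeneticSetup(50, nFounders = 20000)
  gv <- genotypicValue(gs@hap1, gs@hap2, gs@map)
  hwe <- hweAdditiveVariance(gs@map)
  expect_lt(abs(var(gv) - hwe) / hwe, 0.05)
  ## truncation selection on genotypic value reduces the variance
  keep <- gv >= quantile(gv, 0.5)
  expect_lt(var(gv[keep]), var(gv))
})

test_that("offspring-midparent regression recovers the heritability", {
  set.seed(77)
  nPairs <- 4000
  gs <- initGeneticSetup(50, nFounders = 2 * nPairs)
  gv <- genotypicValue(gs@hap1, gs@hap2, gs@map)
  phen <- gv + rnorm(2 * nPairs, 0, sqrt(gs@veFixed))
  mo <- seq_len(nPairs); fa <- nPairs + seq_len(nPairs)
  off1 <- makeGametes(gs@hap1[mo, ], gs@hap2[mo, ], gs@map)
  off2 <- makeGametes(gs@hap1[fa, ], gs@hap2[fa, ], gs@map)
  offPhen <- genotypicValue(off1, off2, gs@map) +
    rnorm(nPairs, 0, sqrt(gs@veFixed))
  midParent <- (phen[mo] + phen[fa]) / 2
  slope <- coef(lm(offPhen ~ midParent))[2]
  expect_lt(abs(slope - 0.3), 0.06)
})

test_that("reproduction without selection conserves allele frequencies", {
  set.seed(55)
  gs <- initGeneticSetup(20, nFounders = 2000)
  n <- 5000
  mo <- sample(2000, n, replace = TRUE)
  fa <- sample(2000, n, replace = TRUE)
  g1 <- makeGametes(gs@hap1[mo, ], gs@hap2[mo, ], gs@map)
  g2 <- makeGametes(gs@hap1[fa, ], gs@hap2[fa, ], gs@map)
  pParent <- (colSums(gs@hap1) + colSums(gs@hap2)) / 4000
  pOff <- (colSums(g1) + colSums(g2)) / (2 * n)
  se <- sqrt(pParent * (1 - pParent) / (2 * n))
  expect_true(all(abs(pOff - pParent) < 4 * se))
})
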