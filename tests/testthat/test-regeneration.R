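test_that("fertility requires both the age and the diameter threshold", {
  set.seed(2)
  fp <- fecundityParams()
  ## dbh below/at 15 cm: no seeds, whatever the age
  expect_equal(femaleFecundity(14, 10, 60, 0, fp), 0)
  expect_equal(femaleFecundity(15, 10, 60, 0, fp), 0)
  ## age not strictly above the recruitment age: no seeds
  expect_equal(femaleFecundity(30, 10, 25, 0, fp), 0)
  expect_equal(maleFertility(30, 25), 0)
  expect_equal(maleFertility(14, 60), 0)
  ## male fertility is dbh squared: ratio exactly 4 for 40 vs 20 cm
  expect_equal(maleFertility(40, 60) / maleFertility(20, 60), 4)
})

test_that("female fecundity is monotone in size on average", {
  set.seed(19)
  n <- 10000
  small <- femaleFecundity(rep(20, n), rep(8, n), rep(60, n), 0)
  large <- femaleFecundity(rep(40, n), rep(8, n), rep(60, n), 0)
  expect_gt(mean(large), mean(small))
})

test_that("the dispersal kernel is normalized with the right mean distance", {
  k <- dispersalKernel()
  ## quadrature of 2 pi r f(r) over a 5000 m radius
  mass <- integrate(function(r) 2 * pi * r * kernelDensity(k, r), 0, 5000,
                    rel.tol = 1e-9)$value
  expect_lt(abs(mass - 1), 1e-3)
  ## mean distance of a large sample of radii
  set.seed(31)
  r <- sampleDispersalDistance(k, 1e6)
  expect_lt(abs(mean(r) - 240) / 240, 0.01)
  ## single mother at the pixel center contributes seeds * f(0)
  contrib <- seedRainContributions(7.5, 7.5, 1000, 7.5, 7.5, k)
  expect_equal(contrib[1, 1], 1000 * kernelDensity(k, 0), tolerance = 1e-12)
})

test_that("paternity shares follow male fertility", {
  set.seed(37)
  st <- miniStand(1, 1, 2, dbhPattern = c(20, 40), age = 60)
  st@map <- qtlMap(c(0.01, 0.01), c(0.5, 0.5))
  st@hap1 <- matrix(c(1L, 0L), 2, 2)
  st@hap2 <- matrix(c(1L, 0L), 2, 2)
  st@phase <- "regeneration-window"
  fp <- fecundityParams(seedsPerCone = 2000)
  res <- generateSeedlings(st, fp)
  tr <- res$stand@trees
  off <- tr[tr$age == 0, ]
  expect_gt(nrow(off), 200)
  shareBig <- mean(off$fatherId == 2)
  se <- sqrt(0.8 * 0.2 / nrow(off))
  expect_lt(abs(shareBig - 0.8), 3 * se)
})

test_that("a single fertile tree selfs and seedlings inherit its gametes", {
  set.seed(41)
  st <- miniStand(1, 1, 1, dbhPattern = 40, age = 60)
  st@map <- qtlMap(c(0.05, 0.02), c(0.5, 0.5))
  st@hap1 <- matrix(1L, 1, 2)
  st@hap2 <- matrix(0L, 1, 2)
  st@phase <- "regeneration-window"
  res <- generateSeedlings(st, fecundityParams(seedsPerCone = 1000))
  off <- res$stand@trees[res$stand@trees$age == 0, ]
  expect_gt(nrow(off), 0)
  expect_true(all(off$motherId == 1L & off$fatherId == 1L))
})

test_that("offspring allele frequency matches the fertility-weighted gametic pool", {
  set.seed(43)
  n <- 30
  st <- miniStand(1, 1, n, dbhPattern = runif(n, 20, 50), age = 60)
  st@map <- qtlMap(0.02, 0.4)
  st@hap1 <- matrix(rbinom(n, 1, 0.4), n, 1)
  st@hap2 <- matrix(rbinom(n, 1, 0.4), n, 1)
  st@phase <- "regeneration-window"
  res <- generateSeedlings(st, fecundityParams(seedsPerCone = 2000))
  tr <- res$stand@trees
  off <- which(tr$age == 0)
  nOff <- length(off)
  expect_gt(nOff, 2000)
  pOff <- mean(res$stand@hap1[off, 1] + res$stand@hap2[off, 1]) / 2
  ## oracle: average of the mothers' realized contribution-weighted gametic
  ## frequency and the fathers' fertility-weighted gametic frequency
  pTree <- (st@hap1[, 1] + st@hap2[, 1]) / 2
  mumW <- tabulate(tr$motherId[off], nbins = n)
  pMum <- sum(pTree * mumW) / sum(mumW)
  mf <- maleFertility(st@trees$dbh, st@trees$age)
  pDad <- sum(pTree * mf) / sum(mf)
  pExp <- (pMum + pDad) / 2
  se <- sqrt(pExp * (1 - pExp) / (2 * nOff)) + 0.3 / sqrt(nOff)
  expect_lt(abs(pOff - pExp), 3 * se)
})

test_that("every seedling genotype is reconstructible from its parents", {
  set.seed(47)
  n <- 10
  st <- miniStand(1, 1, n, dbhPattern = runif(n, 25, 45), age = 60)
  st@map <- qtlMap(runif(5, 0.01, 0.04), runif(5, 0.3, 0.7))
  st@hap1 <- matrix(rbinom(5 * n, 1, 0.5), n, 5)
  st@hap2 <- matrix(rbinom(5 * n, 1, 0.5), n, 5)
  st@phase <- "regeneration-window"
  res <- generateSeedlings(st, fecundityParams(seedsPerCone = 1000))
  tr <- res$stand@trees
  off <- which(tr$age == 0)
  expect_gt(length(off), 10)
  for (i in head(off, 50)) {
    mo <- match(tr$motherId[i], tr$id)
    fa <- match(tr$fatherId[i], tr$id)
    ## each inherited haplotype allele must exist in the parent at that locus
    okM <- res$stand@hap1[i, ] == st@hap1[mo, ] |
      res$stand@hap1[i, ] == st@hap2[mo, ]
    okF <- res$stand@hap2[i, ] == st@hap1[fa, ] |
      res$stand@hap2[i, ] == st@hap2[fa, ]
    expect_true(all(okM) && all(okF))
  }
})

test_that("pixels interact only through seed and pollen flow", {
  set.seed(53)
  base <- miniStand(2, 1, 3, dbhPattern = c(30, 35, 40), age = 60)
  tr <- base@trees
  ## mothers only in pixel A (pixel 1): make pixel-2 trees infertile (young)
  tr$age[tr$pixel == 2] <- 10
  base@trees <- tr
  base@map <- qtlMap(0.02, 0.5)
  base@hap1 <- matrix(1L, 6, 1)
  base@hap2 <- matrix(0L, 6, 1)
  base@phase <- "regeneration-window"
  res <- generateSeedlings(base, fecundityParams(seedsPerCone = 1000))
  tr2 <- res$stand@trees
  off <- tr2[tr2$age == 0, ]
  expect_gt(nrow(off), 0)
  ## all seedlings (in both pixels) have pixel-A mothers
  momPixel <- tr2$pixel[match(off$motherId, tr2$id)]
  expect_true(all(momPixel == 1))
  expect_true(any(off$pixel == 2))  # seed rain reaches the other pixel
})

test_that("recruitment resets density with genotype-independent diameters", {
  set.seed(59)
  st <- makeStand(60, 60)
  st <- generateInventory(st, density = 300, age = 60, meanDbh = 30)
  n <- nTrees(st)
  st@map <- qtlMap(runif(10, 0.01, 0.04), rep(0.5, 10))
  st@hap1 <- matrix(rbinom(10 * n, 1, 0.5), n, 10)
  st@hap2 <- matrix(rbinom(10 * n, 1, 0.5), n, 10)
  st@trees$gv <- genotypicValue(st@hap1, st@hap2, st@map)
  st <- silvigen:::.updateDimensions(st, growthParams())
  st@phase <- "regeneration-window"
  for (i in 1:3) st <- generateSeedlings(st)$stand
  st <- finalHarvest(st)$stand
  sdl <- st@trees[st@trees$status == "alive" & !st@trees$recruited, ]
  preMean <- mean(sdl$gv)
  rc <- recruitCohort(st, targetDensity = 2800)
  tr <- rc$stand@trees
  rec <- tr[tr$status == "alive", ]
  ## density reset is exact when seedlings are plentiful
  expect_identical(nrow(rec), as.integer(round(2800 * 0.36)))
  expect_true(all(rec$age == 25))
  expect_identical(rc$stand@cycle, 2L)
  ## diameters independent of genotypic value
  r <- cor(rec$dbh, rec$gv)
  expect_lt(abs(r), 3 / sqrt(nrow(rec)))
  ## the random reset preserves the seedling genetic mean
  se <- sd(sdl$gv) * sqrt(1 / nrow(rec) - 1 / nrow(sdl))
  expect_lt(abs(mean(rec$gv) - preMean), 3 * se + 1e-12)
})
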