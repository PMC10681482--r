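test_that("the dominant-height curve passes through the site index anchor", {
  expect_equal(dominantHeight(50, 20), 20, tolerance = 1e-12)
  expect_equal(dominantHeight(0, 20), 0)
  expect_gt(dominantHeight(60, 20), dominantHeight(50, 20))
  ages <- seq(1, 150, by = 1)
  expect_true(all(diff(dominantHeight(ages, 20)) > 0))
})

test_that("stand basal-area increment vanishes for empty pixels and flat height", {
  stp <- selfThinningParams()
  expect_equal(standBasalAreaIncrement(0, 0, 0, 40, 20, 0.0225,
                                       selfThinning = stp), 0)
  ## at asymptotic age the dominant-height increment (and so dG) is ~0
  dG <- standBasalAreaIncrement(100, 1, 60, 3000, 20, 0.0225,
                                selfThinning = stp)
  expect_lt(dG, 1e-8)
  dG2 <- standBasalAreaIncrement(100, 1, 60, 40, 20, 0.0225,
                                 selfThinning = stp)
  expect_gt(dG2, 0)
})

test_that("allocation conserves the target increment and honors symmetry", {
  gp <- growthParams()
  ## identical trees, no vigor: equal increments summing to dG
  circ <- rep(60, 40)
  res <- allocateIndividualIncrements(0.02, circ, 0, gp)
  expect_equal(max(res$dDbh) - min(res$dDbh), 0, tolerance = 1e-10)
  ba <- sum(((circ + res$baselineDCirc)^2 - circ^2) / (4 * pi) * 1e-4)
  expect_equal(ba, 0.02, tolerance = 1e-8 * 0.02)
  ## zero increment, zero vigor: nothing grows
  res0 <- allocateIndividualIncrements(0, circ, 0, gp)
  expect_true(all(res0$dDbh == 0))
  expect_error(allocateIndividualIncrements(0.1, numeric(0)), "no tree")
})

test_that("the allocation threshold matches a brute-force grid search", {
  set.seed(9)
  circ <- runif(100, 20, 120)
  gp <- growthParams(allocSlope = 0.05)
  dG <- 0.015
  res <- allocateIndividualIncrements(dG, circ, 0, gp)
  ba <- sum(((circ + res$baselineDCirc)^2 - circ^2) / (4 * pi) * 1e-4)
  expect_equal(ba, dG, tolerance = 1e-8 * dG)
  ## independent fine-grid search for the threshold
  f <- function(sigma) {
    dc <- 0.05 * pmax(0, circ - sigma)
    sum(((circ + dc)^2 - circ^2) / (4 * pi) * 1e-4)
  }
  grid <- seq(min(circ) - 200, max(circ), by = 0.001)
  vals <- vapply(grid, f, numeric(1))
  sigmaGrid <- grid[which.min(abs(vals - dG))]
  expect_lt(abs(res$sigma - sigmaGrid), 0.001)
})

test_that("vigor is neutral for the mean increment when the floor is idle", {
  ## phenotypic variation balanced to zero, all trees above the threshold,
  ## vigor magnitudes below the baseline: mean increment is unchanged exactly
  circ <- rep(80, 50)
  vigor <- rep(c(-0.05, 0.05), 25)
  gp <- growthParams(allocSlope = 0.05)
  base <- allocateIndividualIncrements(0.02, circ, 0, gp)
  withV <- allocateIndividualIncrements(0.02, circ, vigor, gp)
  expect_true(all(base$dDbh > 0.05))        # floor is idle in this regime
  expect_equal(mean(withV$dDbh), mean(base$dDbh), tolerance = 1e-12)
  ## ranking: at equal circumference, higher vigor grows strictly more
  expect_true(all(withV$dDbh[vigor > 0] > withV$dDbh[vigor < 0]))
})

test_that("tree dimensions anchor at the dominant tree and stay monotone", {
  gp <- growthParams()
  d <- updateTreeDimensions(30, Hdom = 20, Ddom = 30, gp)
  expect_equal(d$height, 20)
  expect_equal(d$crownHeight, gp@crownRatio * 20)
  ## volume of a tree with basal area 0.0314 m2, height 20, form factor 0.5
  g <- pi * (20 / 200)^2
  v <- updateTreeDimensions(20, Hdom = 20, Ddom = 20, gp)$volume
  expect_equal(v, 0.5 * g * 20, tolerance = 1e-12)
  ## height strictly increasing in dbh at fixed Hdom
  hs <- updateTreeDimensions(seq(5, 60, by = 1), Hdom = 22, Ddom = 40, gp)$height
  expect_true(all(diff(hs) > 0))
})

test_that("growth without vigor conserves pixel basal area to the increment", {
  set.seed(14)
  st <- miniStand(2, 2, 40, dbhPattern = runif(40, 8, 25), age = 40)
  cfg <- simConfig(width = 30, height = 30, scenario = "U-long",
                   variation = FALSE)
  g0 <- sum(pi * (treeRegistry(st, aliveOnly = TRUE)$dbh / 200)^2)
  pd <- pixelDendrometrics(st)
  dG <- sum(standBasalAreaIncrement(pd$N, pd$G, pd$Cg, 41, 20, 0.0225,
                                    cfg@growth, cfg@selfThinning))
  st2 <- stepYear(st, simConfig(width = 30, height = 30,
                                scenario = "U-long", variation = FALSE,
                                regime = "none"))$stand
  tr2 <- treeRegistry(st2)
  grew <- tr2[tr2$status %in% c("alive", "dead_selfthinning"), ]
  g1 <- sum(pi * (grew$dbh / 200)^2)
  expect_equal(g1 - g0, dG, tolerance = 1e-8 * max(dG, 1e-12))
})
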