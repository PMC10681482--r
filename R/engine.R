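## annual-loop orchestration, multi-cycle runs, and the run-level outputs

#' Simulation configuration constructor
#'
#' @param width,height,pixelSize,siteIndex stand geometry (m) and site index.
#' @param initialDensity,initialAge founder cohort density (stems/ha) and age.
#' @param meanDbh,cvDbh,minDbh initial-diameter distribution (cm).
#' @param variation simulate genetic + environmental variation in vigor? When
#'   FALSE the run is the no-variation reference (no QTL effects, no
#'   environmental variance).
#' @param nQtl,vaTarget,h2,nLinkageGroups genetic architecture targets.
#' @param scenario a [Scenario-class] or a library name (see
#'   [scenarioLibrary()]).
#' @param regime a [DisturbanceRegime-class] or one of "none", "medium",
#'   "severe".
#' @param growth,selfThinning,fecundity,kernel process parameter objects.
#' @param nCycles number of complete silvicultural cycles.
#' @param recruitDensity density reset at recruitment (stems/ha).
#' @param setupSeed,inventorySeed,dynamicsSeed the three named random streams:
#'   genetic-setup optimization, initial inventory, and everything else.
#' @param countRemovalsInProduction include thinned/harvested volumes in
#'   cumulative production (dead volumes are always included).
#' @param h0OnPhenotype compute the evolutionary rate on phenotypic vigor
#'   (default) or on genotypic values.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(width = 210, height = 210, pixelSize = 15,
                      siteIndex = 20, initialDensity = 2800, initialAge = 25,
                      meanDbh = 7, cvDbh = 0.25, minDbh = 0.5,
                      variation = TRUE, nQtl = 50, vaTarget = 0.0042,
                      h2 = 0.3, nLinkageGroups = 10,
                      scenario = "U-long", regime = "none",
                      growth = growthParams(),
                      selfThinning = selfThinningParams(),
                      fecundity = fecundityParams(),
                      kernel = dispersalKernel(),
                      nCycles = 4, recruitDensity = 2800,
                      setupSeed = 1, inventorySeed = 2, dynamicsSeed = 3,
                      countRemovalsInProduction = TRUE,
                      h0OnPhenotype = TRUE) {
  if (is.character(scenario)) scenario <- scenarioLibrary(scenario)
  if (is.character(regime)) regime <- disturbanceRegime(regime)
  problems <- character(0)
  if (width <= 0 || height <= 0) problems <- c(problems, "non-positive extent")
  if (initialDensity <= 0) problems <- c(problems, "non-positive density")
  if (initialAge < growth@recruitmentAge)
    problems <- c(problems, "initial age below recruitment age")
  if (vaTarget <= 0) problems <- c(problems, "non-positive target variance")
  if (h2 <= 0 || h2 > 1) problems <- c(problems, "h2 outside (0, 1]")
  if (nCycles < 1) problems <- c(problems, "nCycles must be >= 1")
  if (length(problems))
    stop("invalid configuration: ", paste(problems, collapse = "; "))
  new("SimConfig", width = width, height = height, pixelSize = pixelSize,
      siteIndex = siteIndex, initialDensity = initialDensity,
      initialAge = initialAge, meanDbh = meanDbh, cvDbh = cvDbh,
      minDbh = minDbh, variation = variation, nQtl = nQtl,
      vaTarget = vaTarget, h2 = h2, nLinkageGroups = nLinkageGroups,
      scenario = scenario, regime = regime, growth = growth,
      selfThinning = selfThinning, fecundity = fecundity, kernel = kernel,
      nCycles = nCycles, recruitDensity = recruitDensity,
      setupSeed = setupSeed, inventorySeed = inventorySeed,
      dynamicsSeed = dynamicsSeed,
      countRemovalsInProduction = countRemovalsInProduction,
      h0OnPhenotype = h0OnPhenotype)
}

## annual growth of all pixels: stand basal-area increment, threshold
## allocation, vigor adjustment, and dimension update
.growTrees <- function(stand, growth, stp, veStep = 0) {
  tr <- stand@trees
  use <- which(tr$status == "alive" & tr$recruited)
  if (!length(use)) return(stand)
  pxAreaHa <- stand@pixelSize^2 / 1e4
  px <- tr$pixel[use]
  dbh <- tr$dbh[use]
  circ <- pi * dbh
  upx <- sort(unique(px))
  grp <- match(px, upx)
  ng <- length(upx)
  agg <- rowsum(cbind(1, circ^2, pi * (dbh / 200)^2), grp, reorder = TRUE)
  N <- agg[, 1L]
  Cg <- sqrt(agg[, 2L] / N)
  G <- agg[, 3L]
  dG <- standBasalAreaIncrement(N, G, Cg, stand@standAge, stand@siteIndex,
                                pxAreaHa, growth, stp)
  sigma <- .allocSigma(circ, grp, dG, growth@allocSlope, ng)
  dc <- growth@allocSlope * pmax(0, circ - sigma[grp])
  dc[dG[grp] <= 0] <- 0
  vigor <- tr$gv[use] + tr$envFixed[use]
  if (veStep > 0) vigor <- vigor + rnorm(length(use), 0, sqrt(veStep))
  tr$dbh[use] <- dbh + pmax(0, dc / pi + vigor)
  stand@trees <- tr
  .updateDimensions(stand, growth)
}

## execute one scheduled intervention; returns stand + removal ledger
.applyIntervention <- function(stand, row) {
  kind <- row$kind
  if (kind == "thinning") {
    res <- applyThinning(stand, row$targetDensity, mode = row$mode)
    list(stand = res$stand, removedIds = res$removedIds, kind = kind,
         seedTreeIds = integer(0))
  } else if (kind == "seeding_cut") {
    res <- seedingCut(stand, row$targetDensity)
    list(stand = res$stand, removedIds = res$removedIds, kind = kind,
         seedTreeIds = res$seedTreeIds)
  } else {
    res <- finalHarvest(stand)
    list(stand = res$stand, removedIds = res$removedIds, kind = kind,
         seedTreeIds = integer(0))
  }
}

#' Advance the simulation by one year
#'
#' Executes, in order: growth of all pixels, selective mortality through
#' self-thinning, non-selective mortality through disturbance, regeneration
#' (when the window is open), and any intervention scheduled at the new stand
#' age. Returns the updated stand and an event ledger (ids and volumes by
#' cause, the pre-intervention dendrometric snapshot, and seed-tree ids when a
#' seeding cut happened).
#'
#' @param stand a [ForestStand-class].
#' @param config a [SimConfig-class] (process parameters, scenario, regime).
#' @param veFixed fixed environmental variance passed to seedling creation.
#' @return list with `stand` and `events`.
#' @export
stepYear <- function(stand, config, veFixed = 0) {
  growth <- config@growth
  tr <- stand@trees
  rec <- tr$status == "alive" & tr$recruited
  tr$age[rec] <- tr$age[rec] + 1
  stand@trees <- tr
  stand@standAge <- stand@standAge + 1

  ## inter-step environmental component is null in the default setting
  stand <- .growTrees(stand, growth, config@selfThinning, veStep = 0)

  st <- selfThinning(stand, config@selfThinning)
  stand <- st$stand
  deadSTVol <- sum(.treeVolumes(stand@trees,
                                match(st$removedIds, stand@trees$id), growth))

  rate <- drawPotentialMortalityRate(config@regime)
  di <- applyDisturbance(stand, rate, config@regime)
  stand <- di$stand
  deadDVol <- sum(.treeVolumes(stand@trees,
                               match(di$removedIds, stand@trees$id), growth))

  nSeedlings <- 0L
  if (stand@phase == "regeneration-window") {
    rg <- generateSeedlings(stand, config@fecundity, config@kernel, growth,
                            veFixed = veFixed)
    stand <- rg$stand
    nSeedlings <- rg$nSeedlings
  }

  ## pre-intervention snapshot (end-of-cycle dendrometrics are read here)
  tr <- stand@trees
  alive <- which(tr$status == "alive" & tr$recruited)
  snapshot <- list(
    qmd = if (length(alive)) quadraticMeanDiameter(tr$dbh[alive]) else NA_real_,
    standingVolume = sum(.treeVolumes(tr, alive, growth)),
    nAlive = length(alive))

  iv <- config@scenario@interventions
  due <- iv[iv$standAge == stand@standAge, , drop = FALSE]
  interventions <- list()
  for (i in seq_len(nrow(due))) {
    res <- .applyIntervention(stand, due[i, ])
    vol <- sum(.treeVolumes(res$stand@trees,
                            match(res$removedIds, res$stand@trees$id), growth))
    stand <- res$stand
    interventions[[length(interventions) + 1L]] <-
      list(kind = res$kind, removedIds = res$removedIds, volume = vol,
           seedTreeIds = res$seedTreeIds)
  }

  list(stand = stand, events = list(
    deadSTIds = st$removedIds, deadSTVol = deadSTVol,
    deadDIds = di$removedIds, deadDVol = deadDVol,
    potentialRate = rate, nSeedlings = nSeedlings,
    snapshot = snapshot, interventions = interventions))
}

## one annual output row (on the alive recruited population)
.annualRecord <- function(stand, year, cycleLedger, areaHa, variation) {
  tr <- stand@trees
  alive <- which(tr$status == "alive" & tr$recruited)
  n <- length(alive)
  he <- NA_real_
  if (variation && n > 0)
    he <- expectedHeterozygosity(stand@hap1[alive, , drop = FALSE],
                                 stand@hap2[alive, , drop = FALSE])
  data.frame(
    year = year, standAge = stand@standAge, cycle = stand@cycle,
    Nha = n / areaHa,
    muGVig = if (n) mean(tr$gv[alive]) else NA_real_,
    VAVig = if (n >= 2) var(tr$gv[alive]) else NA_real_,
    He = he,
    VhaProd = cumulativeProduction(cycleLedger$standingVolume,
                                   cycleLedger$removedVolume, areaHa),
    QMD = if (n) quadraticMeanDiameter(tr$dbh[alive]) else NA_real_,
    DeadST = cycleLedger$deadST / areaHa,
    DeadD = cycleLedger$deadD / areaHa)
}

#' Run a complete multi-cycle simulation
#'
#' Initializes the genetic setup (from the setup seed), the inventory (from
#' the inventory seed), then simulates `nCycles` complete silvicultural cycles
#' under the dynamics seed: annual process years from the initial age to the
#' final harvest, a 3-year regeneration window after the seeding cut, then a
#' single bookkeeping step recruiting the accumulated seedlings at the
#' recruitment age and resetting the density. After the last cycle the new
#' cohort is recruited, and the evolutionary rate is computed between the
#' founders and these final recruits (both sampled at the recruitment age).
#'
#' A population collapse — no surviving recruited tree and no seedling, no
#' fertile seed tree at a seeding cut, or an empty seedling pool at
#' recruitment — terminates the run early with partial records and an
#' undefined evolutionary rate.
#'
#' @param config a [SimConfig-class].
#' @return a [SimRun-class].
#' @examples
#' \donttest{
#' cfg <- simConfig(width = 60, height = 60, initialDensity = 2800,
#'                  scenario = "U-short", nCycles = 1)
#' run <- runSimulation(cfg)
#' head(annualRecords(run))
#' }
#' @export
runSimulation <- function(config) {
  growth <- config@growth
  areaHa <- config@width * config@height / 1e4
  nFounders <- as.integer(round(config@initialDensity * areaHa))

  setup <- NULL
  veFixed <- 0
  if (config@variation) {
    set.seed(config@setupSeed)
    setup <- initGeneticSetup(config@nQtl, nFounders = nFounders,
                              vaTarget = config@vaTarget, h2 = config@h2,
                              nLinkageGroups = config@nLinkageGroups)
    veFixed <- setup@veFixed
  }

  set.seed(config@inventorySeed)
  stand <- makeStand(config@width, config@height, config@pixelSize,
                     config@siteIndex)
  stand <- generateInventory(stand, config@initialDensity, config@initialAge,
                             config@meanDbh, config@cvDbh, config@minDbh)
  if (config@variation) {
    stand@map <- setup@map
    stand@hap1 <- setup@hap1
    stand@hap2 <- setup@hap2
    stand@trees$gv <- genotypicValue(setup@hap1, setup@hap2, setup@map)
  }

  set.seed(config@dynamicsSeed)
  n <- nrow(stand@trees)
  if (config@variation)
    stand@trees$envFixed <- rnorm(n, 0, sqrt(veFixed))
  stand@trees$coneEffect <- rnorm(n, 0, config@fecundity@sdTree)
  stand <- .updateDimensions(stand, growth)

  founderPhen <- stand@trees$gv + stand@trees$envFixed
  h0Start <- if (config@h0OnPhenotype) founderPhen else stand@trees$gv
  startMean <- mean(h0Start); startVar <- var(h0Start)

  records <- vector("list", 1024L)
  nRec <- 0L
  cycles <- list()
  year <- 0
  collapse <- FALSE
  endMean <- NA_real_; endVar <- NA_real_

  ## interventions scheduled at the initial age apply at cycle start
  applyStartInterventions <- function(stand, ledger) {
    iv <- config@scenario@interventions
    due <- iv[iv$standAge == stand@standAge, , drop = FALSE]
    for (i in seq_len(nrow(due))) {
      res <- .applyIntervention(stand, due[i, ])
      if (config@countRemovalsInProduction)
        ledger$removedVolume <- ledger$removedVolume +
          sum(.treeVolumes(res$stand@trees,
                           match(res$removedIds, res$stand@trees$id), growth))
      stand <- res$stand
    }
    list(stand = stand, ledger = ledger)
  }

  for (cyc in seq_len(config@nCycles)) {
    ledger <- list(deadST = 0L, deadD = 0L, removedVolume = 0,
                   standingVolume = 0)
    sa <- applyStartInterventions(stand, ledger)
    stand <- sa$stand; ledger <- sa$ledger
    trs <- stand@trees
    al <- trs$status == "alive" & trs$recruited
    cycStart <- list(meanGv = mean(trs$gv[al]), varGv = var(trs$gv[al]),
                     nha = sum(al) / areaHa)
    cycRow <- list(cycle = cyc, startMeanGv = cycStart$meanGv,
                   startVarGv = cycStart$varGv, startNha = cycStart$nha,
                   seedTreeMeanGv = NA_real_, selDiff = NA_real_,
                   qmdEnd = NA_real_, vhaProdEnd = NA_real_,
                   vhaProdPreCut = NA_real_,
                   deadST = NA_real_, deadD = NA_real_,
                   nRecruited = NA_integer_, shortfall = FALSE)
    harvested <- FALSE
    while (!harvested) {
      res <- stepYear(stand, config, veFixed = veFixed)
      stand <- res$stand
      ev <- res$events
      year <- year + 1
      ledger$deadST <- ledger$deadST + length(ev$deadSTIds)
      ledger$deadD <- ledger$deadD + length(ev$deadDIds)
      ledger$removedVolume <- ledger$removedVolume + ev$deadSTVol + ev$deadDVol
      for (ivn in ev$interventions) {
        if (config@countRemovalsInProduction)
          ledger$removedVolume <- ledger$removedVolume + ivn$volume
        if (ivn$kind == "seeding_cut") {
          cycRow$qmdEnd <- ev$snapshot$qmd
          cycRow$vhaProdPreCut <- cumulativeProduction(
            ev$snapshot$standingVolume, ledger$removedVolume -
              if (config@countRemovalsInProduction) ivn$volume else 0, areaHa)
          sIds <- ivn$seedTreeIds
          rows <- match(sIds, stand@trees$id)
          fertile <- .isFertile(stand@trees$age[rows], stand@trees$dbh[rows],
                                growth@recruitmentAge,
                                config@fecundity@fertilityDbh)
          ## demographic collapse: no fertile seed tree, or fewer than a
          ## tenth of the prescribed seed-tree stand left alive — the
          ## regeneration system cannot be implemented
          iv2 <- config@scenario@interventions
          sct <- iv2$targetDensity[iv2$kind == "seeding_cut"][1]
          if (!any(fertile) ||
              sum(fertile) < 0.1 * sct * areaHa) collapse <- TRUE
          cycRow$seedTreeMeanGv <- mean(stand@trees$gv[rows])
          cycRow$selDiff <- cycRow$seedTreeMeanGv - cycRow$startMeanGv
        }
        if (ivn$kind == "final_harvest") harvested <- TRUE
      }
      trs <- stand@trees
      alr <- trs$status == "alive" & trs$recruited
      ledger$standingVolume <- sum(.treeVolumes(trs, which(alr), growth))
      nRec <- nRec + 1L
      if (nRec > length(records)) records <- c(records, vector("list", 1024L))
      records[[nRec]] <- .annualRecord(stand, year, ledger, areaHa,
                                       config@variation)
      if (collapse) break
      if (!any(alr) && !any(trs$status == "alive" & !trs$recruited)) {
        collapse <- TRUE
        break
      }
    }
    if (collapse) {
      cycles[[cyc]] <- as.data.frame(cycRow)
      break
    }
    cycRow$vhaProdEnd <- cumulativeProduction(0, ledger$removedVolume, areaHa)
    cycRow$deadST <- ledger$deadST / areaHa
    cycRow$deadD <- ledger$deadD / areaHa
    ## recruitment: 25-year pre-recruitment wait bookkept in one step
    if (!any(stand@trees$status == "alive" & !stand@trees$recruited)) {
      collapse <- TRUE
      cycles[[cyc]] <- as.data.frame(cycRow)
      break
    }
    rc <- recruitCohort(stand, config@recruitDensity, growth,
                        config@selfThinning, config@meanDbh, config@cvDbh,
                        config@minDbh)
    stand <- rc$stand
    year <- year + growth@recruitmentAge
    cycRow$nRecruited <- rc$nRecruited
    cycRow$shortfall <- rc$shortfall
    cycles[[cyc]] <- as.data.frame(cycRow)
  }

  h0 <- NA_real_
  if (!collapse && config@variation) {
    trs <- stand@trees
    al <- which(trs$status == "alive" & trs$recruited)
    endVals <- if (config@h0OnPhenotype)
      trs$gv[al] + trs$envFixed[al] else trs$gv[al]
    endMean <- mean(endVals); endVar <- var(endVals)
    if (is.finite(endVar) && (startVar + endVar) > 0)
      h0 <- evolutionaryRateH0(startMean, endMean, startVar, endVar,
                               config@nCycles)
  }

  new("SimRun",
      records = do.call(rbind, records[seq_len(nRec)]),
      cycles = do.call(rbind, cycles),
      h0 = h0, collapse = collapse, finalStand = stand, config = config,
      setup = setup)
}
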