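## reading structured-text configurations and writing the run outputs in the
## standard exchange formats (annual records, pedigree, QTL map, inventory)

#' Read a simulation configuration from a YAML file
#'
#' Sections mirror the [simConfig()] arguments: `stand` (width, height,
#' pixel_size, site_index, density, age), `genetics` (variation, n_qtl, va,
#' h2, n_linkage_groups), `scenario` (name, or an explicit intervention list
#' with age/kind/target/mode entries), `disturbance` (kind), and `rng`
#' (setup_seed, inventory_seed, dynamics_seed).
#'
#' @param path path to the YAML configuration.
#' @return a [SimConfig-class].
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  g <- function(sec, key, default) {
    v <- y[[sec]][[key]]
    if (is.null(v)) default else v
  }
  sc <- y$scenario
  scn <- if (!is.null(sc$name)) scenarioLibrary(sc$name)
  else if (!is.null(sc$interventions)) {
    iv <- do.call(rbind, lapply(sc$interventions, function(r)
      data.frame(standAge = r$age, kind = r$kind,
                 targetDensity = if (is.null(r$target)) 0 else r$target,
                 mode = if (is.null(r$mode)) "random" else r$mode)))
    scenario(if (is.null(sc$label)) "custom" else sc$label, iv)
  } else scenarioLibrary("U-long")
  simConfig(
    width = g("stand", "width", 210), height = g("stand", "height", 210),
    pixelSize = g("stand", "pixel_size", 15),
    siteIndex = g("stand", "site_index", 20),
    initialDensity = g("stand", "density", 2800),
    initialAge = g("stand", "age", 25),
    variation = g("genetics", "variation", TRUE),
    nQtl = g("genetics", "n_qtl", 50),
    vaTarget = g("genetics", "va", 0.0042),
    h2 = g("genetics", "h2", 0.3),
    nLinkageGroups = g("genetics", "n_linkage_groups", 10),
    scenario = scn,
    regime = disturbanceRegime(g("disturbance", "kind", "none")),
    nCycles = g("scenario", "n_cycles", 4),
    setupSeed = g("rng", "setup_seed", 1),
    inventorySeed = g("rng", "inventory_seed", 2),
    dynamicsSeed = g("rng", "dynamics_seed", 3))
}

#' Write annual records with the standard output codes
#'
#' Column headers follow the standard output-variable codes: `Nha`,
#' `muG.Vig`, `VA(Vig)`, `He`, `VhaProd`, `QMD`, `DeadS-T`, `DeadD`, preceded
#' by `year`, `standAge` and `cycle`.
#'
#' @param run a [SimRun-class].
#' @param path output CSV path.
#' @export
writeAnnualRecords <- function(run, path) {
  r <- annualRecords(run)
  out <- data.frame(year = r$year, standAge = r$standAge, cycle = r$cycle,
                    r$Nha, r$muGVig, r$VAVig, r$He, r$VhaProd, r$QMD,
                    r$DeadST, r$DeadD, check.names = FALSE)
  names(out)[4:11] <- c("Nha", "muG.Vig", "VA(Vig)", "He", "VhaProd", "QMD",
                        "DeadS-T", "DeadD")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write the pedigree of a run
#'
#' One row per tree ever created: `id,cohort,mother_id,father_id` (founders
#' have empty parent fields).
#'
#' @param run a [SimRun-class] or [ForestStand-class].
#' @param path output CSV path.
#' @export
writePedigree <- function(run, path) {
  stand <- if (is(run, "SimRun")) run@finalStand else run
  tr <- stand@trees
  write.csv(data.frame(id = tr$id, cohort = tr$cohort,
                       mother_id = tr$motherId, father_id = tr$fatherId),
            path, row.names = FALSE)
  invisible(path)
}

#' Write a QTL map
#'
#' Columns `locus,linkage_group,position_cM,effect,init_freq`.
#'
#' @param map a [QtlMap-class].
#' @param path output CSV path.
#' @export
writeQtlMap <- function(map, path) {
  l <- map@loci
  write.csv(data.frame(locus = l$locus, linkage_group = l$linkageGroup,
                       position_cM = l$positionCM, effect = l$effect,
                       init_freq = l$initFreq),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a QTL map
#'
#' @param path CSV written by [writeQtlMap()].
#' @return a [QtlMap-class].
#' @export
readQtlMap <- function(path) {
  d <- read.csv(path)
  qtlMap(d$effect, d$init_freq, linkageGroup = d$linkage_group,
         positionCM = d$position_cM)
}

#' Write a tree inventory
#'
#' Columns `id,x,y,age,dbh,mother_id,father_id,genotype`; the genotype is the
#' string of per-locus allele dosages (count of the increasing allele, 0/1/2)
#' in map order. A phased-haplotype sidecar (`<path>.haplotypes.csv`) is
#' written alongside for exact replay.
#'
#' @param stand a [ForestStand-class].
#' @param path output CSV path.
#' @param aliveOnly restrict to alive trees (default TRUE).
#' @export
writeInventory <- function(stand, path, aliveOnly = TRUE) {
  tr <- stand@trees
  keep <- if (aliveOnly) tr$status == "alive" else rep(TRUE, nrow(tr))
  geno <- character(sum(keep))
  if (!is.null(stand@map) && ncol(stand@hap1) > 0) {
    d <- stand@hap1[keep, , drop = FALSE] + stand@hap2[keep, , drop = FALSE]
    geno <- apply(d, 1L, paste, collapse = "")
    h1 <- apply(stand@hap1[keep, , drop = FALSE], 1L, paste, collapse = "")
    h2 <- apply(stand@hap2[keep, , drop = FALSE], 1L, paste, collapse = "")
    write.csv(data.frame(id = tr$id[keep], hap1 = h1, hap2 = h2),
              paste0(path, ".haplotypes.csv"), row.names = FALSE)
  }
  write.csv(data.frame(id = tr$id[keep], x = tr$x[keep], y = tr$y[keep],
                       age = tr$age[keep], dbh = tr$dbh[keep],
                       mother_id = tr$motherId[keep],
                       father_id = tr$fatherId[keep], genotype = geno),
            path, row.names = FALSE)
  invisible(path)
}
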