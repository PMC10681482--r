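## timed interventions: thinning to target densities (random / from below /
## from above), seeding cut, final harvest, and the library of named scenarios

#' Thin a stand to a target density
#'
#' Removes `alive - round(target * area)` recruited trees when the stand is
#' above the target: uniformly at random (`random`), in ascending dbh order
#' (`from_below`) or descending dbh order (`from_above`), with ties broken by
#' id. Removed trees are flagged `removed_thinning`. Enforcement is stand-wide
#' (targets are stand densities, not per-pixel quotas).
#'
#' @param stand a [ForestStand-class].
#' @param targetDensity target density, stems/ha (>= 0).
#' @param mode "random", "from_below" or "from_above".
#' @return list with the updated `stand` and `removedIds`.
#' @examples
#' # 2800/ha on 4.41 ha thinned to 1100/ha removes exactly 7497 trees
#' @export
applyThinning <- function(stand, targetDensity,
                          mode = c("random", "from_below", "from_above")) {
  mode <- match.arg(mode)
  stopifnot(targetDensity >= 0)
  tr <- stand@trees
  alive <- which(tr$status == "alive" & tr$recruited)
  keep <- as.integer(round(targetDensity * stand@areaHa))
  nRemove <- length(alive) - keep
  if (nRemove <= 0L) return(list(stand = stand, removedIds = integer(0)))
  sel <- switch(mode,
    random = sample(alive, nRemove),
    from_below = alive[order(tr$dbh[alive], tr$id[alive])][seq_len(nRemove)],
    from_above = alive[order(-tr$dbh[alive], tr$id[alive])][seq_len(nRemove)])
  ids <- tr$id[sel]
  stand <- .markStatus(stand, ids, "removed_thinning")
  list(stand = stand, removedIds = ids)
}

#' Seeding cut
#'
#' Random thinning down to the seed-tree density (110/ha in all library
#' scenarios); the survivors are the seed trees and the 3-year regeneration
#' window opens. When fewer trees than the target are alive, none is removed
#' and a warning is issued.
#'
#' @param stand a [ForestStand-class].
#' @param targetDensity seed-tree density, stems/ha.
#' @return list with the updated `stand`, `removedIds` and `seedTreeIds`.
#' @export
seedingCut <- function(stand, targetDensity = 110) {
  nAlive <- sum(stand@trees$status == "alive" & stand@trees$recruited)
  if (nAlive < round(targetDensity * stand@areaHa))
    warning("fewer trees than the seed-tree target: keeping all")
  res <- applyThinning(stand, targetDensity, mode = "random")
  res$stand@phase <- "regeneration-window"
  tr <- res$stand@trees
  res$seedTreeIds <- tr$id[tr$status == "alive" & tr$recruited]
  res
}

#' Final harvest
#'
#' Removes all recruited alive trees (the seed trees), leaving only the
#' unrecruited seedlings; flagged `removed_harvest`.
#'
#' @param stand a [ForestStand-class].
#' @return list with the updated `stand` and `removedIds`.
#' @export
finalHarvest <- function(stand) {
  tr <- stand@trees
  ids <- tr$id[tr$status == "alive" & tr$recruited]
  stand <- .markStatus(stand, ids, "removed_harvest")
  stand@phase <- "pre-recruitment-wait"
  list(stand = stand, removedIds = ids)
}

#' Scenario constructor
#'
#' @param name scenario name.
#' @param interventions data.frame with columns `standAge`, `kind`,
#'   `targetDensity`, `mode`.
#' @return a [Scenario-class].
#' @export
scenario <- function(name, interventions) {
  new("Scenario", name = name, interventions = interventions)
}

.SCENARIO_THINNINGS <- list(
  "U-long"    = list(ages = integer(0), dens = numeric(0), cut = 100),
  "U-short"   = list(ages = integer(0), dens = numeric(0), cut = 60),
  "B-long"    = list(ages = c(25, 40, 50, 60, 70, 80),
                     dens = c(1100, 600, 430, 320, 245, 200), cut = 100),
  "B-short"   = list(ages = c(25, 30, 40), dens = c(1100, 600, 200), cut = 60),
  "E-low"     = list(ages = c(40, 50, 60, 70, 80),
                     dens = c(2400, 1720, 1280, 980, 800), cut = 100),
  "E-delayed" = list(ages = c(60, 70, 80), dens = c(320, 245, 200), cut = 100),
  "E-relaxed" = list(ages = c(25, 70, 80), dens = c(1100, 245, 200), cut = 100))

#' Library of named silvicultural scenarios
#'
#' Returns one of the seven reference schedules: unthinned long/short cycle
#' (`U-long`, `U-short`), baseline thinning long/short cycle (`B-long`,
#' `B-short`), and the exploratory low-intensity, delayed and relaxed variants
#' (`E-low`, `E-delayed`, `E-relaxed`). Every scenario ends with a seeding cut
#' to 110 seed trees/ha followed 3 years later by the final harvest. All
#' interventions are random (selectively neutral).
#'
#' @param name a scenario name.
#' @return a [Scenario-class].
#' @examples
#' scenarioLibrary("B-long")
#' @export
scenarioLibrary <- function(name) {
  if (!name %in% names(.SCENARIO_THINNINGS))
    stop("unknown scenario '", name, "'; valid names: ",
         paste(names(.SCENARIO_THINNINGS), collapse = ", "))
  sc <- .SCENARIO_THINNINGS[[name]]
  iv <- data.frame(
    standAge = c(sc$ages, sc$cut, sc$cut + 3),
    kind = c(rep("thinning", length(sc$ages)), "seeding_cut", "final_harvest"),
    targetDensity = c(sc$dens, 110, 0),
    mode = "random")
  scenario(name, iv)
}
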