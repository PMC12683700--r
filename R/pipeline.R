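#' Pipeline stages
#'
#' Each stage is a deterministic function of its inputs and seed, writing
#' plain-text primary outputs; the `stressorweave` command-line script wraps
#' these.  Rerunning a stage with the same inputs and seed reproduces its
#' outputs byte for byte.
#'
#' @name pipeline
NULL

#' @describeIn pipeline Simulate a synthetic dataset into a directory
#'   (`surfaces.csv`, the observation tables, and `truth.json` holding the
#'   generating parameters).
#' @param outDir output directory.
#' @param seed integer seed.
#' @param nInitial initial population size.
#' @param frame a [StudyFrame].
#' @param params a [simulationParameters()] list.
#' @return the output path(s), invisibly.
#' @export
runSimulateStage <- function(outDir, seed = 1L, nInitial = 60L,
                             frame = simFrame(),
                             params = simulationParameters()) {
  sim <- simulateDataset(frame = frame, params = params,
                         nInitial = nInitial, seed = seed)
  writeDataset(sim$individuals, sim$observations, outDir,
               surfaces = sim$surfaces)
  truth <- list(
    seed = seed, nInitial = nInitial,
    regions = regionLabels(frame),
    years = range(frameYears(frame)),
    eraBreakYear = eraBreakYear(frame),
    health = sim$truth$preyConstants,
    params = list(
      iota1 = params$iota1, iota2 = params$iota2, vTrend = params$vTrend,
      sigmaH = params$health$sigmaH, deltaGear = params$health$deltaGear,
      gammaGearPrey = params$health$gammaGearPrey,
      aS = params$vital$aS, bS = params$vital$bS,
      A0 = params$growth$A0, k = params$growth$k
    ),
    trueIndividuals = nrow(sim$truth$individuals),
    trueEntanglements = nrow(sim$truth$entanglements),
    trueStrikes = nrow(sim$truth$strikes)
  )
  jsonlite::write_json(truth, file.path(outDir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

#' @describeIn pipeline Validate a dataset directory (types, labels, history
#'   invariants).
#' @param dir dataset directory.
#' @export
runValidateStage <- function(dir, frame = simFrame()) {
  validateDataset(dir, frame)
  message("dataset at ", dir, " passed validation")
  invisible(TRUE)
}

#' @describeIn pipeline Estimate occupancy from a dataset directory and write
#'   the long-format `(t, class, region, z)` table.
#' @param dataDir dataset directory.
#' @param outPath output CSV.
#' @param version `"v1"` or `"v2"`.
#' @export
runOccupancyStage <- function(dataDir, outPath, version = "v1",
                              frame = simFrame()) {
  dd <- readIndividuals(dataDir)
  occ <- if (version == "v1") {
    occupancyV1All(fitDirichletOccupancy(dd$observations, dd$individuals, frame))
  } else {
    surfaces <- readSurfaces(file.path(dataDir, "surfaces.csv"), frame)
    occupancyV2(surfaces, classPropsFromSightings(dd$observations,
                                                  dd$individuals, frame))
  }
  writeOccupancy(occ, outPath)
  invisible(outPath)
}

#' @describeIn pipeline Compute per-class exposure probabilities and write
#'   the `(t, class, pEnt, pStrike, preyW)` table.
#' @param iota1,iota2,vTrend exposure coefficients.
#' @export
runExposureStage <- function(dataDir, outPath, iota1 = 0.02, iota2 = 0.02,
                             vTrend = 0.03, version = "v1",
                             frame = simFrame()) {
  dd <- readIndividuals(dataDir)
  surfaces <- readSurfaces(file.path(dataDir, "surfaces.csv"), frame)
  occ <- if (version == "v1") {
    occupancyV1All(fitDirichletOccupancy(dd$observations, dd$individuals, frame))
  } else {
    occupancyV2(surfaces, classPropsFromSightings(dd$observations,
                                                  dd$individuals, frame))
  }
  tab <- exposureTable(occ, surfaces, iota1, iota2, vTrend)
  tab$pEnt <- signif(tab$pEnt, 12); tab$pStrike <- signif(tab$pStrike, 12)
  tab$preyW <- signif(tab$preyW, 12)
  write.csv(tab, outPath, row.names = FALSE, quote = FALSE)
  invisible(outPath)
}

#' @describeIn pipeline Project the population under a scenario and write the
#'   per-year summary quantiles.
#' @param scenario a [ScenarioSpec].
#' @param params a [pvaParameters()] list.
#' @export
runProjectStage <- function(outPath, scenario = scenarioSpec(nDraws = 100L,
                                                             horizonYears = 50L),
                            params = pvaParameters(), seed = 1L) {
  res <- project(params, scenario, seed = seed)
  summ <- summarizeTrajectories(res)
  write.csv(summ$quantiles, outPath, row.names = FALSE, quote = FALSE)
  invisible(outPath)
}
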