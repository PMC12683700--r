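test_that("seeded generation is bit-identical on rerun", {
  fr <- simFrame(2010:2015)
  s1 <- generateSurfaces(fr, seed = 5)
  s2 <- generateSurfaces(fr, seed = 5)
  for (a in c("G", "entScalar", "AIS", "prey", "DSM"))
    expect_identical(assay(s1, a), assay(s2, a))
  par <- simulationParameters(pVha = 0.5)
  d1 <- simulateDataset(frame = fr, params = par, nInitial = 10, seed = 3)
  d2 <- simulateDataset(frame = fr, params = par, nInitial = 10, seed = 3)
  expect_identical(obsStream(d1$observations, "sightings"),
                   obsStream(d2$observations, "sightings"))
  expect_identical(d1$individuals, d2$individuals)
  expect_identical(d1$truth$entanglements, d2$truth$entanglements)
})

test_that("surfaces are positive with the configured structural features", {
  fr <- simFrame(1970:2019)
  s <- generateSurfaces(fr, seed = 8)
  for (a in c("G", "entScalar", "AIS", "prey", "DSM"))
    expect_true(all(assay(s, a) > 0), info = a)
  # entanglement risk elevated in the north
  G <- assay(s, "G")
  expect_gt(mean(G["NORTH", ]), mean(G["SOUTH", ]))
  # backcast scalar ramps to 1 by the anchor year and stays there
  eS <- assay(s, "entScalar")
  late <- stepYear(fr, seq_len(nSteps(fr))) >= 2015
  expect_true(all(eS[, late] == 1))
  expect_true(all(eS[, !late] <= 1))
})

test_that("zero regime-shift amplitude leaves pre/post prey means equal", {
  fr <- simFrame(1970:2019)   # 40 pre years, 10 post
  s <- generateSurfaces(fr, seed = 13, preyRegimeShift = 0)
  prey <- assay(s, "prey")
  yrs <- stepYear(fr, seq_len(nSteps(fr)))
  pre <- mean(prey[, yrs < 2010]); post <- mean(prey[, yrs >= 2010])
  expect_equal(post / pre, 1, tolerance = 0.15)
  # and the default shift really reduces post-break prey
  sShift <- generateSurfaces(fr, seed = 13, preyRegimeShift = 0.35)
  preyS <- assay(sShift, "prey")
  expect_lt(mean(preyS[, yrs >= 2010]) / mean(preyS[, yrs < 2010]), 0.85)
})

test_that("the configured traffic trend is recovered from the realized field", {
  fr <- simFrame(1970:2019)
  s <- generateSurfaces(fr, seed = 21, trafficTrend = 0.02)
  ais <- assay(s, "AIS")
  yrs <- stepYear(fr, seq_len(nSteps(fr)))
  annual <- tapply(colMeans(ais), yrs, mean)
  slope <- unname(coef(lm(log(annual) ~ as.numeric(names(annual))))[2])
  expect_lt(abs(slope - 0.02), 0.005)
})

test_that("frozen dynamics leave the population constant with no events", {
  fr <- simFrame(2010:2019)
  par <- simulationParameters(
    iota1 = 0, iota2 = 0,
    vital = vitalRateParameters(aS = -50, bS = 0, c0 = -50))
  s <- generateSurfaces(fr, seed = 2)
  truth <- generatePopulation(fr, s, par, nInitial = 15, seed = 2)
  expect_equal(nrow(truth$individuals), 15L)
  expect_true(all(is.na(truth$individuals$deathStep)))
  expect_equal(nrow(truth$entanglements), 0L)
  expect_equal(nrow(truth$strikes), 0L)
  expect_true(all(vapply(truth$trajectories, nrow, 1L) == nSteps(fr)))
})

test_that("doubling the entanglement coefficient doubles the event rate", {
  fr <- simFrame(1995:2019)
  rate <- sapply(c(0.075, 0.15), function(i1) {
    par <- simulationParameters(iota1 = i1)
    truth <- generatePopulation(fr, generateSurfaces(fr, seed = 4), par,
                                nInitial = 60, seed = 4)
    steps <- sum(vapply(truth$trajectories, nrow, 1L))
    c(events = nrow(truth$entanglements), steps = steps)
  })
  expect_gt(rate["events", 2], 200)   # enough events for the ratio check
  ratio <- (rate["events", 2] / rate["steps", 2]) /
    (rate["events", 1] / rate["steps", 1])
  expect_gt(ratio, 1.7); expect_lt(ratio, 2.3)
})

test_that("a mother's entanglement during lactation lowers calf asymptotes", {
  fr <- simFrame(1990:2019)
  par <- simulationParameters(
    iota1 = 0.35,
    growth = growthParameters(betaA = c(motherEnt = -0.8,
                                        motherHealthStart = 0)))
  truth <- generatePopulation(fr, generateSurfaces(fr, seed = 6), par,
                              nInitial = 80, seed = 6)
  calves <- truth$individuals[!is.na(truth$individuals$motherEnt), ]
  exposed <- calves$A[calves$motherEnt == 1]
  unexposed <- calves$A[calves$motherEnt == 0]
  expect_gt(length(exposed), 5)
  expect_equal(mean(exposed) - mean(unexposed), -0.8, tolerance = 0.45)
})

test_that("observation masking honors detection, noise and recovery settings", {
  fr <- simFrame(2012:2019)
  # certain detection: every alive step is a sighting
  par1 <- simulationParameters(
    obs = observationParameters(pDetect = 1, nRegions = 3L), pVha = 0,
    pLength = 1)
  truth <- generatePopulation(fr, generateSurfaces(fr, seed = 3), par1,
                              nInitial = 12, seed = 3)
  masked <- generateObservations(fr, truth, par1, seed = 3)
  aliveSteps <- sum(vapply(truth$trajectories, nrow, 1L))
  expect_equal(nrow(obsStream(masked$observations, "sightings")), aliveSteps)
  # near-zero measurement noise reproduces the latent lengths
  par2 <- simulationParameters(
    obs = observationParameters(pDetect = 1, nRegions = 3L,
                                sigmaP = c(aircraft = 1e-9, drone = 1e-9)),
    pVha = 0, pLength = 1)
  masked2 <- generateObservations(fr, truth, par2, seed = 4)
  len <- obsStream(masked2$observations, "lengths")
  trueL <- mapply(function(id, t) {
    tr <- truth$trajectories[[id]]; tr$L[match(t, tr$t)]
  }, len$id, len$t)
  expect_equal(len$length, unname(trueL), tolerance = 1e-6)
})

test_that("event detection thins true events binomially", {
  fr <- simFrame(1995:2019)
  par <- simulationParameters(
    iota1 = 0.2,
    obs = observationParameters(pDetectEnt = 0.5, nRegions = 3L), pVha = 0)
  truth <- generatePopulation(fr, generateSurfaces(fr, seed = 10), par,
                              nInitial = 30, seed = 10)
  masked <- generateObservations(fr, truth, par, seed = 10)
  nTrue <- nrow(truth$entanglements)
  nObs <- nrow(obsStream(masked$observations, "entanglements"))
  expect_gt(nTrue, 100)
  expect_equal(nObs / nTrue, 0.5, tolerance = 3 * sqrt(0.25 / nTrue) + 0.02)
})
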