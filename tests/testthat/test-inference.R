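test_that("model specifications enforce formulation/hypothesis compatibility", {
  expect_s4_class(modelSpec("v1", "gearPrey"), "ModelSpec")
  expect_s4_class(modelSpec("v3", "prolongedHealth"), "ModelSpec")
  # exposure-level combined effects need a spatial formulation
  expect_error(modelSpec("v3", "distEnt"), "spatial formulation")
  expect_error(modelSpec("v3", "preyEntRisk"), "spatial formulation")
  # prolonged-health-on-length only in the non-spatial version
  expect_error(modelSpec("v1", "prolongedHealth"), "non-spatial")
  expect_error(modelSpec("v4", "none"), "formulation")
})

test_that("the joint density equals the hand-composed sum of components", {
  healthPar <- healthParameters(sigmaH = 2, deltaGear = -2, betaPrey = 1)
  vitalPar <- vitalRateParameters(aS = -2, bS = 0.04)
  obsPar <- observationParameters(pDetect = 0.3, nRegions = 2L)
  T <- 8
  h <- c(70, 68, 69, 64, 65, 63, 62, 60)
  gear <- c(0, 0, 0, 1, 1, 0, 0, 0)
  summer <- c(0, 0, 1, 0, 0, 0, 1, 0)
  preyStd <- -0.5
  drifts <- sapply(2:T, function(t)
    as.numeric(healthDrift(list(summer = summer[t] == 1),
                           list(carryingGear = gear[t] == 1), preyStd, healthPar)))
  surv <- rep(1, T)
  vhaRows <- data.frame(t = c(2L, 5L), variable = c(1L, 2L), score = c(3L, 2L))
  lengthRows <- data.frame(t = 4L, P = 12.1, L = 12.0, platform = "drone")
  seen <- c(1, 1, 0, 0, 1, 0, 0, 1)
  z <- matrix(0.5, T, 2)
  quarters <- rep(1:4, 2)

  joint <- jointLogDensity(h, drifts, surv, vhaRows, lengthRows, seen, z,
                           quarters, healthPar, vitalPar, obsPar)
  # independent composition, term by term
  manual <- healthLoglik(h, drifts, healthPar) +
    sum(log(survivalProbability(h, vitalPar))) +
    vhaLoglik(3, h[2], 1, obsPar) + vhaLoglik(2, h[5], 2, obsPar) +
    lengthMeasurementLoglik(12.1, 12.0, "drone", obsPar) +
    sum(ifelse(seen == 1, log(0.3), log(0.7)))
  expect_equal(joint, manual, tolerance = 1e-12)
})

test_that("MCMC reproduces a conjugate-normal posterior and is seed-deterministic", {
  model <- "
model {
  for (i in 1:n) { y[i] ~ dnorm(mu, 1) }
  mu ~ dnorm(0, 1)
}
"
  set.seed(14)
  y <- rnorm(40, 1.3, 1)
  dat <- list(y = y, n = length(y))
  fit <- runMCMC(model, dat, "mu", chains = 2, iterations = 2000,
                 warmup = 500, seed = 99)
  postMean <- sum(y) / (length(y) + 1)   # conjugate algebra
  postSD <- sqrt(1 / (length(y) + 1))
  draws <- as.matrix(fit$samples)[, "mu"]
  expect_equal(mean(draws), postMean, tolerance = 4 * postSD / sqrt(400))
  expect_equal(sd(draws), postSD, tolerance = 0.25 * postSD)
  expect_true(fit$converged)
  expect_true(all(c("parameter", "rhat", "ess") %in% names(fit$diagnostics)))
  # determinism under the same seed
  fit2 <- runMCMC(model, dat, "mu", chains = 2, iterations = 2000,
                  warmup = 500, seed = 99)
  expect_identical(as.matrix(fit$samples), as.matrix(fit2$samples))
})

test_that("slow-mixing runs are flagged as non-converged", {
  # a long random walk observed once at each end, chains started in opposite
  # corners and run far too briefly
  model <- "
model {
  h[1] ~ dunif(0, 100)
  for (t in 2:150) { h[t] ~ dnorm(h[t - 1], 4) }
  y1 ~ dnorm(h[1], 4)
  y2 ~ dnorm(h[150], 4)
}
"
  dat <- list(y1 = 20, y2 = 80)
  inits <- list(list(h = rep(20, 150)), list(h = rep(80, 150)))
  fit <- runMCMC(model, dat, "h[75]", inits = inits, chains = 2,
                 iterations = 30, warmup = 10, seed = 5)
  expect_false(fit$converged)
  expect_true(any(fit$diagnostics$rhat > 1.1, na.rm = TRUE))
})

test_that("interaction summaries report sign and zero-overlap as published", {
  set.seed(21)
  draws <- cbind(pos = rnorm(4000, 0.5, 0.1), sym = rnorm(4000, 0, 0.2))
  fit <- coda::mcmc.list(coda::mcmc(draws))
  s <- summarizeInteractions(fit)
  expect_equal(s$sign, c("+", ifelse(s$median[2] > 0, "+", "-")))
  expect_false(s$overlapsZero[1])
  expect_true(s$overlapsZero[2])
  expect_lt(abs(s$median[2]), 0.02)
  # quantile oracle for Normal(0.5, 0.1): 95% CI about (0.304, 0.696)
  expect_equal(s$lower95[1], 0.304, tolerance = 0.02)
  expect_equal(s$upper95[1], 0.696, tolerance = 0.02)
  expect_error(summarizeInteractions(fit, "nope"), "unknown parameter")
})

test_that("prepared model arrays are invariant to observation row order", {
  sim <- smallSim()
  spec <- modelSpec("v1", "gearPrey")
  p1 <- prepareModelData(sim, spec)
  sim2 <- sim
  set.seed(9)
  for (s in c("sightings", "vha", "entanglements", "strikes")) {
    df <- obsStream(sim2$observations, s)
    slot(sim2$observations, s) <- df[sample(nrow(df)), , drop = FALSE]
  }
  p2 <- prepareModelData(sim2, spec)
  expect_equal(p1$gear, p2$gear)
  expect_equal(p1$sev, p2$sev)
  expect_equal(p1$surv, p2$surv)
  expect_equal(p1$preyStd, p2$preyStd)
  o1 <- p1$vha[order(p1$vha$n, p1$vha$t, p1$vha$variable), ]
  o2 <- p2$vha[order(p2$vha$n, p2$vha$t, p2$vha$variable), ]
  expect_equal(o1$score, o2$score)
})

test_that("v1 and v2 give identical exposure when their occupancies coincide", {
  # when the density surface reproduces the Dirichlet mean composition the
  # two formulations must agree exactly at the exposure level
  fr <- tinyFrame()
  R <- nRegions(fr); T <- nSteps(fr)
  alpha <- array(rep(c(4, 2, 2), each = 4 * 4 * 2), c(4, 4, 2, R),
                 dimnames = list(DEMOGRAPHIC_CLASSES, quarterLabels(fr),
                                 c("pre", "post"), regionLabels(fr)))
  m <- new("DirichletOccupancyModel", alpha = alpha,
           classes = DEMOGRAPHIC_CLASSES, frame = fr,
           nObs = array(10L, c(4, 4, 2)))
  occ1 <- occupancyV1All(m)
  DSM <- matrix(c(4, 2, 2) / 8, R, T)
  s <- RegionalSurfaces(fr, G = matrix(0.4, R, T), entScalar = matrix(1, R, T),
                        AIS = matrix(0.3, R, T), prey = matrix(2, R, T),
                        DSM = DSM)
  props <- array(1, c(4, 4, R),
                 dimnames = list(DEMOGRAPHIC_CLASSES, quarterLabels(fr), NULL))
  occ2 <- occupancyV2(s, props, dsmStartYear = min(frameYears(fr)))
  e1 <- exposureTable(occ1, s, iota1 = 0.1, iota2 = 0.2, vTrend = 0.05)
  e2 <- exposureTable(occ2, s, iota1 = 0.1, iota2 = 0.2, vTrend = 0.05)
  expect_equal(e1$pEnt, e2$pEnt, tolerance = 1e-12)
  expect_equal(e1$pStrike, e2$pStrike, tolerance = 1e-12)
  expect_equal(e1$preyW, e2$preyW, tolerance = 1e-12)
})

test_that("a small end-to-end fit runs to completion with sensible estimates", {
  sim <- smallSim()
  fit <- fitHealthSurvival(sim, modelSpec("v1", "gearPrey"),
                           obsPar = observationParameters(nRegions = 3L),
                           chains = 1, iterations = 200, warmup = 200,
                           seed = 3)
  expect_true(all(c("gammaGearPrey", "deltaGear", "bS", "sigmaH") %in%
                    rownames(fit$summary)))
  # adverse gear effect estimated negative; health-survival slope positive
  expect_lt(fit$summary["deltaGear", "median"], 0)
  expect_gt(fit$summary["bS", "median"], 0)
  expect_true(all(fit$summary[, "lower95"] <= fit$summary[, "upper95"]))
})
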