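test_that("health is unchanged with no events, no covariates, zero noise", {
  p <- healthParameters()
  expect_equal(healthStep(70, list(), list(), 0, p, noise = 0), 70)
})

test_that("a new entanglement composes immediate, prolonged and interaction terms", {
  # delta_sev[severe] = -20, gamma_sev_prey[severe] = +3, prey_std = -1,
  # delta_gear = -2, gamma_gear_prey = +1:
  # (-20 + 3*(-1)) + (-2 + 1*(-1)) = -26
  p <- healthParameters(
    deltaSev = c(minor = -2, moderate = -8, severe = -20),
    deltaGear = -2,
    gammaSevPrey = c(minor = 0, moderate = 0, severe = 3),
    gammaGearPrey = 1,
    activeInteraction = c("sevPrey", "gearPrey"))
  d <- healthDrift(list(), list(newEntanglement = "severe"), preyStd = -1, p)
  expect_equal(as.numeric(d), -26)
  comp <- attr(d, "components")
  expect_equal(unname(comp["entanglement"]), -23)
  expect_equal(unname(comp["gear"]), -3)
  # the first event step carries one step of the prolonged effect;
  # later carrying steps carry only the prolonged effect
  dCarry <- healthDrift(list(), list(carryingGear = TRUE), preyStd = -1, p)
  expect_equal(as.numeric(dCarry), -3)
})

test_that("the clamp floor binds and the ceiling caps", {
  p <- healthParameters(deltaSev = c(minor = -2, moderate = -8, severe = -30))
  h <- healthStep(5, list(), list(newEntanglement = "severe"), 0, p, noise = 0)
  expect_equal(h, p$floor)
  expect_equal(healthStep(99, list(), list(), 0, p, noise = 50), 100)
  expect_error(healthStep(150, list(), list(), 0, p), "outside")
})

test_that("prior-event features count strictly-before events with an 8-step window", {
  expect_equal(eventHistoryFeatures(integer(0), 30),
               list(nPrior = 0L, anyPrior = 0L, anyPrior2yr = 0L))
  # events at t-3 and t-20: two prior, one within the window
  f <- eventHistoryFeatures(c(10, 27), 30)
  expect_equal(f, list(nPrior = 2L, anyPrior = 1L, anyPrior2yr = 1L))
  # inclusive boundary: exactly 8 steps before still counts
  expect_equal(eventHistoryFeatures(22, 30)$anyPrior2yr, 1L)
  expect_equal(eventHistoryFeatures(21, 30)$anyPrior2yr, 0L)
  # an event at t itself is not "prior"
  expect_equal(eventHistoryFeatures(30, 30)$nPrior, 0L)
})

test_that("prior-entanglement modifiers only act on a new event under the active variant", {
  p <- healthParameters(gammaPrior2yr = -4, activeInteraction = "prior2yr",
                        deltaSev = c(minor = -2, moderate = -8, severe = -20),
                        deltaGear = 0)
  hist <- list(nPrior = 2L, anyPrior = 1L, anyPrior2yr = 1L)
  dNew <- healthDrift(list(), list(newEntanglement = "minor", history = hist), 0, p)
  expect_equal(as.numeric(dNew), -2 - 4)
  # inactive variants contribute nothing
  pOff <- healthParameters(gammaPrior2yr = -4, activeInteraction = "none",
                           deltaGear = 0)
  dOff <- healthDrift(list(), list(newEntanglement = "minor", history = hist), 0, pOff)
  expect_equal(as.numeric(dOff), -2)
})

test_that("prey affects health only in the summer step", {
  p <- healthParameters(betaPrey = 1.5)
  expect_equal(as.numeric(healthDrift(list(summer = TRUE), list(), -2, p)), -3)
  expect_equal(as.numeric(healthDrift(list(summer = FALSE), list(), -2, p)), 0)
})

test_that("with no stressors the walk has mean-zero increments", {
  p <- healthParameters(sigmaH = 1)
  set.seed(99)
  n <- 10000L
  h <- numeric(n + 1); h[1] <- 50
  for (i in seq_len(n))
    h[i + 1] <- healthStep(h[i], list(), list(), 0, p, noise = rnorm(1, 0, 1))
  inc <- diff(h)
  clamped <- h[-1] %in% c(p$floor, p$ceiling)
  tt <- t.test(inc[!clamped])
  expect_gt(tt$p.value, 0.001)
})

test_that("trajectory log-likelihood matches truncated-Gaussian algebra", {
  p <- healthParameters(sigmaH = 2)
  h <- c(70, 71, 69.5, 70.2)
  drifts <- rep(0, 3)
  ll <- healthLoglik(h, drifts, p)
  # independent evaluation
  mu <- h[1:3]
  man <- sum(dnorm(h[2:4], mu, 2, log = TRUE) -
               log(pnorm(100, mu, 2) - pnorm(0.01, mu, 2)))
  expect_equal(ll, man, tolerance = 1e-12)
  # doubling sigma changes the density by the closed-form scale adjustment
  p2 <- healthParameters(sigmaH = 4)
  man2 <- sum(dnorm(h[2:4], mu, 4, log = TRUE) -
                log(pnorm(100, mu, 4) - pnorm(0.01, mu, 4)))
  expect_equal(healthLoglik(h, drifts, p2), man2, tolerance = 1e-12)
  expect_error(healthLoglik(c(70, 150), 0, p), "outside")
})

test_that("parameter validation enforces the sign conventions", {
  expect_error(healthParameters(deltaGear = 1), "adverse")
  expect_error(healthParameters(sigmaH = -1))
  expect_error(healthParameters(activeInteraction = "gearXmoon"),
               "unknown interaction")
})
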