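test_that("entanglement probability follows the occupancy-weighted risk", {
  # hand arithmetic: 0.1 * (0.5*0.2 + 0.5*0.4) = 0.03
  expect_equal(entanglementProbability(c(0.5, 0.5), c(0.2, 0.4), c(1, 1), 0.1),
               0.03)
  # occupancy concentrated on a zero-risk region
  expect_equal(entanglementProbability(c(1, 0), c(0, 0.9), c(1, 1), 0.2), 0)
  # linear in the backcast scalar
  p1 <- entanglementProbability(c(0.3, 0.7), c(0.2, 0.4), c(0.8, 1.2), 0.1)
  p2 <- entanglementProbability(c(0.3, 0.7), c(0.2, 0.4), 2 * c(0.8, 1.2), 0.1)
  expect_equal(p2, 2 * p1)
  # out-of-support combination errors rather than clipping
  expect_error(entanglementProbability(c(1, 0), c(1, 0), c(20, 1), 0.1), "> 1")
})

test_that("regional strike probability is anchored at the reference year", {
  # identity at the reference year
  expect_equal(regionalStrikeProbability(c(0.2, 0.7), 0.3, 0.05, 2019),
               0.3 * c(0.2, 0.7))
  # independent evaluation of logit^-1(logit(0.1) + 1.0)
  got <- regionalStrikeProbability(0.5, 0.2, 0.05, 1999)
  expect_equal(got, 1 / (1 + exp(-(log(0.1 / 0.9) + 0.05 * 20))),
               tolerance = 1e-12)
  expect_equal(round(got, 4), 0.232)
  # zero trend: constant over years
  expect_equal(regionalStrikeProbability(0.4, 0.2, 0, 1975),
               regionalStrikeProbability(0.4, 0.2, 0, 2019))
  # zero risk maps to zero (limit convention)
  expect_equal(regionalStrikeProbability(c(0, 0.5), 0.2, 0.1, 2000)[1], 0)
  expect_error(regionalStrikeProbability(1, 1, 0.1, 2000), "logit undefined")
})

test_that("individual strike probability is a convex combination", {
  expect_equal(individualStrikeProbability(c(1, 0), c(0.07, 0.9)), 0.07)
  expect_equal(individualStrikeProbability(c(0.5, 0.5), c(0.02, 0.04)), 0.03)
  # constant field: value independent of occupancy
  set.seed(3)
  for (i in 1:25) {
    z <- randomSimplex(5)
    expect_equal(individualStrikeProbability(z, rep(0.123, 5)), 0.123)
    pr <- runif(5)
    p <- individualStrikeProbability(z, pr)
    expect_gte(p, min(pr) - 1e-12); expect_lte(p, max(pr) + 1e-12)
  }
})

test_that("prey weighting and annual standardization behave", {
  expect_equal(individualPreyIndex(c(1, 0, 0), c(3.2, 9, 9)), 3.2)
  std <- annualizeAndStandardize(c(1, 2, 3), c(2001, 2002, 2003))
  expect_equal(unname(std$annual), c(-1, 0, 1))
  expect_error(annualizeAndStandardize(c(2, 2), c(2001, 2002)),
               "degenerate standardization")
  # population constants reused give identical series for identical inputs
  std2 <- annualizeAndStandardize(c(1, 2, 3), c(2001, 2002, 2003),
                                  constants = std$constants)
  expect_equal(std2$annual, std$annual)
})

test_that("landings backcast scalars are 1 in the baseline and scale linearly", {
  fr <- tinyFrame()
  landings <- expand.grid(year = 2006:2014, group = c("south", "north"))
  landings$landings <- ifelse(landings$group == "north", 100, 50)
  landings$landings[landings$year == 2006 & landings$group == "north"] <- 50
  groups <- c(A = "south", B = "south", C = "north")
  e <- backcastEntanglementScalars(landings, groups,
                                   baselineYears = 2010:2014, frame = fr)
  # baseline-period scalar is 1 by construction
  expect_equal(unname(e["C", stepIndex(fr, 2012, 1)]), 1)
  # landings half the baseline mean -> 0.5
  expect_equal(unname(e["C", stepIndex(fr, 2006, 1)]), 0.5)
  # constant series -> identically 1
  expect_true(all(e["A", ] == 1))
})

test_that("Canadian risk extrapolation scales northern-US totals by landings", {
  fr <- StudyFrame(regions = c("NEUS", "CCB", "SNE", "GSL"), years = 2010:2011,
                   eraBreakYear = 2010L)
  G <- matrix(c(1, 2, 3, 0), 4, 8, dimnames = list(regionLabels(fr), NULL))
  lc <- expand.grid(region = "GSL", year = 2010:2011)
  lus <- data.frame(year = 2010:2011, landings = c(100, 100))
  lc$landings <- c(100, 10)
  out <- extrapolateCanadianEntanglement(G, fr, lc, lus,
                                         northernUS = c("NEUS", "CCB", "SNE"),
                                         fillRegions = "GSL")
  expect_equal(unname(out["GSL", stepIndex(fr, 2010, 1)]), 6)      # ratio 1 -> total
  expect_equal(unname(out["GSL", stepIndex(fr, 2011, 1)]), 0.6)    # ratio 0.1
  lc$landings <- c(0, 0)
  out0 <- extrapolateCanadianEntanglement(G, fr, lc, lus, fillRegions = "GSL")
  expect_true(all(out0["GSL", ] == 0))
})

test_that("prey backcast recovers a noiseless log-linear relationship", {
  anomaly <- setNames(seq(-2, 2, length.out = 21), 1999:2019)
  index <- exp(1 + 0.5 * anomaly)
  pre <- setNames(rnorm(5), 1994:1998)
  fit <- backcastPrey(index, c(pre, anomaly), predictYears = 1994:1998)
  expect_equal(fit$a, 1, tolerance = 1e-6)
  expect_equal(fit$b, 0.5, tolerance = 1e-6)
  expect_equal(unname(fit$predicted), unname(exp(1 + 0.5 * pre)),
               tolerance = 1e-6)
  # prediction at the overlap-mean anomaly equals the fitted geometric level
  fitM <- backcastPrey(index, c(setNames(mean(anomaly), 1998), anomaly), 1998)
  expect_equal(unname(fitM$predicted), exp(fitM$a + fitM$b * mean(anomaly)))
  expect_error(backcastPrey(index, setNames(rep(1, 21), 1999:2019), 1998),
               "constant over the overlap")
  expect_error(backcastPrey(c(`1999` = -1, index[-1]), anomaly, 1998),
               "strictly positive")
})

test_that("exposure probabilities stay valid across the prior support", {
  # 10^4 random draws within supports: all probabilities in [0, 1]
  set.seed(11)
  n <- 10000L
  bad <- 0L
  for (i in seq_len(n)) {
    R <- sample(2:7, 1)
    z <- randomSimplex(R)
    G <- runif(R); eSc <- runif(R, 0, 1.5)
    iota1 <- runif(1, 0, 1 / max(1e-9, max(G * eSc)))
    pe <- entanglementProbability(z, G, eSc, iota1)
    AIS <- runif(R)
    iota2 <- runif(1, 0, 0.99 / max(max(AIS), 1e-9))
    pr <- regionalStrikeProbability(AIS, iota2, runif(1, -0.1, 0.1),
                                    sample(1970:2019, 1))
    pv <- individualStrikeProbability(z, pr)
    if (pe < 0 || pe > 1 || pv < 0 || pv > 1 || any(pr < 0) || any(pr > 1))
      bad <- bad + 1L
  }
  expect_identical(bad, 0L)
})

test_that("entanglement probability is monotone in risk, scalar and iota1", {
  set.seed(4)
  for (i in 1:50) {
    R <- 4
    z <- randomSimplex(R); G <- runif(R); eSc <- runif(R, 0.5, 1.5)
    i1 <- runif(1, 0, 0.3)
    base <- entanglementProbability(z, G, eSc, i1)
    Gup <- pmin(G + runif(R, 0, 1 - max(G)), 1)
    expect_gte(entanglementProbability(z, Gup, eSc, i1), base)
    expect_gte(entanglementProbability(z, G, eSc * 1.1, i1), base)
    expect_gte(entanglementProbability(z, G, eSc, i1 * 1.05), base)
  }
})
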