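test_that("Dirichlet MLE recovers the generating mean composition", {
  set.seed(101)
  alpha <- c(2, 5, 3)
  comps <- rDirichlet(500, alpha)
  ahat <- fitDirichlet(comps)
  expect_equal(ahat / sum(ahat), alpha / sum(alpha), tolerance = 0.03)
  # symmetry: swapping two exchangeable components gives equal concentrations
  set.seed(102)
  comps2 <- rDirichlet(2000, c(4, 4, 1))
  ahat2 <- fitDirichlet(comps2)
  expect_lt(abs(ahat2[1] - ahat2[2]) / mean(ahat2[1:2]), 0.15)
})

test_that("mean-composition error shrinks as the sample grows", {
  alpha <- c(1.5, 3, 2.5)
  err <- sapply(c(50, 500), function(n) {
    set.seed(7)
    ahat <- fitDirichlet(rDirichlet(n, alpha))
    max(abs(ahat / sum(ahat) - alpha / sum(alpha)))
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.03)
})

test_that("degenerate vertex strata fall back with a warning, not an error", {
  comps <- matrix(rep(c(0, 0, 1), each = 12), ncol = 3)
  expect_warning(a <- fitDirichlet(comps), "degenerate")
  expect_gt((a / sum(a))[3], 0.95)
})

test_that("v1 occupancy returns the stratum Dirichlet mean and routes eras", {
  sim <- smallSim()
  model <- fitDirichletOccupancy(sim$observations, sim$individuals, sim$frame)
  # mean formula alpha / sum(alpha)
  a <- model@alpha["adult female", 2, 1, ]
  expect_equal(occupancyV1(model, "adult female", stepIndex(sim$frame, 2005, 2)),
               a / sum(a), ignore_attr = TRUE)
  # symmetric prior stratum (no data) gives the uniform simplex
  fresh <- model
  fresh@alpha["calf", 1, 1, ] <- rep(1, 3)
  expect_equal(unname(occupancyV1(fresh, "calf", stepIndex(sim$frame, 2005, 1))),
               rep(1 / 3, 3), ignore_attr = TRUE)
  # pre and post era draw from different strata
  zPre <- occupancyV1(model, "adult female", stepIndex(sim$frame, 2009, 3))
  zPost <- occupancyV1(model, "adult female", stepIndex(sim$frame, 2012, 3))
  aPre <- model@alpha["adult female", 3, 1, ]
  aPost <- model@alpha["adult female", 3, 2, ]
  expect_equal(unname(zPre), unname(aPre / sum(aPre)), ignore_attr = TRUE)
  expect_equal(unname(zPost), unname(aPost / sum(aPost)), ignore_attr = TRUE)
})

test_that("perturbing post-era data never changes pre-era estimates", {
  sim <- smallSim()
  m1 <- fitDirichletOccupancy(sim$observations, sim$individuals, sim$frame)
  obs2 <- sim$observations
  sg <- obsStream(obs2, "sightings")
  post <- stepYear(sim$frame, sg$t) >= 2010
  sg$region[post] <- sample(regionLabels(sim$frame), sum(post), replace = TRUE)
  obs2@sightings <- sg
  m2 <- fitDirichletOccupancy(obs2, sim$individuals, sim$frame)
  expect_equal(m1@alpha[, , 1, ], m2@alpha[, , 1, ], tolerance = 1e-12)
})

test_that("every emitted occupancy is a simplex", {
  sim <- smallSim()
  model <- fitDirichletOccupancy(sim$observations, sim$individuals, sim$frame)
  occ <- occupancyV1All(model)
  sums <- apply(occ@z, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(occ@z >= 0))
  # sampled compositions are simplices too
  set.seed(1)
  for (i in 1:20) {
    z <- occupancyV1(model, "juvenile", i, draw = TRUE)
    expect_equal(sum(z), 1, tolerance = 1e-9)
    expect_true(all(z >= 0))
  }
})

test_that("v2 occupancy normalizes density times class proportions", {
  fr <- tinyFrame()
  R <- nRegions(fr); T <- nSteps(fr)
  mk <- function(DSM) RegionalSurfaces(fr, G = matrix(0.5, R, T),
    entScalar = matrix(1, R, T), AIS = matrix(0.5, R, T),
    prey = matrix(1, R, T), DSM = DSM)
  props <- array(1, c(4, 4, R),
                 dimnames = list(DEMOGRAPHIC_CLASSES, quarterLabels(fr), NULL))
  # uniform density, uniform proportions -> uniform z
  occU <- occupancyV2(mk(matrix(1, R, T)), props, dsmStartYear = 2006L)
  expect_true(all(abs(occU@z - 1 / R) < 1e-12))
  # hand-normalized: density (2, 1, 1) -> z = (0.5, 0.25, 0.25)
  occ2 <- occupancyV2(mk(matrix(c(2, 1, 1), R, T)), props, dsmStartYear = 2006L)
  expect_equal(unname(occ2@z[5, 1, ]), c(0.5, 0.25, 0.25))
})

test_that("v2 backfills pre-density years with the reference-period mean", {
  fr <- StudyFrame(regions = c("A", "B", "C"), years = 1995:2013,
                   eraBreakYear = 2010L)
  R <- 3; T <- nSteps(fr)
  yrs <- stepYear(fr, seq_len(T))
  DSM <- matrix(1, R, T)
  sel <- yrs >= 2003 & yrs <= 2009
  DSM[, sel] <- c(3, 2, 1)      # reference period pattern
  DSM[, yrs > 2009] <- c(1, 1, 8)
  s <- RegionalSurfaces(fr, G = matrix(0.5, R, T), entScalar = matrix(1, R, T),
                        AIS = matrix(0.5, R, T), prey = matrix(1, R, T),
                        DSM = DSM)
  props <- array(1, c(4, 4, R),
                 dimnames = list(DEMOGRAPHIC_CLASSES, quarterLabels(fr), NULL))
  occ <- occupancyV2(s, props)
  t1995 <- stepIndex(fr, 1995, 2)
  t2005 <- stepIndex(fr, 2005, 2)
  expect_equal(occ@z[t1995, 1, ], occ@z[t2005, 1, ])
  expect_equal(unname(occ@z[t1995, 1, ]), c(3, 2, 1) / 6)
})

test_that("v2 errors on an all-zero weight row, naming class and step", {
  fr <- tinyFrame(); R <- 3; T <- nSteps(fr)
  DSM <- matrix(1, R, T); DSM[, 3] <- 0
  s <- RegionalSurfaces(fr, G = matrix(0.5, R, T), entScalar = matrix(1, R, T),
                        AIS = matrix(0.5, R, T), prey = matrix(1, R, T),
                        DSM = DSM)
  props <- array(1, c(4, 4, R),
                 dimnames = list(DEMOGRAPHIC_CLASSES, quarterLabels(fr), NULL))
  expect_error(occupancyV2(s, props, dsmStartYear = 2006L), "all-zero.*step 3")
})

test_that("uncovered-region densities follow the sightings-to-abundance ratio", {
  DSM <- matrix(c(10, 0, 0), 3, 4, dimnames = list(c("NEUS", "GSL", "MAR"), NULL))
  counts <- matrix(c(5, 2, 1), 3, 4, dimnames = dimnames(DSM))
  out <- dsmFillUncovered(DSM, counts, refRegion = "NEUS",
                          fillRegions = c("GSL", "MAR"))
  expect_equal(unname(out["GSL", 1]), 2 * 10 / 5)
  expect_equal(unname(out["MAR", 1]), 1 * 10 / 5)
})
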