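# Shared fixtures, built lazily and cached for the session.

.fixtureEnv <- new.env(parent = emptyenv())

# tiny 3-region, 8-year frame for fast structural tests
tinyFrame <- function() StudyFrame(regions = c("A", "B", "C"),
                                   years = 2006:2013, eraBreakYear = 2010L)

# small complete surfaces on the tiny frame, deterministic
tinySurfaces <- function() {
  fr <- tinyFrame()
  R <- nRegions(fr); T <- nSteps(fr)
  base <- outer(1:R, 1 + 0.5 * sin(2 * pi * (1:T) / 4))
  RegionalSurfaces(fr,
    G = base / max(base), entScalar = matrix(1, R, T),
    AIS = 0.5 * base / max(base), prey = base,
    DSM = base / rep(colSums(base), each = R))
}

# one cached desk-scale simulated dataset reused by several test files
smallSim <- function() {
  if (is.null(.fixtureEnv$sim)) {
    .fixtureEnv$sim <- simulateDataset(
      frame = simFrame(2004:2019),
      params = simulationParameters(pVha = 0.3, pLength = 0.25),
      nInitial = 20L, seed = 42L)
  }
  .fixtureEnv$sim
}

randomSimplex <- function(k) {
  g <- rgamma(k, 1)
  g / sum(g)
}
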