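#' Scenario specification for viability projections
#'
#' The projection levers: a multiplicative reduction of entanglement risk
#' (1 = status quo, 0 = risk removed), the prey regime (historical 1990–2009
#' variation vs the low post-2010 decade), the asymptotic-length regime
#' (continuing decline to a 10 m floor, stabilizing at the current ~11.8 m
#' mean, or recovering toward the ~14.0 m historical maximum), the horizon
#' and the number of parameter draws.  Vessel-strike levers are excluded from
#' the default grid but the multiplier slot exists.
#'
#' @slot entMultiplier entanglement-risk multiplier in `[0, 1]`.
#' @slot strikeMultiplier vessel-strike multiplier in `[0, 1]` (default 1).
#' @slot preyRegime `"historical"` or `"low"`.
#' @slot lengthRegime `"decline"`, `"stabilize"` or `"recover"`.
#' @slot horizonYears projection horizon (>= 1).
#' @slot nDraws number of stochastic draws.
#' @export
setClass("ScenarioSpec",
  representation(entMultiplier = "numeric", strikeMultiplier = "numeric",
                 preyRegime = "character", lengthRegime = "character",
                 horizonYears = "integer", nDraws = "integer"))

setValidity("ScenarioSpec", function(object) {
  msg <- character()
  if (object@entMultiplier < 0 || object@entMultiplier > 1)
    msg <- c(msg, "entMultiplier must lie in [0, 1]")
  if (object@strikeMultiplier < 0 || object@strikeMultiplier > 1)
    msg <- c(msg, "strikeMultiplier must lie in [0, 1]")
  if (!object@preyRegime %in% c("historical", "low"))
    msg <- c(msg, "preyRegime must be 'historical' or 'low'")
  if (!object@lengthRegime %in% c("decline", "stabilize", "recover"))
    msg <- c(msg, "lengthRegime must be 'decline', 'stabilize' or 'recover'")
  if (object@horizonYears < 1L) msg <- c(msg, "horizon must be >= 1 year")
  if (object@nDraws < 1L) msg <- c(msg, "need at least one draw")
  if (length(msg)) msg else TRUE
})

#' @describeIn ScenarioSpec-class Constructor.
#' @param entMultiplier,strikeMultiplier,preyRegime,lengthRegime,horizonYears,nDraws
#'   see slots.
#' @export
scenarioSpec <- function(entMultiplier = 1, strikeMultiplier = 1,
                         preyRegime = "historical",
                         lengthRegime = "stabilize",
                         horizonYears = 100L, nDraws = 1000L) {
  new("ScenarioSpec", entMultiplier = entMultiplier,
      strikeMultiplier = strikeMultiplier, preyRegime = preyRegime,
      lengthRegime = lengthRegime, horizonYears = as.integer(horizonYears),
      nDraws = as.integer(nDraws))
}

setMethod("show", "ScenarioSpec", function(object) {
  cat("ScenarioSpec: ent x", object@entMultiplier,
      "| prey", object@preyRegime, "| length", object@lengthRegime,
      "|", object@horizonYears, "yr x", object@nDraws, "draws\n")
})

#' Full factorial scenario grid
#'
#' Builds the cross of the supplied lever values; the demonstration grid
#' (`entMultipliers = c(1, 0.5, 0)`, both prey regimes, all three length
#' regimes) has 18 scenarios.
#'
#' @param entMultipliers numeric vector of entanglement multipliers.
#' @param preyRegimes character vector of prey regimes.
#' @param lengthRegimes character vector of length regimes.
#' @param horizonYears,nDraws shared across scenarios.
#' @return list of [ScenarioSpec] objects.
#' @export
scenarioGrid <- function(entMultipliers = c(1, 0.5, 0),
                         preyRegimes = c("historical", "low"),
                         lengthRegimes = c("decline", "stabilize", "recover"),
                         horizonYears = 100L, nDraws = 1000L) {
  if (!length(entMultipliers) || !length(preyRegimes) || !length(lengthRegimes))
    stop("every lever needs at least one value")
  g <- expand.grid(ent = entMultipliers, prey = preyRegimes,
                   len = lengthRegimes, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i)
    scenarioSpec(entMultiplier = g$ent[i], preyRegime = g$prey[i],
                 lengthRegime = g$len[i], horizonYears = horizonYears,
                 nDraws = nDraws))
}

#' Parameters of the forward population projection
#'
#' The projector replaces the fitted nonstationary health random walk with a
#' mean-reverting AR(1) anchored at the uninjured-health mean (the fitted
#' walk is unsuitable for forward prediction); survival is hazard-based with
#' additive annual hazards; calving depends on health and length; newborn
#' asymptotes follow the scenario's length-trend rule.
#'
#' @param vital a [vitalRateParameters()] list (annual hazard =
#'   4 x quarterly hazard).
#' @param healthMean,healthSD stationary mean and SD of uninjured health.
#' @param rho year-to-year health autocorrelation.
#' @param betaPreyAnnual effect of the standardized prey regime on the health
#'   mean.
#' @param preyHistorical,preyLow `(mean, sd)` of the standardized prey draw
#'   under each regime.
#' @param pEntAnnual annual entanglement probability before the scenario
#'   multiplier.
#' @param entEffect expected annual health decrement per entanglement.
#' @param pStrikeAnnual,strikeEffect same for strikes.
#' @param k,L0 growth-curve constants (per year, m).
#' @param currentMeanA,floorA,maxA asymptote anchors (m).
#' @param declineRate,recoverRate asymptote trend rates (m/yr).
#' @param sigmaACohort SD of individual asymptotes around the cohort mean.
#' @param maturityAge,maxAge demographic bounds (years).
#' @return a `pvaParameters` list.
#' @export
pvaParameters <- function(vital = vitalRateParameters(aS = -2.3, bS = 0.035,
                                                      c0 = -1.2, c1 = 0.04,
                                                      c2 = 0.8, LRef = 11.8),
                          healthMean = 75, healthSD = 8, rho = 0.7,
                          betaPreyAnnual = 2,
                          preyHistorical = c(0, 1), preyLow = c(-1, 0.5),
                          pEntAnnual = 0.12, entEffect = 12,
                          pStrikeAnnual = 0.01, strikeEffect = 15,
                          k = 0.25, L0 = 4.3,
                          currentMeanA = 11.8, floorA = 10, maxA = 14.0,
                          declineRate = 0.025, recoverRate = 0.025,
                          sigmaACohort = 0.3,
                          maturityAge = 9L, maxAge = 70L) {
  stopifnot(rho >= 0, rho < 1, healthSD > 0, pEntAnnual >= 0, pEntAnnual <= 1)
  p <- list(vital = vital, healthMean = healthMean, healthSD = healthSD,
            rho = rho, betaPreyAnnual = betaPreyAnnual,
            preyHistorical = preyHistorical, preyLow = preyLow,
            pEntAnnual = pEntAnnual, entEffect = entEffect,
            pStrikeAnnual = pStrikeAnnual, strikeEffect = strikeEffect,
            k = k, L0 = L0, currentMeanA = currentMeanA, floorA = floorA,
            maxA = maxA, declineRate = declineRate, recoverRate = recoverRate,
            sigmaACohort = sigmaACohort, maturityAge = as.integer(maturityAge),
            maxAge = as.integer(maxAge))
  class(p) <- "pvaParameters"
  p
}

#' Default initial population for projections
#'
#' A synthetic stand-in for the present-day population state: staggered ages,
#' even sex ratio, health around the uninjured mean, asymptotes around the
#' current mean length.
#'
#' @param n initial population size.
#' @param params a [pvaParameters()] list.
#' @param seed integer seed.
#' @return data.frame `(sex, age, h, A, lastCalving)`.
#' @export
defaultInitialPopulation <- function(n = 300L, params = pvaParameters(),
                                     seed = 1L) {
  set.seed(seed)
  data.frame(
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = sample(0:40, n, replace = TRUE,
                 prob = 0.97^(0:40)),
    h = pmin(pmax(rnorm(n, params$healthMean, params$healthSD), 1), 100),
    A = rnorm(n, params$currentMeanA, params$sigmaACohort),
    lastCalving = NA_integer_
  )
}

#' Projection results
#'
#' @slot sizes matrix `[draw, year]` of total population sizes (year 0 =
#'   initial state).
#' @slot classSizes array `[draw, year, class]` with classes calf, juvenile,
#'   adult.
#' @slot entEvents total entanglement events per draw (the scenario gate:
#'   identically zero under multiplier 0).
#' @slot scenario the [ScenarioSpec] projected.
#' @slot demonstration logical flag: projections are demonstration-grade and
#'   must not be used to inform management decisions.
#' @export
setClass("ProjectionResult",
  representation(sizes = "matrix", classSizes = "array",
                 entEvents = "numeric",
                 scenario = "ScenarioSpec", demonstration = "logical"))

setMethod("show", "ProjectionResult", function(object) {
  d <- dim(object@sizes)
  cat("ProjectionResult:", d[1], "draws x", d[2] - 1, "years",
      "(demonstration-grade)\n")
  fin <- object@sizes[, d[2]]
  cat("  final size median", median(fin), " [",
      quantile(fin, 0.025), ",", quantile(fin, 0.975), "]\n")
})

.cohortAsymptote <- function(params, regime, yearsAhead) {
  switch(regime,
    decline = pmax(params$floorA, params$currentMeanA -
                     params$declineRate * yearsAhead),
    stabilize = params$currentMeanA,
    recover = pmin(params$maxA, params$currentMeanA +
                     params$recoverRate * yearsAhead))
}

#' Project the population under a scenario
#'
#' Annual individual-based projection: health follows a mean-reverting AR(1)
#' around the prey-regime-adjusted uninjured mean; entanglement and strike
#' events (thinned by the scenario multipliers) subtract their health
#' effects; survival is drawn from the annual hazard
#' `4 * exp(aS - bS * h)`; available females calve with the health- and
#' length-dependent probability; newborn asymptotes follow the scenario's
#' length-trend rule.  One parameter draw per trajectory propagates
#' parameter uncertainty when `draws` is a list.
#'
#' @param draws a single [pvaParameters()] list (used for every trajectory)
#'   or a list of such lists of length `scenario@nDraws`.
#' @param scenario a [ScenarioSpec].
#' @param initial initial population data.frame (see
#'   [defaultInitialPopulation()]).
#' @param seed integer seed.
#' @return a [ProjectionResult].
#' @export
project <- function(draws, scenario, initial = NULL, seed = 1L) {
  single <- inherits(draws, "pvaParameters")
  if (!single && length(draws) != scenario@nDraws)
    stop("need one parameter draw per trajectory (",
         scenario@nDraws, "), got ", length(draws))
  if (is.null(initial))
    initial <- defaultInitialPopulation(params = if (single) draws else draws[[1]],
                                        seed = seed)
  H <- scenario@horizonYears
  nD <- scenario@nDraws
  sizes <- matrix(NA_real_, nD, H + 1L)
  entEvents <- numeric(nD)
  classSizes <- array(NA_real_, c(nD, H + 1L, 3L),
                      dimnames = list(NULL, NULL, c("calf", "juvenile", "adult")))
  set.seed(seed)
  drawSeeds <- sample.int(.Machine$integer.max %/% 2L, nD)
  for (d in seq_len(nD)) {
    set.seed(drawSeeds[d])
    p <- if (single) draws else draws[[d]]
    v <- p$vital
    pop <- initial
    sizes[d, 1L] <- nrow(pop)
    classSizes[d, 1L, ] <- c(sum(pop$age < 1), sum(pop$age >= 1 & pop$age < p$maturityAge),
                             sum(pop$age >= p$maturityAge))
    sigAR <- p$healthSD * sqrt(1 - p$rho^2)
    for (y in seq_len(H)) {
      if (!nrow(pop)) { sizes[d, y + 1L] <- 0; classSizes[d, y + 1L, ] <- 0; next }
      regime <- if (scenario@preyRegime == "historical") p$preyHistorical else p$preyLow
      preyStd <- rnorm(1, regime[1], regime[2])
      mu <- p$healthMean + p$betaPreyAnnual * preyStd
      pop$h <- pmin(pmax(mu + p$rho * (pop$h - mu) + rnorm(nrow(pop), 0, sigAR),
                         0.01), 100)
      # stressor events (annual), thinned by the scenario levers
      entHit <- rbinom(nrow(pop), 1, p$pEntAnnual * scenario@entMultiplier) == 1L
      entEvents[d] <- entEvents[d] + sum(entHit)
      pop$h[entHit] <- pmax(pop$h[entHit] - p$entEffect, 0.01)
      strHit <- rbinom(nrow(pop), 1, p$pStrikeAnnual * scenario@strikeMultiplier) == 1L
      pop$h[strHit] <- pmax(pop$h[strHit] - p$strikeEffect, 0.01)
      lambda <- 4 * exp(v$aS - v$bS * pop$h)
      survived <- rbinom(nrow(pop), 1, exp(-lambda)) == 1L
      pop <- pop[survived & pop$age < p$maxAge, , drop = FALSE]
      if (!nrow(pop)) { sizes[d, y + 1L] <- 0; classSizes[d, y + 1L, ] <- 0; next }
      # calving
      L <- expectedLength(pop$age, pop$A, p$k, p$L0)
      avail <- pop$sex == "F" & pop$age >= v$maturityAge &
        (is.na(pop$lastCalving) | (y - pop$lastCalving) > v$calvingGapYears)
      phi <- plogis(v$c0 + v$c1 * (pop$h - v$hRef) + v$c2 * (L - v$LRef))
      calved <- avail & rbinom(nrow(pop), 1, phi) == 1L
      pop$lastCalving[calved] <- y
      nB <- sum(calved)
      if (nB) {
        Acoh <- .cohortAsymptote(p, scenario@lengthRegime, y)
        born <- data.frame(
          sex = sample(c("F", "M"), nB, replace = TRUE),
          age = 0,
          h = pmin(pmax(rnorm(nB, mu, p$healthSD), 0.01), 100),
          A = rnorm(nB, Acoh, p$sigmaACohort),
          lastCalving = NA_integer_
        )
        pop <- rbind(pop, born)
      }
      pop$age <- pop$age + 1
      sizes[d, y + 1L] <- nrow(pop)
      classSizes[d, y + 1L, ] <- c(sum(pop$age < 1),
                                   sum(pop$age >= 1 & pop$age < p$maturityAge),
                                   sum(pop$age >= p$maturityAge))
    }
  }
  new("ProjectionResult", sizes = sizes, classSizes = classSizes,
      entEvents = entEvents, scenario = scenario, demonstration = TRUE)
}

#' Summarize projected trajectories
#'
#' Per-year quantiles of total population size (2.5, 25, 50, 75, 97.5%,
#' giving the median and the 50% and 95% projection intervals) and the
#' cumulative quasi-extinction probability for each threshold (fraction of
#' trajectories that fell below the threshold at or before each year).
#'
#' @param result a [ProjectionResult].
#' @param thresholds numeric quasi-extinction thresholds.
#' @return list `(quantiles, quasiExtinction)`; `quantiles` is a data.frame
#'   `(year, q2.5, q25, q50, q75, q97.5)`, `quasiExtinction` a data.frame
#'   `(year, threshold, probability)`.
#' @export
summarizeTrajectories <- function(result, thresholds = c(0, 50)) {
  sz <- result@sizes
  yrs <- seq_len(ncol(sz)) - 1L
  qs <- t(apply(sz, 2, quantile, probs = c(0.025, 0.25, 0.5, 0.75, 0.975)))
  quantiles <- data.frame(year = yrs, q2.5 = qs[, 1], q25 = qs[, 2],
                          q50 = qs[, 3], q75 = qs[, 4], q97.5 = qs[, 5])
  qe <- do.call(rbind, lapply(thresholds, function(th) {
    below <- t(apply(sz < th | (th == 0 & sz == 0), 1, cummax))
    data.frame(year = yrs, threshold = th, probability = colMeans(below))
  }))
  list(quantiles = quantiles, quasiExtinction = qe)
}
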