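#' Parameters of the latent health process
#'
#' Health is a bounded random walk on a 0–100 scale.  Each step adds intrinsic
#' effects (the calf-to-juvenile transition, lactation cost for the mother),
#' immediate entanglement effects by severity, a per-step prolonged effect
#' while carrying gear, vessel-strike effects by injury class, a prey effect
#' in the summer step, and the stressor-interaction terms under test.  Adverse
#' main effects are sign-constrained non-positive; interaction coefficients
#' are unconstrained.
#'
#' Interaction terms (each active only when named in `activeInteraction`):
#' * `gearPrey` — prolonged gear effect modified by standardized prey,
#' * `sevPrey` — immediate entanglement effect by severity modified by prey,
#' * `injPrey` — strike effect by injury modified by prey,
#' * `nPrior` — effect of a new entanglement scales with the count of prior
#'   entanglements,
#' * `priorAny` — modified by any prior entanglement,
#' * `prior2yr` — modified by a prior entanglement within the last 2 years
#'   (8 steps).
#'
#' @param sigmaH process SD per quarterly step (> 0).
#' @param transitionEffect health change at the calf-to-juvenile step (<= 0).
#' @param lactationEffect per-step cost while lactating (<= 0).
#' @param deltaSev named vector: immediate effect of a new entanglement by
#'   severity (<= 0).
#' @param deltaGear per-step prolonged effect of carrying gear (<= 0).
#' @param deltaInj named vector: effect of a strike by injury class (<= 0).
#' @param betaPrey effect of standardized annual prey in the summer step.
#' @param gammaGearPrey,gammaSevPrey,gammaInjPrey,gammaNPrior,gammaPriorAny,gammaPrior2yr
#'   interaction coefficients (see above); vectors `gammaSevPrey` /
#'   `gammaInjPrey` are per severity / injury class.
#' @param activeInteraction character vector naming the active interaction(s)
#'   (`"none"` disables all; a single active hypothesis is the default
#'   experimental design).
#' @param floor,ceiling clamp bounds of the health scale.
#' @return a validated `healthParameters` list.
#' @export
healthParameters <- function(
    sigmaH = 2,
    transitionEffect = -2,
    lactationEffect = -1,
    deltaSev = c(minor = -2, moderate = -8, severe = -20),
    deltaGear = -2,
    deltaInj = c(superficial = -1, shallow = -6, deep = -15, blunt = -10),
    betaPrey = 1,
    gammaGearPrey = 0,
    gammaSevPrey = c(minor = 0, moderate = 0, severe = 0),
    gammaInjPrey = c(superficial = 0, shallow = 0, deep = 0, blunt = 0),
    gammaNPrior = 0,
    gammaPriorAny = 0,
    gammaPrior2yr = 0,
    activeInteraction = "none",
    floor = 0.01,
    ceiling = 100) {
  stopifnot(sigmaH > 0, floor > 0, ceiling > floor)
  if (transitionEffect > 0 || lactationEffect > 0 || deltaGear > 0 ||
      any(deltaSev > 0) || any(deltaInj > 0))
    stop("adverse main effects must be <= 0")
  if (!identical(sort(names(deltaSev)), sort(SEVERITY_LEVELS)))
    stop("deltaSev must be named by severity level")
  if (!identical(sort(names(deltaInj)), sort(INJURY_LEVELS)))
    stop("deltaInj must be named by injury class")
  known <- c("none", "gearPrey", "sevPrey", "injPrey", "nPrior",
             "priorAny", "prior2yr")
  if (!all(activeInteraction %in% known))
    stop("unknown interaction name; valid: ", paste(known, collapse = ", "))
  p <- list(sigmaH = sigmaH, transitionEffect = transitionEffect,
            lactationEffect = lactationEffect, deltaSev = deltaSev,
            deltaGear = deltaGear, deltaInj = deltaInj, betaPrey = betaPrey,
            gammaGearPrey = gammaGearPrey, gammaSevPrey = gammaSevPrey,
            gammaInjPrey = gammaInjPrey, gammaNPrior = gammaNPrior,
            gammaPriorAny = gammaPriorAny, gammaPrior2yr = gammaPrior2yr,
            activeInteraction = activeInteraction,
            floor = floor, ceiling = ceiling)
  class(p) <- "healthParameters"
  p
}

.isActive <- function(params, name) name %in% params$activeInteraction

#' Deterministic drift of the health process at one step
#'
#' Decomposes the expected health change into named components; the random
#' walk adds Gaussian noise on top of this drift.  The first step of an
#' entanglement event contributes both the immediate severity effect and one
#' step of the prolonged gear-carrying effect (the prolonged effect does not
#' otherwise apply in the step the event occurred).
#'
#' @param covariates list with logicals `transition`, `lactating`, `summer`.
#' @param events list with `newEntanglement` (severity label or `NULL`),
#'   `carryingGear` (gear acquired at an earlier step, logical),
#'   `strike` (injury label or `NULL`), and `history` (list
#'   `nPrior, anyPrior, anyPrior2yr` from [eventHistoryFeatures()]).
#' @param preyStd standardized annual prey covariate for the step's year.
#' @param params a [healthParameters()] list.
#' @return total drift with attribute `"components"` (named numeric vector).
#' @export
healthDrift <- function(covariates, events, preyStd, params) {
  comp <- c(intrinsic = 0, entanglement = 0, gear = 0, strike = 0, prey = 0,
            priorModifier = 0)
  if (isTRUE(covariates$transition))
    comp["intrinsic"] <- comp["intrinsic"] + params$transitionEffect
  if (isTRUE(covariates$lactating))
    comp["intrinsic"] <- comp["intrinsic"] + params$lactationEffect

  gearActive <- isTRUE(events$carryingGear) || !is.null(events$newEntanglement)
  if (gearActive) {
    g <- params$deltaGear
    if (.isActive(params, "gearPrey")) g <- g + params$gammaGearPrey * preyStd
    comp["gear"] <- g
  }
  if (!is.null(events$newEntanglement)) {
    s <- events$newEntanglement
    if (!s %in% SEVERITY_LEVELS) stop("unresolved entanglement severity: ", s)
    e <- params$deltaSev[[s]]
    if (.isActive(params, "sevPrey")) e <- e + params$gammaSevPrey[[s]] * preyStd
    h <- events$history
    if (!is.null(h)) {
      if (.isActive(params, "nPrior"))
        comp["priorModifier"] <- comp["priorModifier"] + params$gammaNPrior * h$nPrior
      if (.isActive(params, "priorAny"))
        comp["priorModifier"] <- comp["priorModifier"] + params$gammaPriorAny * h$anyPrior
      if (.isActive(params, "prior2yr"))
        comp["priorModifier"] <- comp["priorModifier"] + params$gammaPrior2yr * h$anyPrior2yr
    }
    comp["entanglement"] <- e
  }
  if (!is.null(events$strike)) {
    j <- events$strike
    if (!j %in% INJURY_LEVELS) stop("unresolved strike injury: ", j)
    e <- params$deltaInj[[j]]
    if (.isActive(params, "injPrey")) e <- e + params$gammaInjPrey[[j]] * preyStd
    comp["strike"] <- e
  }
  if (isTRUE(covariates$summer))
    comp["prey"] <- params$betaPrey * preyStd
  total <- sum(comp)
  attr(total, "components") <- comp
  total
}

#' One step of the latent health random walk
#'
#' `h_t = clamp(h_prev + drift + noise, floor, ceiling)`.
#'
#' @param hPrev previous health in `(0, 100]`.
#' @param covariates,events,preyStd,params see [healthDrift()].
#' @param noise Gaussian process increment (pass 0 for the deterministic
#'   skeleton, or `rnorm(1, 0, params$sigmaH)` when simulating).
#' @return new health value.
#' @export
healthStep <- function(hPrev, covariates, events, preyStd, params, noise = 0) {
  if (hPrev <= 0 || hPrev > params$ceiling)
    stop("hPrev outside (0, ", params$ceiling, "]")
  d <- healthDrift(covariates, events, preyStd, params)
  min(max(hPrev + as.numeric(d) + noise, params$floor), params$ceiling)
}

#' Entanglement-history features at a step
#'
#' Counts and indicators computed strictly from events before `t`.  The
#' recent window spans the previous 2 years = 8 quarterly steps, with an
#' inclusive boundary (an event exactly 8 steps earlier counts).
#'
#' @param eventSteps integer steps of prior entanglement events.
#' @param t current step.
#' @param windowSteps window length in steps.
#' @return list `(nPrior, anyPrior, anyPrior2yr)`.
#' @export
eventHistoryFeatures <- function(eventSteps, t, windowSteps = 8L) {
  prior <- eventSteps[eventSteps < t]
  recent <- prior[t - prior <= windowSteps]
  list(nPrior = length(prior),
       anyPrior = as.integer(length(prior) > 0),
       anyPrior2yr = as.integer(length(recent) > 0))
}

#' Log-likelihood of a health trajectory
#'
#' Sum of truncated-Gaussian increment log-densities: each increment is
#' Normal(drift, sigmaH) truncated so that `h_t` stays within
#' `[floor, ceiling]`.
#'
#' @param h numeric trajectory in `(0, 100]`.
#' @param drifts deterministic drift for each transition (length
#'   `length(h) - 1`), e.g. accumulated from [healthDrift()].
#' @param params a [healthParameters()] list.
#' @return log-density.
#' @export
healthLoglik <- function(h, drifts, params) {
  if (any(h <= 0) || any(h > params$ceiling))
    stop("trajectory outside (0, ", params$ceiling, "]")
  n <- length(h) - 1L
  if (length(drifts) != n) stop("need one drift per transition")
  mu <- h[seq_len(n)] + drifts
  s <- params$sigmaH
  lo <- pnorm(params$floor, mu, s)
  hi <- pnorm(params$ceiling, mu, s)
  sum(dnorm(h[-1L], mu, s, log = TRUE) - log(hi - lo))
}
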