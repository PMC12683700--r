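#' Parameters of the observation models
#'
#' Latent states are observed through detection-limited data streams:
#' Bernoulli sightings with region-by-season detection probability, ordinal
#' visual health scores generated by an ordered-probit model with monotone
#' cutpoints on the health scale, Normal photogrammetric length measurements
#' with platform-specific SD, event detection, and carcass recovery.
#'
#' @param pDetect matrix `[region, quarter]` of per-step detection
#'   probabilities, or a scalar recycled to all cells.
#' @param cutpoints list with one strictly increasing numeric vector per VHA
#'   variable (category boundaries on the 0–100 health scale).
#' @param tauVha per-variable ordered-probit noise SD.
#' @param sigmaP named vector of length-measurement SDs by platform (m).
#' @param pRecover carcass recovery probability.
#' @param pDetectEnt,pDetectStrike event detection probabilities.
#' @param terminalSevPrior,terminalInjPrior categorical priors over severity /
#'   injury for unobserved terminal events.
#' @param nRegions,nQuarters used when `pDetect` is scalar.
#' @return a validated `observationParameters` list.
#' @export
observationParameters <- function(
    pDetect = 0.3,
    cutpoints = rep(list(c(35, 55, 75)), 4L),
    tauVha = rep(6, 4L),
    sigmaP = c(aircraft = 0.2, drone = 0.1),
    pRecover = 0.3,
    pDetectEnt = 0.9,
    pDetectStrike = 0.5,
    terminalSevPrior = c(minor = 0.2, moderate = 0.3, severe = 0.5),
    terminalInjPrior = c(superficial = 0.1, shallow = 0.2, deep = 0.4, blunt = 0.3),
    nRegions = 7L, nQuarters = 4L) {
  if (length(pDetect) == 1L)
    pDetect <- matrix(pDetect, nRegions, nQuarters)
  stopifnot(all(pDetect >= 0 & pDetect <= 1),
            all(sigmaP > 0),
            pRecover >= 0, pRecover <= 1,
            abs(sum(terminalSevPrior) - 1) < 1e-8,
            abs(sum(terminalInjPrior) - 1) < 1e-8)
  for (k in cutpoints)
    if (is.unsorted(k, strictly = TRUE)) stop("cutpoints must be strictly increasing")
  if (length(tauVha) != length(cutpoints))
    stop("one tauVha per VHA variable")
  p <- list(pDetect = pDetect, cutpoints = cutpoints, tauVha = tauVha,
            sigmaP = sigmaP, pRecover = pRecover, pDetectEnt = pDetectEnt,
            pDetectStrike = pDetectStrike, terminalSevPrior = terminalSevPrior,
            terminalInjPrior = terminalInjPrior)
  class(p) <- "observationParameters"
  p
}

#' Per-step sighting probability
#'
#' `P(seen at t) = alive * sum_l z_l * pDetect[l, quarter]` — the occupancy-
#' weighted detection probability, 0 for dead individuals.
#'
#' @param z occupancy simplex over regions.
#' @param alive logical.
#' @param quarter season index 1..4.
#' @param params an [observationParameters()] list.
#' @return probability.
#' @export
sightingProbability <- function(z, alive, quarter, params) {
  if (!alive) return(0)
  .checkSimplex(z)
  sum(z * params$pDetect[, quarter])
}

#' Bernoulli log-likelihood of a sighting record
#'
#' @param seen 0/1 vector over steps.
#' @param z matrix `[step, region]` of occupancy simplices.
#' @param alive logical vector over steps.
#' @param quarters season index per step.
#' @param params an [observationParameters()] list.
#' @return log-probability.
#' @export
sightingLoglik <- function(seen, z, alive, quarters, params) {
  stopifnot(length(seen) == nrow(z), length(alive) == length(seen))
  ll <- 0
  for (t in seq_along(seen)) {
    p <- sightingProbability(z[t, ], alive[t], quarters[t], params)
    if (seen[t] == 1) {
      if (p <= 0) return(-Inf)
      ll <- ll + log(p)
    } else {
      ll <- ll + log1p(-p)
    }
  }
  ll
}

#' Ordered-probit category probabilities for a VHA variable
#'
#' `P(category c) = Phi((kappa_c - h)/tau) - Phi((kappa_{c-1} - h)/tau)` with
#' `kappa_0 = -Inf` and `kappa_C = +Inf`.
#'
#' @param h latent health.
#' @param variable VHA variable index.
#' @param params an [observationParameters()] list.
#' @return probability vector over categories (sums to 1).
#' @export
vhaCategoryProbs <- function(h, variable, params) {
  k <- params$cutpoints[[variable]]
  tau <- params$tauVha[variable]
  cdf <- c(0, pnorm((k - h) / tau), 1)
  diff(cdf)
}

#' Log-likelihood of ordinal health scores
#'
#' @param score observed category.
#' @param h latent health.
#' @param variable VHA variable index.
#' @param params an [observationParameters()] list.
#' @return log-probability.
#' @export
vhaLoglik <- function(score, h, variable, params) {
  p <- vhaCategoryProbs(h, variable, params)
  if (score < 1L || score > length(p)) stop("score outside category range")
  log(p[score])
}

#' Log-density of a photogrammetric length measurement
#'
#' `P ~ Normal(L, sigmaP[platform])`.
#'
#' @param P measured length (m, > 0).
#' @param L latent length (m).
#' @param platform `"aircraft"` or `"drone"`.
#' @param params an [observationParameters()] list.
#' @return log-density.
#' @export
lengthMeasurementLoglik <- function(P, L, platform, params) {
  if (!platform %in% names(params$sigmaP))
    stop("unknown platform: ", platform)
  s <- params$sigmaP[[platform]]
  dnorm(P, L, s, log = TRUE)
}

#' Distribution of an unobserved terminal event
#'
#' To capture cryptic deaths, at most one unobserved entanglement and one
#' unobserved vessel strike are allowed after an individual's last sighting.
#' The event-time prior over the candidate steps is the normalized exposure
#' probability; the overall event probability is the probability that at
#' least one exposure draw succeeds over the window; severity/injury follow
#' the categorical terminal priors.  Individuals recovered dead with known
#' cause get no imputation.
#'
#' @param exposure per-step exposure probabilities over the post-last-sighting
#'   window (entanglement or strike probabilities).
#' @param recoveredKnownCause logical gate.
#' @param classPrior categorical prior over severity or injury classes.
#' @return list `(pEvent, timeWeights, classPrior)`; `pEvent = 0` and uniform
#'   `timeWeights` when exposure is zero everywhere or imputation is gated
#'   off.
#' @export
terminalEventDistribution <- function(exposure, recoveredKnownCause = FALSE,
                                      classPrior) {
  if (any(exposure < 0 | exposure > 1)) stop("exposure must be in [0, 1]")
  n <- length(exposure)
  if (recoveredKnownCause || n == 0L || sum(exposure) == 0) {
    return(list(pEvent = 0,
                timeWeights = if (n) rep(1 / n, n) else numeric(0),
                classPrior = classPrior))
  }
  list(pEvent = 1 - prod(1 - exposure),
       timeWeights = exposure / sum(exposure),
       classPrior = classPrior)
}

#' Sample terminal unobserved events for an individual
#'
#' Draws the latent terminal entanglement and strike (occurrence, time and
#' class) from [terminalEventDistribution()]; used by the simulator and as
#' the initialization of the discrete latents in MCMC.
#'
#' @param entExposure,strikeExposure per-step exposure probabilities after the
#'   last sighting.
#' @param recoveredKnownCause logical gate.
#' @param params an [observationParameters()] list.
#' @param lastSighting step index of the last sighting (times are offset from
#'   it).
#' @return data.frame with 0–2 rows `(type, t, class)`.
#' @export
imputeTerminalEvents <- function(entExposure, strikeExposure,
                                 recoveredKnownCause, params, lastSighting) {
  out <- list()
  ent <- terminalEventDistribution(entExposure, recoveredKnownCause,
                                   params$terminalSevPrior)
  if (ent$pEvent > 0 && runif(1) < ent$pEvent) {
    tt <- sample.int(length(ent$timeWeights), 1L, prob = ent$timeWeights)
    out[[length(out) + 1L]] <- data.frame(
      type = "entanglement", t = lastSighting + tt,
      class = sample(names(ent$classPrior), 1L, prob = ent$classPrior))
  }
  str <- terminalEventDistribution(strikeExposure, recoveredKnownCause,
                                   params$terminalInjPrior)
  if (str$pEvent > 0 && runif(1) < str$pEvent) {
    tt <- sample.int(length(str$timeWeights), 1L, prob = str$timeWeights)
    out[[length(out) + 1L]] <- data.frame(
      type = "strike", t = lastSighting + tt,
      class = sample(names(str$classPrior), 1L, prob = str$classPrior))
  }
  if (!length(out))
    return(data.frame(type = character(0), t = integer(0), class = character(0)))
  do.call(rbind, out)
}
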