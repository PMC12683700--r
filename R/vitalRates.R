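#' Parameters linking health to survival and calving
#'
#' Survival uses a hazard-rate form of the complementary log-log link:
#' `lambda = exp(aS - bS * h)` per quarter and `theta = exp(-lambda)`, so the
#' same hazard feeds the viability projections directly.  Calving probability
#' for available adult females is logistic in mean annual health and body
#' length.
#'
#' @param aS survival intercept (cloglog scale, per quarter).
#' @param bS health slope (>= 0: higher health, higher survival).
#' @param c0 calving intercept (logit scale, per available female-year).
#' @param c1 calving health slope.
#' @param c2 calving length slope (>= 0: longer females calve more).
#' @param hRef,LRef centering constants for health (0–100 scale) and length (m).
#' @param calvingGapYears minimum number of full calendar years between
#'   calvings (resting + gestation) before a female is available again.
#' @param maturityAge age (years) at which females enter the available pool.
#' @return a validated `vitalRateParameters` list.
#' @export
vitalRateParameters <- function(aS = -2, bS = 0.04, c0 = -1, c1 = 0.03,
                                c2 = 0.5, hRef = 70, LRef = 13,
                                calvingGapYears = 2L, maturityAge = 9L) {
  stopifnot(bS >= 0, c2 >= 0, calvingGapYears >= 0, maturityAge >= 1)
  p <- list(aS = aS, bS = bS, c0 = c0, c1 = c1, c2 = c2, hRef = hRef,
            LRef = LRef, calvingGapYears = as.integer(calvingGapYears),
            maturityAge = as.integer(maturityAge))
  class(p) <- "vitalRateParameters"
  p
}

#' Quarterly mortality hazard rate
#'
#' `lambda(h) = exp(aS - bS * h)`; hazards are additive across quarters, so
#' the annual hazard is the sum of the four quarterly hazards.
#'
#' @param h health in `(0, 100]` (vectorized).
#' @param params a [vitalRateParameters()] list.
#' @return hazard rate(s).
#' @export
hazardRate <- function(h, params) {
  if (any(h <= 0 | h > 100)) stop("health outside (0, 100]")
  exp(params$aS - params$bS * h)
}

#' Quarterly survival probability
#'
#' `theta(h) = exp(-lambda(h))`, identical to the complementary log-log
#' survival form `exp(-exp(aS - bS * h))`.
#'
#' @param h health in `(0, 100]` (vectorized).
#' @param params a [vitalRateParameters()] list.
#' @return survival probability in `[0, 1]`.
#' @export
survivalProbability <- function(h, params) {
  exp(-hazardRate(h, params))
}

#' Annual calving probability of an available female
#'
#' `phi = plogis(c0 + c1 * (hBar - hRef) + c2 * (L - LRef))` when the female
#' is available (mature, and at least `calvingGapYears` full calendar years
#' since her last calving); 0 otherwise.
#'
#' @param hBar mean health over the year's four steps.
#' @param L latent length (m).
#' @param available logical availability flag (see [calvingAvailability()]).
#' @param params a [vitalRateParameters()] list.
#' @return calving probability.
#' @export
calvingProbability <- function(hBar, L, available, params) {
  if (!available) return(0)
  plogis(params$c0 + params$c1 * (hBar - params$hRef) +
           params$c2 * (L - params$LRef))
}

#' Availability of a female for calving in a year
#'
#' A female is available when she has reached maturity and her last calving,
#' if any, was followed by at least `calvingGapYears` full calendar years
#' (e.g. with a 2-year gap a female calving in 2000 is next available in
#' 2003).
#'
#' @param age age in years at the start of the year.
#' @param lastCalvingYear year of the most recent calving, or `NA`.
#' @param year current year.
#' @param params a [vitalRateParameters()] list.
#' @return logical.
#' @export
calvingAvailability <- function(age, lastCalvingYear, year, params) {
  if (is.na(age) || age < params$maturityAge) return(FALSE)
  if (is.na(lastCalvingYear)) return(TRUE)
  (year - lastCalvingYear) > params$calvingGapYears
}

#' Demographic class transition
#'
#' Calves become juveniles at age 1; juveniles become adults at the maturity
#' age; death is absorbing.
#'
#' @param class current class (`"calf"`, `"juvenile"`, `"adult male"`,
#'   `"adult female"`, or `"dead"`).
#' @param age age in years at the next step.
#' @param sex `"F"` or `"M"`.
#' @param alive logical: alive at the next step.
#' @param maturityAge age at adulthood.
#' @return class label at the next step.
#' @export
demographicTransition <- function(class, age, sex, alive, maturityAge = 9L) {
  if (!alive || class == "dead") return("dead")
  if (age < 1) "calf"
  else if (age < maturityAge) "juvenile"
  else if (sex == "F") "adult female" else "adult male"
}
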