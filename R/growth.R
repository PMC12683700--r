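#' Parameters of the somatic growth model
#'
#' Length follows a von-Bertalanffy-type curve toward an individual asymptote
#' `A_i`: the growth rate `k` and length at age 0 `L0` are shared, while the
#' asymptote varies by individual around a mean that can depend on birth-year
#' trend and the covariate block of the active length hypothesis (prolonged
#' health, mother's health, mean prey / entanglement status and their
#' product, mother's entanglement status).
#'
#' @param A0 population asymptote intercept (m).
#' @param trend birth-year trend on the asymptote (m per year).
#' @param k growth rate (per year, > 0).
#' @param L0 length at age 0 (m, < A0).
#' @param sigmaA SD of individual asymptote deviations (m, > 0).
#' @param betaA named numeric vector of asymptote covariate coefficients
#'   (empty by default; covariates are standardized by the caller).
#' @param birthYearRef centering year for the trend.
#' @return a validated `growthParameters` list.
#' @export
growthParameters <- function(A0 = 13.5, trend = 0, k = 0.25, L0 = 4.3,
                             sigmaA = 0.5, betaA = numeric(0),
                             birthYearRef = 1980L) {
  stopifnot(k > 0, sigmaA > 0, L0 > 0, A0 > L0)
  p <- list(A0 = A0, trend = trend, k = k, L0 = L0, sigmaA = sigmaA,
            betaA = betaA, birthYearRef = birthYearRef)
  class(p) <- "growthParameters"
  p
}

#' Expected length at age
#'
#' `L(age) = A - (A - L0) * exp(-k * age)`; monotone nondecreasing in age,
#' approaching the asymptote `A`.
#'
#' @param age age in years (>= 0, vectorized).
#' @param A individual asymptote (m).
#' @param k growth rate (per year).
#' @param L0 length at age 0 (m).
#' @return expected length in meters.
#' @export
expectedLength <- function(age, A, k, L0) {
  if (any(age < 0)) stop("age must be >= 0")
  A - (A - L0) * exp(-k * age)
}

#' Mean asymptote for an individual
#'
#' `A_mean = A0 + trend * (birthYear - ref) + X %*% betaA`, with the covariate
#' block of the single active length hypothesis.  Individual asymptotes are
#' then Normal(A_mean, sigmaA) truncated above `L0`.
#'
#' @param params a [growthParameters()] list.
#' @param birthYear integer birth year.
#' @param covariates named numeric vector matching `params$betaA` (standardized).
#' @return asymptote mean in meters.
#' @export
asymptotePredictor <- function(params, birthYear, covariates = numeric(0)) {
  x <- 0
  if (length(params$betaA)) {
    if (!all(names(params$betaA) %in% names(covariates)))
      stop("missing covariate(s): ",
           paste(setdiff(names(params$betaA), names(covariates)), collapse = ", "))
    x <- sum(params$betaA * covariates[names(params$betaA)])
  }
  params$A0 + params$trend * (birthYear - params$birthYearRef) + x
}

#' Draw an individual asymptote
#'
#' Normal around the predictor mean, truncated below at `L0` (rejection
#' sampling; the truncation is rarely active for realistic parameters).
#'
#' @param params a [growthParameters()] list.
#' @param birthYear integer birth year.
#' @param covariates see [asymptotePredictor()].
#' @return asymptote draw (m).
#' @export
drawAsymptote <- function(params, birthYear, covariates = numeric(0)) {
  m <- asymptotePredictor(params, birthYear, covariates)
  for (i in 1:1000) {
    a <- rnorm(1, m, params$sigmaA)
    if (a > params$L0) return(a)
  }
  params$L0 + 1e-6
}

#' Early-life covariate windows for the length model
#'
#' Means of health, standardized prey and entanglement status (fraction of
#' steps carrying gear) over the quarterly steps within the first `w` years
#' of life.  If the observed lifespan is shorter than the window, the mean is
#' taken over the available steps and flagged.
#'
#' @param h health trajectory from birth (quarterly).
#' @param preyStd standardized prey covariate per step.
#' @param gear logical/0-1 gear-carrying indicator per step.
#' @param windowYears window length in years (the hypotheses use 15, 10, 5,
#'   2 or 1).
#' @return list `(meanHealth, meanPrey, meanEntanglement, covered)` where
#'   `covered` is `FALSE` when the window exceeded the available steps.
#' @export
growthCovariateWindows <- function(h, preyStd, gear, windowYears) {
  stopifnot(length(h) == length(preyStd), length(h) == length(gear))
  want <- as.integer(windowYears * 4L)
  n <- min(want, length(h))
  if (n == 0L) stop("empty trajectory")
  idx <- seq_len(n)
  list(meanHealth = mean(h[idx]),
       meanPrey = mean(preyStd[idx]),
       meanEntanglement = mean(as.numeric(gear[idx])),
       covered = want <= length(h))
}
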