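#' Rescale a risk surface to the unit interval
#'
#' Risk inputs to the probability equations are rescaled to `[0, 1]` by
#' dividing by the global maximum over all regions and steps, preserving the
#' surface's relative spatiotemporal structure.
#'
#' @param m non-negative matrix.
#' @return matrix with maximum 1 (an all-zero surface is returned unchanged).
#' @export
rescaleSurface <- function(m) {
  if (any(m < 0)) stop("risk surfaces must be non-negative")
  mx <- max(m)
  if (mx == 0) m else m / mx
}

#' Per-step entanglement probability
#'
#' `p_ent = iota1 * sum_l z_l * G_l * e_l`, the occupancy-weighted rescaled
#' entanglement risk converted to a probability by the estimated coefficient
#' `iota1`.  The coefficient's support must guarantee a valid probability; a
#' result above 1 is an error, never a silent clip.
#'
#' @param z occupancy simplex over regions.
#' @param G rescaled entanglement-risk row (in `[0, 1]`).
#' @param entScalar landings-backcast multiplier row (>= 0).
#' @param iota1 conversion coefficient.
#' @return probability in `[0, 1]`.
#' @export
entanglementProbability <- function(z, G, entScalar, iota1) {
  .checkSimplex(z)
  if (any(G < 0) || any(G > 1)) stop("G must be rescaled to [0, 1]")
  if (any(entScalar < 0)) stop("entanglement scalar must be non-negative")
  p <- iota1 * sum(z * G * entScalar)
  if (p > 1)
    stop("entanglement probability ", format(p),
         " > 1: iota1/entScalar combination outside its support")
  if (p < 0) stop("negative entanglement probability; iota1 must be >= 0")
  p
}

.checkSimplex <- function(z, tol = 1e-8) {
  if (any(z < -1e-12) || abs(sum(z) - 1) > tol)
    stop("z must be a simplex over regions")
  invisible(TRUE)
}

#' Regional vessel-strike probability
#'
#' Strike probability is proportional to traffic-derived risk in the
#' reference year and changes linearly on the logit scale going back in time:
#' `logit(p_r) = logit(iota2 * AIS_l) + vTrend * (refYear - year)`.
#' `AIS_l = 0` maps to probability 0 (the limit convention).
#'
#' @param AIS rescaled traffic-risk row in `[0, 1]`.
#' @param iota2 conversion coefficient; `iota2 * AIS` must stay below 1.
#' @param vTrend temporal trend per year on the logit scale.
#' @param year calendar year of the step.
#' @param refYear reference year of the traffic surface.
#' @return vector of probabilities over regions.
#' @export
regionalStrikeProbability <- function(AIS, iota2, vTrend, year, refYear = 2019L) {
  if (any(AIS < 0) || any(AIS > 1)) stop("AIS must lie in [0, 1]")
  base <- iota2 * AIS
  if (any(base >= 1))
    stop("iota2 * AIS >= 1: logit undefined, iota2 outside its support")
  p <- numeric(length(AIS))
  pos <- base > 0
  p[pos] <- plogis(qlogis(base[pos]) + vTrend * (refYear - year))
  p
}

#' Individual vessel-strike probability
#'
#' The occupancy-weighted regional strike probability,
#' `p_strike = sum_l z_l * p_r_l` — a convex combination, so always bounded
#' by the regional extremes.
#'
#' @param z occupancy simplex.
#' @param pRegional regional strike probabilities in `[0, 1]`.
#' @return probability.
#' @export
individualStrikeProbability <- function(z, pRegional) {
  .checkSimplex(z)
  if (any(pRegional < 0) || any(pRegional > 1))
    stop("regional strike probabilities must lie in [0, 1]")
  sum(z * pRegional)
}

#' Prey index experienced by an individual in a step
#'
#' `prey' = sum_l z_l * prey_l` (g/m^3), the occupancy-weighted regional prey
#' concentration.
#'
#' @param z occupancy simplex.
#' @param prey regional prey row (>= 0).
#' @return weighted prey value.
#' @export
individualPreyIndex <- function(z, prey) {
  .checkSimplex(z)
  if (any(prey < 0)) stop("prey index must be non-negative")
  sum(z * prey)
}

#' Annualize and standardize experienced prey
#'
#' Per-step experienced prey values are averaged within each calendar year,
#' then standardized with population-level constants (mean and SD across all
#' annual means).  The standardized annual value is the prey covariate that
#' enters the health process in the Jun–Aug step.
#'
#' @param values numeric per-step experienced prey.
#' @param years integer year of each value.
#' @param constants optional list `(mean, sd)`; when `NULL` they are computed
#'   from the annual means of `values` (requires at least 2 distinct annual
#'   means).
#' @return list with `annual` (named vector of standardized annual values),
#'   `constants` (the standardization constants used).
#' @export
annualizeAndStandardize <- function(values, years, constants = NULL) {
  stopifnot(length(values) == length(years))
  ann <- tapply(values, years, mean)
  ann <- setNames(as.numeric(ann), names(ann))
  if (is.null(constants)) {
    if (length(ann) < 2L) stop("need at least 2 annual means to standardize")
    s <- sd(ann)
    if (s == 0) stop("degenerate standardization: SD of annual means is 0")
    constants <- list(mean = mean(ann), sd = s)
  }
  std <- (ann - constants$mean) / constants$sd
  list(annual = std, constants = constants)
}

#' Backcast entanglement-risk scalars from fishery landings
#'
#' The entanglement surface reflects recent risk; earlier years are rescaled
#' by the trend in landings of the high-risk fisheries:
#' `e[l, t] = landings(year(t), group(l)) / mean(landings over baseline years)`,
#' so the baseline period has scalar 1 by construction.  From
#' `scalarFromYear` onward the scalar is fixed at 1 (the surface itself is
#' taken to describe those years).
#'
#' @param landings data.frame `(year, group, landings)`.
#' @param regionGroups named character vector mapping region label to landings
#'   group.
#' @param baselineYears integer years defining the baseline mean.
#' @param frame a [StudyFrame].
#' @param scalarFromYear first year in which the scalar is identically 1.
#' @return `R x T` matrix of scalars.
#' @export
backcastEntanglementScalars <- function(landings, regionGroups, baselineYears,
                                        frame, scalarFromYear = 2015L) {
  R <- nRegions(frame); T <- nSteps(frame)
  out <- matrix(1, R, T, dimnames = list(regionLabels(frame), NULL))
  yrs <- stepYear(frame, seq_len(T))
  for (l in seq_len(R)) {
    grp <- regionGroups[[regionLabels(frame)[l]]]
    sub <- landings[landings$group == grp, ]
    if (!nrow(sub)) stop("no landings series for group ", grp)
    base <- mean(sub$landings[sub$year %in% baselineYears])
    if (!is.finite(base) || base <= 0)
      stop("invalid baseline landings mean for group ", grp)
    lx <- setNames(sub$landings, sub$year)
    for (t in seq_len(T)) {
      y <- yrs[t]
      if (y >= scalarFromYear) next
      v <- lx[as.character(y)]
      if (is.na(v)) stop("no landings for group ", grp, " in year ", y)
      out[l, t] <- v / base
    }
  }
  out
}

#' Extrapolate entanglement risk into uncovered regions
#'
#' Risk in regions outside the fishery-risk model's coverage is taken as the
#' total risk over the northern US regions scaled by the ratio of the
#' uncovered region's lobster/crab landings to northern-US landings:
#' `G_can[l, t] = sum(G_us_north[, t]) * landingsCan[l, year] / landingsUS[year]`.
#'
#' @param G `R x T` entanglement-risk matrix (rows named by region).
#' @param frame a [StudyFrame].
#' @param landingsCan data.frame `(region, year, landings)` for the uncovered
#'   regions.
#' @param landingsUS data.frame `(year, landings)` for the northern US
#'   reference fisheries.
#' @param northernUS character labels of the northern US regions.
#' @param fillRegions character labels of the regions to fill.
#' @return the completed risk matrix.
#' @export
extrapolateCanadianEntanglement <- function(G, frame, landingsCan, landingsUS,
                                            northernUS = c("NEUS", "CCB", "SNE"),
                                            fillRegions = c("GSL", "MAR")) {
  ni <- match(northernUS, rownames(G))
  if (anyNA(ni)) stop("unknown northern US region label")
  usTotal <- colSums(G[ni, , drop = FALSE])
  usL <- setNames(landingsUS$landings, landingsUS$year)
  yrs <- stepYear(frame, seq_len(ncol(G)))
  for (l in fillRegions) {
    li <- match(l, rownames(G))
    if (is.na(li)) stop("unknown fill region: ", l)
    sub <- landingsCan[landingsCan$region == l, ]
    cl <- setNames(sub$landings, sub$year)
    for (t in seq_len(ncol(G))) {
      y <- as.character(yrs[t])
      if (is.na(cl[y]) || is.na(usL[y]))
        stop("missing landings for year ", y)
      if (usL[y] <= 0) stop("non-positive US landings in year ", y)
      G[li, t] <- usTotal[t] * cl[y] / usL[y]
    }
  }
  G
}

#' Backcast the prey index from a plankton-anomaly series
#'
#' Fits `log(index) = a + b * anomaly` over the overlap years and predicts
#' `exp(a + b * anomaly)` for the years preceding the index.  Fitted
#' coefficients and the in-sample R^2 are returned alongside the predictions.
#'
#' @param index named numeric vector of the recent prey index (names = years,
#'   strictly positive values).
#' @param anomaly named numeric vector of annual anomalies covering both the
#'   overlap and the prediction years.
#' @param predictYears integer years to predict.
#' @return list `(predicted, a, b, r2)` with `predicted` a named vector.
#' @export
backcastPrey <- function(index, anomaly, predictYears) {
  if (any(index <= 0)) stop("prey index must be strictly positive for the log fit")
  overlap <- intersect(names(index), names(anomaly))
  if (length(overlap) < 5L) stop("need at least 5 overlapping years")
  x <- anomaly[overlap]; y <- log(index[overlap])
  if (sd(x) == 0)
    stop("anomaly series is constant over the overlap; slope unidentifiable")
  fit <- lm(y ~ x)
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  py <- as.character(predictYears)
  if (anyNA(anomaly[py])) stop("anomaly series missing prediction year(s)")
  pred <- exp(a + b * anomaly[py])
  names(pred) <- py
  list(predicted = pred, a = a, b = b, r2 = r2)
}

#' Exposure table for a set of individuals
#'
#' Applies the exposure equations across all steps for each demographic
#' class's occupancy, producing per-class entanglement and strike
#' probabilities and the experienced prey index.
#'
#' @param occ an [OccupancyDistribution].
#' @param surfaces a [RegionalSurfaces] whose `G` and `AIS` assays are
#'   rescaled to `[0, 1]` internally.
#' @param iota1,iota2,vTrend exposure parameters.
#' @param refYear traffic-surface reference year.
#' @return data.frame `(t, class, pEnt, pStrike, preyW)`.
#' @export
exposureTable <- function(occ, surfaces, iota1, iota2, vTrend, refYear = 2019L) {
  frame <- studyFrame(surfaces)
  G <- rescaleSurface(assay(surfaces, "G"))
  AIS <- rescaleSurface(assay(surfaces, "AIS"))
  eS <- assay(surfaces, "entScalar")
  prey <- assay(surfaces, "prey")
  T <- nSteps(frame)
  yrs <- stepYear(frame, seq_len(T))
  classes <- occ@classes
  out <- expand.grid(t = seq_len(T), class = classes,
                     stringsAsFactors = FALSE)
  out$pEnt <- NA_real_; out$pStrike <- NA_real_; out$preyW <- NA_real_
  for (t in seq_len(T)) {
    pr <- regionalStrikeProbability(AIS[, t], iota2, vTrend, yrs[t], refYear)
    for (ci in seq_along(classes)) {
      z <- occ@z[t, ci, ]
      row <- which(out$t == t & out$class == classes[ci])
      out$pEnt[row] <- entanglementProbability(z, G[, t], eS[, t], iota1)
      out$pStrike[row] <- individualStrikeProbability(z, pr)
      out$preyW[row] <- individualPreyIndex(z, prey[, t])
    }
  }
  out
}
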