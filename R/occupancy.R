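#' @include studyFrame.R
NULL

#' Dirichlet model of proportional regional presence
#'
#' Concentration parameters `alpha` are estimated separately for each
#' demographic class x season x era stratum, capturing the shift in habitat
#' use between the pre- and post-break eras.
#'
#' @slot alpha 4-d array `[class, quarter, era, region]` of concentrations
#'   (> 0).
#' @slot classes character vector of demographic class labels.
#' @slot frame the [StudyFrame] the model was fitted against.
#' @slot nObs matrix of composition counts per `[class, quarter, era]` stratum
#'   (flattened to an array) recording how much data informed each stratum.
#' @export
setClass("DirichletOccupancyModel",
  representation(alpha = "array", classes = "character",
                 frame = "StudyFrame", nObs = "array"))

setValidity("DirichletOccupancyModel", function(object) {
  msg <- character()
  if (length(dim(object@alpha)) != 4L)
    msg <- c(msg, "alpha must be [class, quarter, era, region]")
  if (any(object@alpha <= 0)) msg <- c(msg, "alpha must be strictly positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DirichletOccupancyModel", function(object) {
  d <- dim(object@alpha)
  cat("DirichletOccupancyModel:", d[1], "classes x", d[2], "quarters x",
      d[3], "eras x", d[4], "regions\n")
  cat("  strata with data:", sum(object@nObs > 0), "/", length(object@nObs), "\n")
})

#' Demographic class labels used throughout the package
#' @export
DEMOGRAPHIC_CLASSES <- c("calf", "juvenile", "adult male", "adult female")

#' Per-individual occupancy distributions
#'
#' Proportional presence over regions for every step, shared within
#' demographic class.  `z[t, class, l]` is a simplex over `l` for every
#' `(t, class)`.
#'
#' @slot z array `[step, class, region]`.
#' @slot classes character class labels.
#' @slot version `"v1"` (sightings-driven Dirichlet) or `"v2"` (density-surface
#'   based).
#' @slot frame the [StudyFrame].
#' @export
setClass("OccupancyDistribution",
  representation(z = "array", classes = "character", version = "character",
                 frame = "StudyFrame"))

setValidity("OccupancyDistribution", function(object) {
  s <- apply(object@z, c(1, 2), sum)
  if (any(object@z < -1e-12)) return("negative occupancy")
  if (any(abs(s - 1) > 1e-9)) return("occupancy rows must sum to 1")
  TRUE
})

setMethod("show", "OccupancyDistribution", function(object) {
  d <- dim(object@z)
  cat("OccupancyDistribution (", object@version, "): ",
      d[1], " steps x ", d[2], " classes x ", d[3], " regions\n", sep = "")
})

# ---- Dirichlet estimation ---------------------------------------------------

#' Inverse digamma function
#'
#' Newton iteration with Minka's initialization; used by the fixed-point
#' Dirichlet maximum-likelihood estimator.
#'
#' @param y numeric vector.
#' @return x with `digamma(x) = y`.
#' @keywords internal
.invDigamma <- function(y) {
  x <- ifelse(y >= -2.22, exp(y) + 0.5, -1 / (y - digamma(1)))
  for (i in 1:8) x <- x - (digamma(x) - y) / trigamma(x)
  x
}

#' Maximum-likelihood Dirichlet fit to compositions
#'
#' Fixed-point iteration on the digamma moment condition.  Degenerate inputs
#' (all compositions at the same vertex, zero spread) fall back to a
#' vertex-concentrated alpha with a warning rather than failing.
#'
#' @param comps matrix, one composition (simplex) per row.
#' @param maxIter,tol iteration controls.
#' @return numeric vector of concentrations alpha.
#' @export
fitDirichlet <- function(comps, maxIter = 500L, tol = 1e-10) {
  comps <- as.matrix(comps)
  if (any(comps < 0) || any(abs(rowSums(comps) - 1) > 1e-8))
    stop("rows of comps must be simplices")
  K <- ncol(comps)
  if (nrow(comps) < 2L || max(apply(comps, 2, var)) < 1e-12) {
    warning("degenerate compositions; returning vertex-concentrated alpha")
    m <- colMeans(comps)
    return(pmax(m, 1e-6) * 1e4)
  }
  eps <- 1e-10
  logpBar <- colMeans(log(pmax(comps, eps)))
  # method-of-moments start
  m <- colMeans(comps); v <- apply(comps, 2, var)
  ok <- v > 1e-12 & m > 0 & m < 1
  s <- if (any(ok)) median(m[ok] * (1 - m[ok]) / v[ok] - 1) else K
  s <- max(s, 1e-3)
  alpha <- pmax(m * s, 1e-3)
  for (i in seq_len(maxIter)) {
    alphaNew <- .invDigamma(digamma(sum(alpha)) + logpBar)
    if (max(abs(alphaNew - alpha)) < tol) { alpha <- alphaNew; break }
    alpha <- alphaNew
  }
  unname(alpha)
}

#' Draw from a Dirichlet distribution
#' @param n number of draws.
#' @param alpha concentration vector.
#' @return `n x length(alpha)` matrix of simplices.
#' @export
rDirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Build per-individual-quarter compositions from sightings
#'
#' For every (individual, year, quarter) with at least one sighting, region
#' counts receive additive smoothing (default +0.5 per region) and are
#' normalized to a composition; true zero presence is unidentifiable from
#' sparse sightings, so smoothed compositions keep all regions in the support.
#'
#' @param observations an [ObservationSet].
#' @param individuals individuals data.frame (see [readIndividuals()]).
#' @param frame a [StudyFrame].
#' @param smoothing additive count per region.
#' @param maturityAge passed to [demographicClass()].
#' @return data.frame with columns `class`, `quarter`, `era`, and one
#'   composition column per region.
#' @export
sightingCompositions <- function(observations, individuals, frame,
                                 smoothing = 0.5, maturityAge = 9L) {
  sg <- obsStream(observations, "sightings")
  if (!nrow(sg)) stop("no sightings to build compositions from")
  R <- nRegions(frame)
  regs <- regionLabels(frame)
  sexOf <- setNames(individuals$sex, individuals$id)
  byOf <- setNames(individuals$birthYear, individuals$id)
  yr <- stepYear(frame, sg$t)
  qu <- stepQuarter(frame, sg$t)
  key <- paste(sg$id, yr, qu, sep = "\r")
  groups <- split(seq_len(nrow(sg)), key)
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    rows <- groups[[gi]]
    id <- sg$id[rows[1L]]
    y <- yr[rows[1L]]; q <- qu[rows[1L]]
    counts <- tabulate(match(sg$region[rows], regs), nbins = R) + smoothing
    comp <- counts / sum(counts)
    cls <- demographicClass(sexOf[[id]], byOf[[id]], y, maturityAge)
    out[[gi]] <- c(list(class = cls, quarter = q,
                        era = if (y >= eraBreakYear(frame)) "post" else "pre"),
                   as.list(setNames(comp, regs)))
  }
  do.call(rbind, lapply(out, function(x) as.data.frame(x, check.names = FALSE)))
}

#' Fit the sightings-driven (v1) occupancy model
#'
#' Fits a Dirichlet distribution to per-individual-quarter regional
#' compositions within each demographic class x season x era stratum.  Strata
#' with no data fall back to the symmetric prior `alpha = 1`; tiny strata
#' (fewer than `minN` compositions) use a conjugate-style estimate
#' (`1 + column sums of compositions`) instead of the fixed-point MLE.
#'
#' @param observations an [ObservationSet].
#' @param individuals individuals data.frame.
#' @param frame a [StudyFrame].
#' @param smoothing additive count smoothing (see [sightingCompositions()]).
#' @param minN minimum stratum size for maximum likelihood.
#' @return a [DirichletOccupancyModel].
#' @export
fitDirichletOccupancy <- function(observations, individuals, frame,
                                  smoothing = 0.5, minN = 5L) {
  comps <- sightingCompositions(observations, individuals, frame, smoothing)
  R <- nRegions(frame)
  regs <- regionLabels(frame)
  classes <- DEMOGRAPHIC_CLASSES
  eras <- c("pre", "post")
  alpha <- array(1, dim = c(length(classes), 4L, 2L, R),
                 dimnames = list(classes, quarterLabels(frame), eras, regs))
  nObs <- array(0L, dim = c(length(classes), 4L, 2L),
                dimnames = list(classes, quarterLabels(frame), eras))
  for (ci in seq_along(classes)) for (q in 1:4) for (ei in 1:2) {
    sel <- comps$class == classes[ci] & comps$quarter == q & comps$era == eras[ei]
    n <- sum(sel)
    nObs[ci, q, ei] <- n
    if (n == 0L) next
    x <- as.matrix(comps[sel, regs, drop = FALSE])
    alpha[ci, q, ei, ] <- if (n < minN) 1 + colSums(x) else fitDirichlet(x)
  }
  new("DirichletOccupancyModel", alpha = alpha, classes = classes,
      frame = frame, nObs = nObs)
}

#' Occupancy under the v1 (Dirichlet) formulation
#'
#' Returns either the stratum's posterior-mean composition (`alpha / sum(alpha)`,
#' the plug-in default) or a single Dirichlet draw.
#'
#' @param model a [DirichletOccupancyModel].
#' @param class demographic class label.
#' @param t step index.
#' @param draw if `TRUE`, sample a composition instead of the mean.
#' @return numeric simplex over regions, with attribute `"draw"` recording
#'   which flavor was returned.
#' @export
occupancyV1 <- function(model, class, t, draw = FALSE) {
  frame <- model@frame
  ci <- match(class, model@classes)
  if (is.na(ci)) stop("unknown demographic class: ", class)
  q <- stepQuarter(frame, t)
  ei <- if (stepEra(frame, t) == "post") 2L else 1L
  a <- model@alpha[ci, q, ei, ]
  z <- if (draw) drop(rDirichlet(1L, a)) else a / sum(a)
  attr(z, "draw") <- draw
  z
}

#' Occupancy for all steps and classes under v1
#'
#' @param model a [DirichletOccupancyModel].
#' @return an [OccupancyDistribution] of plug-in mean compositions.
#' @export
occupancyV1All <- function(model) {
  frame <- model@frame
  T <- nSteps(frame); C <- length(model@classes); R <- nRegions(frame)
  z <- array(NA_real_, c(T, C, R),
             dimnames = list(NULL, model@classes, regionLabels(frame)))
  for (t in seq_len(T)) for (ci in seq_len(C))
    z[t, ci, ] <- occupancyV1(model, model@classes[ci], t)
  new("OccupancyDistribution", z = z, classes = model@classes,
      version = "v1", frame = frame)
}

#' Empirical class proportions by region and season
#'
#' The fraction of sightings contributed by each demographic class within a
#' region-season cell; the v2 default rescaling of the average-individual
#' density distribution.
#'
#' @param observations an [ObservationSet].
#' @param individuals individuals data.frame.
#' @param frame a [StudyFrame].
#' @param maturityAge passed to [demographicClass()].
#' @return array `[class, quarter, region]`, uniform where a cell has no
#'   sightings.
#' @export
classPropsFromSightings <- function(observations, individuals, frame,
                                    maturityAge = 9L) {
  sg <- obsStream(observations, "sightings")
  classes <- DEMOGRAPHIC_CLASSES
  R <- nRegions(frame)
  props <- array(1 / length(classes), c(length(classes), 4L, R),
                 dimnames = list(classes, quarterLabels(frame), regionLabels(frame)))
  if (!nrow(sg)) return(props)
  sexOf <- setNames(individuals$sex, individuals$id)
  byOf <- setNames(individuals$birthYear, individuals$id)
  cls <- mapply(function(id, t) {
    demographicClass(sexOf[[id]], byOf[[id]], stepYear(frame, t), maturityAge)
  }, sg$id, sg$t)
  q <- stepQuarter(frame, sg$t)
  li <- match(sg$region, regionLabels(frame))
  for (qq in 1:4) for (l in seq_len(R)) {
    sel <- q == qq & li == l
    if (any(sel)) {
      counts <- tabulate(match(cls[sel], classes), nbins = length(classes))
      props[, qq, l] <- counts / sum(counts)
    }
  }
  props
}

#' Fill density columns for regions not covered by the density model
#'
#' Densities predicted by the external density-surface model cover US waters
#' only.  Abundance in the uncovered (Canadian) regions is inferred by scaling
#' regional sighting counts with the sightings-to-modeled-abundance ratio of a
#' reference US region: `DSM_can[l,t] = sightings_can[l,t] * DSM_ref[t] /
#' sightings_ref[t]`.
#'
#' @param DSM `R x T` density matrix (rows named by region).
#' @param sightingCounts `R x T` matrix of sighting counts per region-step.
#' @param refRegion name of the covered reference region.
#' @param fillRegions names of the regions to fill.
#' @return the completed density matrix.
#' @export
dsmFillUncovered <- function(DSM, sightingCounts, refRegion = "NEUS",
                             fillRegions = c("GSL", "MAR")) {
  ref <- match(refRegion, rownames(DSM))
  if (is.na(ref)) stop("unknown reference region")
  ratio <- ifelse(sightingCounts[ref, ] > 0,
                  DSM[ref, ] / sightingCounts[ref, ], 0)
  for (l in fillRegions) {
    li <- match(l, rownames(DSM))
    if (is.na(li)) stop("unknown fill region: ", l)
    DSM[li, ] <- sightingCounts[li, ] * ratio
  }
  DSM
}

#' Occupancy under the v2 (density-surface) formulation
#'
#' The relative whale density per region-step is taken to describe the
#' average individual's distribution, rescaled by the class proportions per
#' region-season and renormalized:
#' `z[t, class, l] ~ DSM[l, t] * classProps[class, quarter(t), l]`.
#' Density predictions are only available from `dsmStartYear` onward; earlier
#' steps reuse the per-quarter mean density over `backfillYears`.
#'
#' @param surfaces a [RegionalSurfaces] (its `DSM` assay is used).
#' @param classProps array `[class, quarter, region]`, e.g. from
#'   [classPropsFromSightings()].
#' @param dsmStartYear first year with density predictions.
#' @param backfillYears length-2 year range whose per-quarter mean fills
#'   earlier steps.
#' @return an [OccupancyDistribution].
#' @export
occupancyV2 <- function(surfaces, classProps, dsmStartYear = 2003L,
                        backfillYears = c(2003L, 2009L)) {
  frame <- studyFrame(surfaces)
  DSM <- assay(surfaces, "DSM")
  T <- nSteps(frame); R <- nRegions(frame)
  classes <- dimnames(classProps)[[1]]
  yrs <- stepYear(frame, seq_len(T))
  qidx <- stepQuarter(frame, seq_len(T))
  # backfill: distribution before dsmStartYear assumed equal to the
  # backfill-period mean for the same season
  if (any(yrs < dsmStartYear)) {
    for (q in 1:4) {
      src <- which(qidx == q & yrs >= backfillYears[1] & yrs <= backfillYears[2])
      if (!length(src)) stop("no backfill columns for quarter ", q)
      mcol <- rowMeans(DSM[, src, drop = FALSE])
      DSM[, qidx == q & yrs < dsmStartYear] <- mcol
    }
  }
  z <- array(NA_real_, c(T, length(classes), R),
             dimnames = list(NULL, classes, regionLabels(frame)))
  for (t in seq_len(T)) for (ci in seq_along(classes)) {
    w <- DSM[, t] * classProps[ci, qidx[t], ]
    s <- sum(w)
    if (s <= 0)
      stop("all-zero occupancy weight for class '", classes[ci],
           "' at step ", t)
    z[t, ci, ] <- w / s
  }
  new("OccupancyDistribution", z = z, classes = classes,
      version = "v2", frame = frame)
}

#' Write an occupancy distribution as a long-format table
#'
#' @param occ an [OccupancyDistribution].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeOccupancy <- function(occ, path) {
  d <- dim(occ@z)
  frame <- occ@frame
  out <- data.frame(
    t = rep(seq_len(d[1]), times = d[2] * d[3]),
    class = rep(rep(occ@classes, each = d[1]), times = d[3]),
    region = rep(regionLabels(frame), each = d[1] * d[2]),
    z = as.vector(occ@z)
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
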