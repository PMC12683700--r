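#' @include studyFrame.R
NULL

#' Regional stressor and density surfaces
#'
#' `RegionalSurfaces` holds the five region-by-step surfaces the exposure
#' model consumes, as assays of a [SummarizedExperiment::SummarizedExperiment]
#' (rows = regions, columns = quarterly steps):
#'
#' * `G` — relative entanglement risk (unitless, >= 0),
#' * `entScalar` — landings-derived backcast multiplier for entanglement risk
#'   (unitless, >= 0; 1 in the baseline period),
#' * `AIS` — vessel-traffic strike risk (rescaled to `[0, 1]` before use in
#'   probability equations),
#' * `prey` — prey concentration index (g/m^3, >= 0),
#' * `DSM` — relative whale density from external density-surface predictions
#'   (unitless, >= 0).
#'
#' The [StudyFrame] and the missing-cell fill policy live in `metadata()`.
#'
#' @export
#' @import SummarizedExperiment
#' @importFrom S4Vectors metadata DataFrame SimpleList
setClass("RegionalSurfaces", contains = "SummarizedExperiment")

.SURFACE_VARS <- c("G", "entScalar", "AIS", "prey", "DSM")

setValidity("RegionalSurfaces", function(object) {
  msg <- character()
  want <- .SURFACE_VARS
  if (!all(want %in% assayNames(object)))
    msg <- c(msg, paste("missing assays:",
                        paste(setdiff(want, assayNames(object)), collapse = ", ")))
  fr <- metadata(object)$frame
  if (is.null(fr) || !is(fr, "StudyFrame")) {
    msg <- c(msg, "metadata()$frame must be a StudyFrame")
  } else {
    if (nrow(object) != nRegions(fr) || ncol(object) != nSteps(fr))
      msg <- c(msg, "assay shape does not match the StudyFrame (regions x steps)")
  }
  for (a in intersect(want, assayNames(object))) {
    v <- assay(object, a)
    if (any(!is.finite(v)))
      msg <- c(msg, paste("non-finite values in", a))
    else if (any(v < 0))
      msg <- c(msg, paste("negative values in", a))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn RegionalSurfaces-class Constructor from five `R x T` matrices.
#' @param frame a [StudyFrame].
#' @param G,entScalar,AIS,prey,DSM matrices of dimension
#'   `nRegions(frame) x nSteps(frame)`.
#' @param fillPolicy character tag recording how missing cells were filled
#'   (metadata only).
#' @export
RegionalSurfaces <- function(frame, G, entScalar, AIS, prey, DSM,
                             fillPolicy = "none") {
  R <- nRegions(frame); T <- nSteps(frame)
  mats <- list(G = G, entScalar = entScalar, AIS = AIS, prey = prey, DSM = DSM)
  mats <- lapply(mats, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(R, T)))
      stop("surface matrix must be ", R, " x ", T)
    dimnames(m) <- list(regionLabels(frame), NULL)
    m
  })
  cd <- DataFrame(
    t = seq_len(T),
    year = stepYear(frame, seq_len(T)),
    quarter = quarterLabels(frame)[stepQuarter(frame, seq_len(T))]
  )
  se <- SummarizedExperiment(
    assays = mats,
    rowData = DataFrame(region = regionLabels(frame)),
    colData = cd,
    metadata = list(frame = frame, fillPolicy = fillPolicy)
  )
  out <- new("RegionalSurfaces", se)
  validObject(out)
  out
}

#' @rdname studyFrame
#' @export
setMethod("studyFrame", "RegionalSurfaces", function(x) metadata(x)$frame)

#' @rdname nRegions
#' @export
setMethod("nRegions", "RegionalSurfaces", function(x) nrow(x))

#' @rdname nSteps
#' @export
setMethod("nSteps", "RegionalSurfaces", function(x) ncol(x))

setMethod("show", "RegionalSurfaces", function(object) {
  cat("RegionalSurfaces:", nrow(object), "regions x", ncol(object), "steps\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  cat("  fill policy:", metadata(object)$fillPolicy, "\n")
})

#' Read stressor surfaces from a long-format table
#'
#' Reads a CSV with columns `region, year, quarter, variable, value` into a
#' [RegionalSurfaces] object.  Missing cells are filled according to
#' `fillPolicy`:
#'
#' * `"region-season mean"` (default): the mean of the same region and season
#'   over the years where the cell is observed (climatology);
#' * `"error"`: any missing cell is an error.
#'
#' The applied policy is recorded in `metadata()$fillPolicy`.
#'
#' @param path path to the CSV file.
#' @param frame a [StudyFrame]; region and quarter labels must match.
#' @param fillPolicy see Details.
#' @return a [RegionalSurfaces].
#' @export
readSurfaces <- function(path, frame, fillPolicy = c("region-season mean", "error")) {
  fillPolicy <- match.arg(fillPolicy)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "year", "quarter", "variable", "value")
  if (!all(need %in% names(tab)))
    stop("surface table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(tab$region), regionLabels(frame))
  if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(tab$quarter), quarterLabels(frame))
  if (length(bad)) stop("unknown quarter label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(tab$variable), .SURFACE_VARS)
  if (length(bad)) stop("unknown variable(s): ", paste(bad, collapse = ", "))
  neg <- which(tab$value < 0)
  if (length(neg)) {
    b <- tab[neg[1L], ]
    stop(sprintf("negative value for (%s, %d, %s, %s)",
                 b$region, b$year, b$quarter, b$variable))
  }
  key <- paste(tab$region, tab$year, tab$quarter, tab$variable)
  if (anyDuplicated(key))
    stop("duplicate cell: ", key[which(duplicated(key))[1L]])

  R <- nRegions(frame); T <- nSteps(frame)
  li <- match(tab$region, regionLabels(frame))
  ti <- stepIndex(frame, tab$year, tab$quarter)
  mats <- list()
  nFilled <- 0L
  for (v in .SURFACE_VARS) {
    m <- matrix(NA_real_, R, T)
    sel <- tab$variable == v
    m[cbind(li[sel], ti[sel])] <- tab$value[sel]
    if (anyNA(m)) {
      if (fillPolicy == "error") stop("missing cells for variable ", v)
      qidx <- stepQuarter(frame, seq_len(T))
      for (q in 1:4) {
        cols <- which(qidx == q)
        sub <- m[, cols, drop = FALSE]
        rsMean <- rowMeans(sub, na.rm = TRUE)
        for (l in seq_len(R)) {
          miss <- is.na(sub[l, ])
          if (any(miss)) {
            if (!is.finite(rsMean[l]))
              stop("variable ", v, ": region ", regionLabels(frame)[l],
                   " season ", quarterLabels(frame)[q],
                   " has no observed cells to fill from")
            m[l, cols[miss]] <- rsMean[l]
            nFilled <- nFilled + sum(miss)
          }
        }
      }
    }
    mats[[v]] <- m
  }
  out <- RegionalSurfaces(frame, mats$G, mats$entScalar, mats$AIS, mats$prey,
                          mats$DSM, fillPolicy = fillPolicy)
  metadata(out)$nFilled <- nFilled
  out
}

#' Write stressor surfaces to a long-format table
#'
#' Inverse of [readSurfaces()]; writes `region, year, quarter, variable, value`.
#'
#' @param x a [RegionalSurfaces].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSurfaces <- function(x, path) {
  frame <- studyFrame(x)
  T <- nSteps(frame)
  yr <- stepYear(frame, seq_len(T))
  qu <- quarterLabels(frame)[stepQuarter(frame, seq_len(T))]
  rows <- lapply(.SURFACE_VARS, function(v) {
    m <- assay(x, v)
    data.frame(
      region = rep(regionLabels(frame), times = T),
      year = rep(yr, each = nRegions(frame)),
      quarter = rep(qu, each = nRegions(frame)),
      variable = v,
      value = as.vector(m)
    )
  })
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
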