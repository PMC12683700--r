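#' Spatio-temporal frame for the multi-stressor model
#'
#' A `StudyFrame` fixes the discretization that every other object in the
#' package shares: an ordered set of regional polygons, the four three-month
#' seasons, an inclusive range of years, and the year at which the
#' distributional era changes (pre/post shift in habitat use).  Time is
#' indexed by quarterly steps `t = 1, ..., T` with `T = 4 * nYears`; the
#' Dec–Feb season is assigned to the calendar year containing January.
#'
#' @slot regions character vector of region labels (length >= 2).
#' @slot quarters character vector of the four season labels.
#' @slot years integer vector of consecutive years.
#' @slot eraBreakYear single integer; steps in years `>= eraBreakYear` belong
#'   to the post era.
#'
#' @examples
#' fr <- StudyFrame()
#' nSteps(fr)            # 4 x 50 = 200
#' stepYear(fr, 5)       # second year, first quarter
#' @export
setClass("StudyFrame",
  representation(
    regions = "character",
    quarters = "character",
    years = "integer",
    eraBreakYear = "integer"
  )
)

setValidity("StudyFrame", function(object) {
  msg <- character()
  if (length(object@regions) < 2L)
    msg <- c(msg, "need at least 2 regions")
  if (anyDuplicated(object@regions))
    msg <- c(msg, "duplicated region labels")
  if (length(object@quarters) != 4L)
    msg <- c(msg, "exactly 4 quarterly seasons are required")
  if (length(object@years) < 1L || any(diff(object@years) != 1L))
    msg <- c(msg, "years must be a consecutive integer range")
  if (length(object@eraBreakYear) != 1L)
    msg <- c(msg, "eraBreakYear must be a single year")
  if (length(msg)) msg else TRUE
})

#' @describeIn StudyFrame-class Constructor.  Defaults reproduce the study
#'   system: 7 regions (SEUS, MIDA, SNE, CCB, NEUS, GSL, MAR), seasons
#'   Dec–Feb through Sep–Nov, years 1970–2019, era break 2010.
#' @param regions,quarters,years,eraBreakYear see slots.
#' @export
StudyFrame <- function(regions = c("SEUS", "MIDA", "SNE", "CCB", "NEUS", "GSL", "MAR"),
                       quarters = c("Dec-Feb", "Mar-May", "Jun-Aug", "Sep-Nov"),
                       years = 1970:2019,
                       eraBreakYear = 2010L) {
  new("StudyFrame",
    regions = as.character(regions), quarters = as.character(quarters),
    years = as.integer(years), eraBreakYear = as.integer(eraBreakYear))
}

#' @rdname nRegions
#' @export
setMethod("nRegions", "StudyFrame", function(x) length(x@regions))

#' @rdname nSteps
#' @export
setMethod("nSteps", "StudyFrame", function(x) 4L * length(x@years))

setMethod("show", "StudyFrame", function(object) {
  cat("StudyFrame:", length(object@regions), "regions x",
      nSteps(object), "quarterly steps\n")
  cat("  regions:", paste(object@regions, collapse = ", "), "\n")
  cat("  years:", min(object@years), "-", max(object@years),
      " (era break ", object@eraBreakYear, ")\n", sep = "")
})

#' Regions of a StudyFrame
#' @param frame a [StudyFrame].
#' @return character vector of region labels.
#' @export
regionLabels <- function(frame) frame@regions

#' Season labels of a StudyFrame
#' @param frame a [StudyFrame].
#' @return character vector of length 4.
#' @export
quarterLabels <- function(frame) frame@quarters

#' Years covered by a StudyFrame
#' @param frame a [StudyFrame].
#' @return integer vector.
#' @export
frameYears <- function(frame) frame@years

#' Era break year of a StudyFrame
#' @param frame a [StudyFrame].
#' @return integer scalar.
#' @export
eraBreakYear <- function(frame) frame@eraBreakYear

#' Map a quarterly step to its calendar year
#'
#' @param frame a [StudyFrame].
#' @param t integer step index (vectorized), 1-based.
#' @return integer vector of years.
#' @export
stepYear <- function(frame, t) {
  stopifnot(all(t >= 1L), all(t <= nSteps(frame)))
  frame@years[(as.integer(t) - 1L) %/% 4L + 1L]
}

#' Map a quarterly step to its season index
#'
#' @param frame a [StudyFrame].
#' @param t integer step index (vectorized).
#' @return integer vector in 1..4 (1 = first season label, Dec–Feb by default).
#' @export
stepQuarter <- function(frame, t) {
  stopifnot(all(t >= 1L), all(t <= nSteps(frame)))
  (as.integer(t) - 1L) %% 4L + 1L
}

#' Map (year, quarter) to the step index
#'
#' @param frame a [StudyFrame].
#' @param year integer year(s) within the frame.
#' @param quarter season index (1..4) or season label.
#' @return integer step index.
#' @export
stepIndex <- function(frame, year, quarter) {
  if (is.character(quarter)) {
    quarter <- match(quarter, frame@quarters)
    if (anyNA(quarter)) stop("unknown quarter label")
  }
  yi <- match(as.integer(year), frame@years)
  if (anyNA(yi)) stop("year outside the study frame: ", year[which(is.na(yi))[1L]])
  stopifnot(all(quarter >= 1L), all(quarter <= 4L))
  (yi - 1L) * 4L + as.integer(quarter)
}

#' Era of a step (pre/post distribution shift)
#'
#' @param frame a [StudyFrame].
#' @param t integer step index (vectorized).
#' @return character vector, `"pre"` or `"post"`.
#' @export
stepEra <- function(frame, t) {
  ifelse(stepYear(frame, t) >= frame@eraBreakYear, "post", "pre")
}

#' Steps belonging to a given year
#' @param frame a [StudyFrame].
#' @param year integer year.
#' @return the 4 step indices of that year.
#' @export
yearSteps <- function(frame, year) {
  yi <- match(as.integer(year), frame@years)
  if (anyNA(yi)) stop("year outside the study frame")
  (yi - 1L) * 4L + 1:4
}
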