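#' @import methods
#' @importFrom stats rnorm runif rbinom rpois rgamma rbeta dnorm pnorm qnorm
#'   quantile median sd var coef lm plogis qlogis setNames aggregate complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

#' Re-exported accessors
#'
#' [SummarizedExperiment::assay()], [SummarizedExperiment::assayNames()] and
#' [S4Vectors::metadata()] are re-exported so [RegionalSurfaces] objects can
#' be inspected without attaching the container packages.
#'
#' @importFrom SummarizedExperiment assay assayNames
#' @importFrom S4Vectors metadata
#' @export assay assayNames metadata
#' @name reexports
#' @aliases assay assayNames metadata
NULL

#' Study frame accessor
#'
#' Returns the [StudyFrame] that an object was built against.
#'
#' @param x an object carrying a study frame.
#' @return a [StudyFrame].
#' @export
setGeneric("studyFrame", function(x) standardGeneric("studyFrame"))

#' Number of regions
#' @param x an object with a regional dimension.
#' @return integer scalar.
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' Number of quarterly time steps
#' @param x an object with a time dimension.
#' @return integer scalar.
#' @export
setGeneric("nSteps", function(x) standardGeneric("nSteps"))
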