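#' Enumerated event classes
#'
#' Entanglement events carry a severity class and vessel-strike events an
#' injury class; all other labels are rejected at read time.
#'
#' @name eventClasses
NULL

#' @rdname eventClasses
#' @export
SEVERITY_LEVELS <- c("minor", "moderate", "severe")

#' @rdname eventClasses
#' @export
INJURY_LEVELS <- c("superficial", "shallow", "deep", "blunt")

#' Longitudinal observations of a whale population
#'
#' An `ObservationSet` bundles the detection-limited data streams of the
#' sightings database: individual sightings with region, ordinal visual health
#' assessment (VHA) scores, photogrammetric length measurements, entanglement
#' and vessel-strike event records, annual calving outcomes for adult females,
#' and recovered-carcass death records.
#'
#' @slot sightings data.frame `(id, t, region)`.
#' @slot vha data.frame `(id, t, variable, score)`; `variable` indexes the
#'   ordinal health variables, `score` the observed category.
#' @slot lengths data.frame `(id, t, length, platform)` with `length` in
#'   meters and `platform` in `c("aircraft", "drone")`.
#' @slot entanglements data.frame `(id, t, severity, gearSteps)`; `t` is the
#'   step the event occurred, `gearSteps` the number of steps gear was carried
#'   (>= 1, counting the event step).
#' @slot strikes data.frame `(id, t, injury)`.
#' @slot calvings data.frame `(id, year, calved)`.
#' @slot deaths data.frame `(id, t, causeKnown, cause)`.
#' @export
setClass("ObservationSet",
  representation(
    sightings = "data.frame", vha = "data.frame", lengths = "data.frame",
    entanglements = "data.frame", strikes = "data.frame",
    calvings = "data.frame", deaths = "data.frame"
  )
)

.emptyDf <- function(...) {
  cols <- list(...)
  as.data.frame(lapply(cols, function(cl) vector(cl, 0L)),
                stringsAsFactors = FALSE)
}

#' @describeIn ObservationSet-class Constructor; any stream may be omitted.
#' @param sightings,vha,lengths,entanglements,strikes,calvings,deaths see slots.
#' @export
ObservationSet <- function(
    sightings = .emptyDf(id = "character", t = "integer", region = "character"),
    vha = .emptyDf(id = "character", t = "integer", variable = "integer", score = "integer"),
    lengths = .emptyDf(id = "character", t = "integer", length = "numeric", platform = "character"),
    entanglements = .emptyDf(id = "character", t = "integer", severity = "character", gearSteps = "integer"),
    strikes = .emptyDf(id = "character", t = "integer", injury = "character"),
    calvings = .emptyDf(id = "character", year = "integer", calved = "integer"),
    deaths = .emptyDf(id = "character", t = "integer", causeKnown = "logical", cause = "character")) {
  new("ObservationSet",
    sightings = sightings, vha = vha, lengths = lengths,
    entanglements = entanglements, strikes = strikes,
    calvings = calvings, deaths = deaths)
}

setValidity("ObservationSet", function(object) {
  msg <- character()
  if (nrow(object@entanglements)) {
    bad <- setdiff(unique(object@entanglements$severity), SEVERITY_LEVELS)
    if (length(bad))
      msg <- c(msg, paste("unknown entanglement severity:", paste(bad, collapse = ", ")))
    if (any(object@entanglements$gearSteps < 1L))
      msg <- c(msg, "gearSteps must be >= 1")
  }
  if (nrow(object@strikes)) {
    bad <- setdiff(unique(object@strikes$injury), INJURY_LEVELS)
    if (length(bad))
      msg <- c(msg, paste("unknown strike injury:", paste(bad, collapse = ", ")))
  }
  if (nrow(object@lengths) && any(object@lengths$length <= 0))
    msg <- c(msg, "photogrammetric lengths must be positive")
  if (nrow(object@vha) && any(object@vha$score < 1L))
    msg <- c(msg, "ordinal scores must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ObservationSet", function(object) {
  cat("ObservationSet:\n")
  cat("  sightings:", nrow(object@sightings),
      " vha:", nrow(object@vha),
      " lengths:", nrow(object@lengths), "\n")
  cat("  entanglements:", nrow(object@entanglements),
      " strikes:", nrow(object@strikes),
      " calvings:", nrow(object@calvings),
      " deaths:", nrow(object@deaths), "\n")
})

#' Accessors for ObservationSet streams
#'
#' @param x an [ObservationSet].
#' @param stream one of `"sightings"`, `"vha"`, `"lengths"`,
#'   `"entanglements"`, `"strikes"`, `"calvings"`, `"deaths"`.
#' @return the requested data.frame.
#' @export
obsStream <- function(x, stream = c("sightings", "vha", "lengths",
                                    "entanglements", "strikes",
                                    "calvings", "deaths")) {
  stream <- match.arg(stream)
  slot(x, stream)
}

#' Demographic class of an individual at a year
#'
#' Classes are calf (age 0), juvenile (ages 1 to maturity-1) and adult male /
#' adult female from the maturity age onward.  Individuals with unknown birth
#' year are treated as adults (their age covariate stays missing; see
#' [readIndividuals()]).
#'
#' @param sex `"F"` or `"M"`.
#' @param birthYear integer or `NA`.
#' @param year integer calendar year.
#' @param maturityAge age (years) at which juveniles become adults.
#' @return one of `"calf"`, `"juvenile"`, `"adult female"`, `"adult male"`.
#' @export
demographicClass <- function(sex, birthYear, year, maturityAge = 9L) {
  adult <- ifelse(sex == "F", "adult female", "adult male")
  if (is.na(birthYear)) return(adult)
  age <- year - birthYear
  if (age < 0L) stop("class requested before birth")
  if (age == 0L) "calf"
  else if (age < maturityAge) "juvenile"
  else adult
}

.readOrEmpty <- function(path, empty) {
  if (file.exists(path)) {
    out <- read.csv(path, stringsAsFactors = FALSE)
    # restore types on empty reads
    if (!nrow(out)) return(empty)
    out
  } else empty
}

#' Read a directory of individual/observation tables
#'
#' Expects per-stream CSVs (`individuals.csv`, `sightings.csv`, `vha.csv`,
#' `lengths.csv`, `entanglements.csv`, `strikes.csv`, `calvings.csv`,
#' `deaths.csv`) as written by [writeDataset()].  Missing stream files are
#' treated as empty.  Consistency checks: no sighting, score or measurement
#' after a recorded death; event labels within the enumerated classes.
#' Unknown birth years are passed through as `NA`, never imputed.
#'
#' @param dir directory containing the CSV files.
#' @return list with elements `individuals` (data.frame
#'   `(id, sex, birthYear, deathStep)`) and `observations` ([ObservationSet]).
#' @export
readIndividuals <- function(dir) {
  ind <- read.csv(file.path(dir, "individuals.csv"), stringsAsFactors = FALSE)
  need <- c("id", "sex", "birthYear", "deathStep")
  if (!all(need %in% names(ind)))
    stop("individuals.csv must have columns: ", paste(need, collapse = ", "))
  ind$id <- as.character(ind$id)
  proto <- ObservationSet()
  obs <- ObservationSet(
    sightings = .readOrEmpty(file.path(dir, "sightings.csv"), proto@sightings),
    vha = .readOrEmpty(file.path(dir, "vha.csv"), proto@vha),
    lengths = .readOrEmpty(file.path(dir, "lengths.csv"), proto@lengths),
    entanglements = .readOrEmpty(file.path(dir, "entanglements.csv"), proto@entanglements),
    strikes = .readOrEmpty(file.path(dir, "strikes.csv"), proto@strikes),
    calvings = .readOrEmpty(file.path(dir, "calvings.csv"), proto@calvings),
    deaths = .readOrEmpty(file.path(dir, "deaths.csv"), proto@deaths)
  )
  for (s in c("sightings", "vha", "lengths", "entanglements", "strikes",
              "calvings", "deaths")) {
    df <- slot(obs, s)
    if (nrow(df)) slot(obs, s)$id <- as.character(df$id)
  }
  validObject(obs)
  validateHistories(ind, obs)
  list(individuals = ind, observations = obs)
}

#' Check individual histories for internal consistency
#'
#' @param individuals data.frame `(id, sex, birthYear, deathStep)`.
#' @param observations an [ObservationSet].
#' @return `TRUE` invisibly; inconsistencies raise errors naming the record.
#' @export
validateHistories <- function(individuals, observations) {
  death <- setNames(individuals$deathStep, individuals$id)
  for (s in c("sightings", "vha", "lengths")) {
    df <- slot(observations, s)
    if (!nrow(df)) next
    d <- death[df$id]
    bad <- which(!is.na(d) & df$t > d)
    if (length(bad))
      stop(sprintf("%s record for '%s' at step %d is after its death step %d",
                   s, df$id[bad[1L]], df$t[bad[1L]], d[bad[1L]]))
  }
  ids <- unique(c(observations@sightings$id, observations@vha$id,
                  observations@lengths$id, observations@entanglements$id,
                  observations@strikes$id, observations@calvings$id,
                  observations@deaths$id))
  unknown <- setdiff(ids, individuals$id)
  if (length(unknown))
    stop("observation streams mention unknown individual(s): ",
         paste(head(unknown, 3L), collapse = ", "))
  invisible(TRUE)
}

#' Write a dataset directory
#'
#' Writes the per-stream CSVs read back by [readIndividuals()], plus the
#' surfaces table when given.  Files are written with fixed column order so a
#' seeded pipeline rerun is byte-identical.
#'
#' @param individuals data.frame `(id, sex, birthYear, deathStep)`.
#' @param observations an [ObservationSet].
#' @param dir output directory (created if needed).
#' @param surfaces optional [RegionalSurfaces], written to `surfaces.csv`.
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(individuals, observations, dir, surfaces = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(individuals, file.path(dir, "individuals.csv"),
            row.names = FALSE, quote = FALSE)
  for (s in c("sightings", "vha", "lengths", "entanglements", "strikes",
              "calvings", "deaths")) {
    write.csv(slot(observations, s), file.path(dir, paste0(s, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  if (!is.null(surfaces)) writeSurfaces(surfaces, file.path(dir, "surfaces.csv"))
  invisible(dir)
}

#' Validate a dataset directory
#'
#' Reads every table in `dir` and runs all type and history invariants;
#' the entry point behind the `validate-data` pipeline stage.
#'
#' @param dir dataset directory.
#' @param frame a [StudyFrame] used to validate `surfaces.csv` when present.
#' @return `TRUE` invisibly if everything passes.
#' @export
validateDataset <- function(dir, frame = StudyFrame()) {
  readIndividuals(dir)
  sp <- file.path(dir, "surfaces.csv")
  if (file.exists(sp)) readSurfaces(sp, frame)
  invisible(TRUE)
}
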