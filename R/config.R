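#' Default run configuration
#'
#' The resolved configuration controls the study frame, prior supports, MCMC
#' settings, and projection scenario defaults.  Every key here is the complete
#' set of valid keys: [loadConfig()] fails closed on anything it does not
#' recognize.
#'
#' @return nested list of defaults.
#' @export
defaultConfig <- function() {
  list(
    frame = list(
      regions = c("SEUS", "MIDA", "SNE", "CCB", "NEUS", "GSL", "MAR"),
      quarters = c("Dec-Feb", "Mar-May", "Jun-Aug", "Sep-Nov"),
      start_year = 1970L,
      end_year = 2019L,
      era_break_year = 2010L
    ),
    occupancy = list(
      version = "v1",
      smoothing = 0.5,          # additive count smoothing per region
      dsm_start_year = 2003L,   # density predictions available from here
      dsm_backfill_years = c(2003L, 2009L),
      canadian_regions = c("GSL", "MAR"),
      reference_us_region = "NEUS"
    ),
    exposure = list(
      iota1_max = 0.1,          # upper bound of the uniform support for iota1
      iota2_max = 0.1,
      strike_reference_year = 2019L,
      ent_scalar_from_year = 2015L,  # entScalar = 1 from this year onward
      northern_us_regions = c("NEUS", "CCB", "SNE")
    ),
    health = list(
      floor = 0.01,             # clamp floor for latent health
      ceiling = 100,
      sigma_h = 2,
      prey_quarter = "Jun-Aug"  # season in which the annual prey effect applies
    ),
    growth = list(
      birth_year_ref = 1980L,
      maturity_age = 9L
    ),
    vital = list(
      h_ref = 70,
      calving_gap_years = 2L,   # full calendar years between calvings
      maturity_age = 9L
    ),
    observation = list(
      n_vha_vars = 4L,
      n_vha_categories = 3L
    ),
    mcmc = list(
      chains = 2L,
      iterations = 1000L,
      warmup = 500L,
      thin = 1L
    ),
    scenario = list(
      entanglement_multiplier = 1,
      prey_regime = "historical",
      length_regime = "stabilize",
      horizon_years = 100L,
      n_draws = 1000L
    )
  )
}

.mergeConfig <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user))
    stop("config section '", path, "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s) ", paste0("'", path, unknown, "'", collapse = ", "),
         "; valid keys here: ", paste(names(defaults), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- .mergeConfig(defaults[[k]], user[[k]],
                                    path = paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration file, overlays it on [defaultConfig()], and
#' rejects unknown keys (fail-closed, so typos like `era_brake_year` raise an
#' error listing the valid keys).  With `path = NULL` the defaults are
#' returned unchanged.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param quiet suppress echoing the resolved configuration.
#' @return resolved configuration list with attribute `"source"`.
#' @export
loadConfig <- function(path = NULL, quiet = TRUE) {
  cfg <- defaultConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- .mergeConfig(cfg, user)
  }
  attr(cfg, "source") <- if (is.null(path)) "<defaults>" else path
  if (!quiet) {
    message("resolved configuration (", attr(cfg, "source"), "):")
    message(yaml::as.yaml(cfg))
  }
  cfg
}

#' Build a StudyFrame from a configuration
#'
#' @param config a configuration list from [loadConfig()].
#' @return a [StudyFrame].
#' @export
configFrame <- function(config) {
  StudyFrame(
    regions = config$frame$regions,
    quarters = config$frame$quarters,
    years = config$frame$start_year:config$frame$end_year,
    eraBreakYear = config$frame$era_break_year
  )
}
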