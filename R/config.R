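#' Default model configuration
#'
#' The default parameters of the screening model: radiologist operating
#' points on the abbreviated (90%/92%) and full (92%/95%) protocols, protocol
#' durations (262 s abbreviated, 776 s full), screening malignancy rate
#' (1.46%), AI operating point fixed at 80%/80% unless swept, and the
#' literature agreement-accuracy interval 75%-91% (mean 83.4%, n = 14) used
#' for the "most likely" band. The full-protocol radiologist performance is
#' carried for completeness but does not enter the adaptive limit formulas.
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    rad_sensitivity_abbr = 0.90,
    rad_specificity_abbr = 0.92,
    rad_sensitivity_full = 0.92,
    rad_specificity_full = 0.95,
    ai_sensitivity = 0.80,
    ai_specificity = 0.80,
    t_abbr = 262,
    t_full = 776,
    prevalence = 0.0146,
    band_interval = c(0.75, 0.91),
    band_mode = "emulation",
    cohort_size = 1e6,
    seed = 1L
  ), class = "run_config")
}

config_fraction_keys <- c(
  "rad_sensitivity_abbr", "rad_specificity_abbr",
  "rad_sensitivity_full", "rad_specificity_full",
  "ai_sensitivity", "ai_specificity", "prevalence"
)

# Table 1 prints percentages; accept either convention and normalise to
# fractions. Values in (1, 100] are read as percentages.
normalize_fraction <- function(x, key) {
  if (!is.numeric(x) || anyNA(x)) {
    stop("config key '", key, "' must be numeric", call. = FALSE)
  }
  x <- ifelse(x > 1 & x <= 100, x / 100, x)
  if (any(x < 0 | x > 1)) {
    stop("config key '", key, "' out of range: must be a fraction in [0, 1] ",
         "or a percentage in (1, 100]", call. = FALSE)
  }
  x
}

#' Load a run configuration from a JSON file
#'
#' Reads a JSON configuration, validates every key, fills absent keys with
#' the defaults of [default_config()], and rejects unknown keys. Sensitivity,
#' specificity and prevalence entries may be given either as fractions
#' (0.92) or as percentages (92), matching how such parameters are usually
#' printed; percentages are normalised to fractions on load.
#'
#' @param path Path to a JSON file; an empty file or empty object yields the
#'   full default configuration.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  raw <- if (!nzchar(trimws(txt))) list() else
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  if (!is.list(raw)) stop("config must be a JSON object", call. = FALSE)
  cfg <- default_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; known keys: ", paste(names(cfg), collapse = ", "), call. = FALSE)
  }
  for (key in names(raw)) cfg[[key]] <- raw[[key]]
  validate_config(cfg)
}

validate_config <- function(cfg) {
  for (key in config_fraction_keys) {
    cfg[[key]] <- normalize_fraction(cfg[[key]], key)
    check_probability(cfg[[key]], key)
  }
  check_positive(cfg$t_abbr, "t_abbr")
  check_positive(cfg$t_full, "t_full")
  bi <- as.numeric(cfg$band_interval)
  if (length(bi) != 2L || anyNA(bi) || bi[1] > bi[2]) {
    stop("'band_interval' must be two ordered numbers [low, high]",
         call. = FALSE)
  }
  cfg$band_interval <- normalize_fraction(bi, "band_interval")
  if (!cfg$band_mode %in% c("emulation", "restricted_limits")) {
    stop("'band_mode' must be one of: emulation, restricted_limits",
         call. = FALSE)
  }
  if (!is.null(cfg$cohort_size)) {
    if (!is.numeric(cfg$cohort_size) || cfg$cohort_size < 1 ||
        cfg$cohort_size != floor(cfg$cohort_size)) {
      stop("'cohort_size' must be a positive integer", call. = FALSE)
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Write a run configuration to JSON
#'
#' Serialises a configuration so that [load_config()] round-trips it
#' exactly. Used by the CLI to echo the effective configuration into every
#' output directory for provenance.
#'
#' @param cfg A `run_config` list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

config_cohort <- function(cfg, size = NULL) cohort(cfg$prevalence, size)
config_timing <- function(cfg) protocol_timing(cfg$t_abbr, cfg$t_full)
config_rad_op <- function(cfg) {
  operating_point(cfg$rad_sensitivity_abbr, cfg$rad_specificity_abbr)
}
config_ai_op <- function(cfg) {
  operating_point(cfg$ai_sensitivity, cfg$ai_specificity)
}
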