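sweep_parameters <- c("ai_sensitivity", "ai_specificity",
                      "rad_sensitivity_abbr", "rad_specificity_abbr",
                      "t_full", "t_abbr")

#' Specify a one-at-a-time parameter sweep
#'
#' One model parameter is swept over an ordered grid while all others are
#' held at the configuration values (defaults: the standard screening
#' parameters of [default_config()], with the AI operating point fixed at
#' 80%/80% where not swept). Probability parameters default to 1001 uniform
#' points on \eqn{[0, 1]}; durations to 1001 points on half-to-double the
#' default duration.
#'
#' @param parameter One of `"ai_sensitivity"`, `"ai_specificity"`,
#'   `"rad_sensitivity_abbr"`, `"rad_specificity_abbr"`, `"t_full"`,
#'   `"t_abbr"`.
#' @param grid Strictly increasing numeric grid within the parameter's
#'   domain; `NULL` for the default grid.
#' @param config A `run_config` (see [default_config()], [load_config()]).
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(parameter, grid = NULL, config = default_config()) {
  parameter <- match.arg(parameter, sweep_parameters)
  config <- validate_config(config)
  is_duration <- parameter %in% c("t_full", "t_abbr")
  if (is.null(grid)) {
    grid <- if (is_duration) {
      seq(0.5 * config[[parameter]], 2 * config[[parameter]], length.out = 1001L)
    } else {
      seq(0, 1, length.out = 1001L)
    }
  }
  if (!is.numeric(grid) || length(grid) < 1L || anyNA(grid)) {
    stop("'grid' must be a non-empty numeric vector", call. = FALSE)
  }
  if (length(grid) > 1L && any(diff(grid) <= 0)) {
    stop("'grid' must be strictly increasing", call. = FALSE)
  }
  bad <- if (is_duration) grid[grid <= 0] else grid[grid < 0 | grid > 1]
  if (length(bad)) {
    stop("grid value ", bad[1], " outside the domain of '", parameter, "'",
         call. = FALSE)
  }
  structure(list(parameter = parameter, grid = grid, config = config),
            class = "sweep_spec")
}

# All strategy metrics for one fully specified configuration.
evaluate_strategies <- function(cfg) {
  coh <- config_cohort(cfg)
  timing <- suppressWarnings(config_timing(cfg))
  rad <- confusion_rates(config_rad_op(cfg), coh)
  ad <- adaptive_bounds(config_rad_op(cfg), config_ai_op(cfg), coh, timing)
  full <- metrics_full_only(timing)
  c(rr_abbr_only = rr_abbreviated_only(rad),
    rr_full_only = full$rr,
    rr_adaptive_lower = unname(ad$rr[1]),
    rr_adaptive_upper = unname(ad$rr[2]),
    epd_abbr_only = epd_abbreviated_only(rad, timing),
    epd_full_only = full$epd,
    epd_adaptive_lower = unname(ad$epd[1]),
    epd_adaptive_upper = unname(ad$epd[2]))
}

substitute_parameter <- function(cfg, parameter, value) {
  cfg[[parameter]] <- value
  cfg
}

#' Run a parameter sweep
#'
#' Evaluates the abbreviated-only, full-only and adaptive (lower/upper
#' limit) strategies at every grid value of a [sweep_spec()]. Deterministic:
#' identical specs give identical results.
#'
#' @param spec A [sweep_spec()].
#' @param normalize Also emit EPD columns expressed as a percentage of the
#'   (per-row) full-protocol duration, as used for duration sweeps.
#' @return A `sweep_result`: a data.frame with one row per grid value and
#'   columns `value`, `rr_abbr_only`, `rr_full_only`, `rr_adaptive_lower`,
#'   `rr_adaptive_upper`, `epd_abbr_only`, `epd_full_only`,
#'   `epd_adaptive_lower`, `epd_adaptive_upper` (seconds), plus
#'   `epd_*_pct_full` percentage columns when `normalize = TRUE`. The spec is
#'   attached as attribute `"spec"`.
#' @examples
#' res <- run_sweep(sweep_spec("ai_specificity", grid = c(0.5, 0.8, 1)))
#' res$rr_adaptive_lower
#' @export
run_sweep <- function(spec, normalize = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- vapply(spec$grid, function(v) {
    evaluate_strategies(substitute_parameter(spec$config, spec$parameter, v))
  }, numeric(8L))
  out <- data.frame(value = spec$grid, t(rows))
  if (normalize) {
    t_full <- if (spec$parameter == "t_full") spec$grid else spec$config$t_full
    for (col in c("epd_abbr_only", "epd_full_only",
                  "epd_adaptive_lower", "epd_adaptive_upper")) {
      out[[paste0(col, "_pct_full")]] <- 100 * out[[col]] / t_full
    }
  }
  attr(out, "spec") <- spec
  class(out) <- c("sweep_result", "data.frame")
  out
}

# Analytic curve evaluator used for breakpoint refinement: the named result
# column as a function of the swept parameter.
curve_function <- function(spec, curve) {
  base_cols <- c("rr_abbr_only", "rr_full_only", "rr_adaptive_lower",
                 "rr_adaptive_upper", "epd_abbr_only", "epd_full_only",
                 "epd_adaptive_lower", "epd_adaptive_upper")
  pct <- grepl("_pct_full$", curve)
  col <- sub("_pct_full$", "", curve)
  if (!col %in% base_cols) {
    stop("unknown curve '", curve, "'; expected one of: ",
         paste(base_cols, collapse = ", "), " (optionally with _pct_full)",
         call. = FALSE)
  }
  force(spec)
  function(x) {
    m <- evaluate_strategies(substitute_parameter(spec$config, spec$parameter, x))
    y <- unname(m[[col]])
    if (pct) {
      t_full <- if (spec$parameter == "t_full") x else spec$config$t_full
      y <- 100 * y / t_full
    }
    y
  }
}

#' Locate the kinks of a piecewise-linear sweep curve
#'
#' Every metric curve produced by [run_sweep()] is piecewise linear in the
#' swept parameter; the regime boundaries of the model are the points where
#' the slope changes. Candidate kinks are found where the per-grid-step
#' slope change (second difference divided by the grid step) exceeds
#' `tolerance`, then each is refined by bisection on the analytic curve to
#' better than `1e-9` in the parameter.
#'
#' @param result A `sweep_result` from [run_sweep()] on a uniform grid.
#' @param curve Result column to analyse, e.g. `"rr_adaptive_lower"`.
#' @param tolerance Slope-change threshold per grid step; defaults to `1e-8`
#'   for probability curves and `1e-5` for duration (seconds/percent) curves.
#' @return Sorted numeric vector of breakpoint locations (possibly empty).
#' @examples
#' res <- run_sweep(sweep_spec("ai_sensitivity"))
#' detect_breakpoints(res, "rr_adaptive_lower")  # 0.9
#' @export
detect_breakpoints <- function(result, curve, tolerance = NULL) {
  stopifnot(inherits(result, "sweep_result"))
  spec <- attr(result, "spec")
  x <- result$value
  if (length(x) < 3L) stop("need at least 3 grid points", call. = FALSE)
  h <- diff(x)
  if (max(h) - min(h) > 1e-9 * max(abs(x))) {
    stop("grid is not uniform; breakpoint detection requires a uniform grid",
         call. = FALSE)
  }
  if (is.null(tolerance)) {
    tolerance <- if (grepl("^epd", curve)) 1e-5 else 1e-8
  }
  y <- result[[curve]]
  if (is.null(y)) stop("no column '", curve, "' in sweep result", call. = FALSE)
  step <- mean(h)
  slope_change <- abs(diff(y, differences = 2L)) / step
  hits <- which(slope_change > tolerance) + 1L  # index of central grid point
  if (!length(hits)) return(numeric(0))
  # merge consecutive hits into brackets, then refine each on the analytic curve
  groups <- split(hits, cumsum(c(1L, diff(hits) > 1L)))
  f <- curve_function(spec, curve)
  vapply(groups, function(idx) {
    a <- x[max(1L, min(idx) - 1L)]
    b <- x[min(length(x), max(idx) + 1L)]
    refine_kink(f, a, b)
  }, numeric(1L), USE.NAMES = FALSE)
}

# Localise a single slope change inside [a, b] by quarter-point scanning:
# split the bracket into four equal segments, find the internal boundary
# with the largest slope change, and keep the two segments flanking it.
# The bracket halves each iteration and always contains the kink, whether
# it falls inside a segment or exactly on a probed point.
refine_kink <- function(f, a, b, xtol = 1e-9) {
  while (b - a > xtol) {
    q <- (b - a) / 4
    xs <- a + q * 0:4
    ys <- vapply(xs, f, numeric(1L))
    s <- diff(ys) / q
    j <- which.max(abs(diff(s)))
    a <- xs[j]
    b <- xs[j + 2L]
  }
  (a + b) / 2
}

#' Expected-duration reduction relative to the full protocol
#'
#' @param epd Expected protocol duration in seconds.
#' @param timing A [protocol_timing()].
#' @return Percentage reduction `100 * (t_full - epd) / t_full` (negative if
#'   `epd` exceeds the full-protocol duration).
#' @export
percent_reduction_vs_full <- function(epd, timing) {
  stopifnot(inherits(timing, "protocol_timing"))
  100 * (timing$t_full - epd) / timing$t_full
}
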