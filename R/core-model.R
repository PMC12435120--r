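#' Per-person confusion rates for one reader
#'
#' Converts a reader's operating point and the cohort prevalence into
#' per-person probabilities of the four confusion-matrix cells. All analytic
#' work in this package is done in this N = 1 convention; expected counts for
#' a finite cohort are these probabilities times the cohort size.
#'
#' @param op An [operating_point()].
#' @param cohort A [cohort()].
#' @return An object of class `confusion_rates` with fields `tp`, `fp`, `tn`,
#'   `fn` (each a probability) and `prevalence`. The four cells sum to 1 and
#'   `tp + fn` equals the prevalence.
#' @examples
#' confusion_rates(operating_point(0.90, 0.92), cohort(0.0146))
#' @export
confusion_rates <- function(op, cohort) {
  op <- as_operating_point(op)
  stopifnot(inherits(cohort, "cohort"))
  p <- cohort$prevalence
  structure(list(
    tp = p * op$sensitivity,
    fn = p * (1 - op$sensitivity),
    tn = (1 - p) * op$specificity,
    fp = (1 - p) * (1 - op$specificity),
    prevalence = p
  ), class = "confusion_rates")
}

flag_rate <- function(cr) cr$tp + cr$fp

#' Frechet bounds on radiologist/AI flagging overlap
#'
#' The overlap is the probability that the radiologist and the AI flag the
#' same person on the abbreviated protocol. Its feasible range, given only
#' the two readers' marginal confusion rates, follows from the
#' Frechet-Hoeffding bounds applied within each disease stratum: true
#' positives can only co-occur among diseased individuals and false positives
#' only among disease-free individuals.
#'
#' @param rad,ai `confusion_rates` for the radiologist and the AI model,
#'   built on the same prevalence.
#' @param cohort Optional [cohort()]; if supplied, its prevalence must match
#'   the rates' prevalence.
#' @return An object of class `overlap_bounds` with fields `minimum` and
#'   `maximum`.
#' @examples
#' coh <- cohort(0.0146)
#' rad <- confusion_rates(operating_point(0.90, 0.92), coh)
#' ai  <- confusion_rates(operating_point(0.80, 0.80), coh)
#' overlap_bounds(rad, ai)   # minimum 0.010220, maximum 0.090512
#' @export
overlap_bounds <- function(rad, ai, cohort = NULL) {
  stopifnot(inherits(rad, "confusion_rates"), inherits(ai, "confusion_rates"))
  p <- rad$prevalence
  if (abs(ai$prevalence - p) > 1e-12) {
    stop("prevalence mismatch between radiologist (", p, ") and AI (",
         ai$prevalence, ") confusion rates", call. = FALSE)
  }
  if (!is.null(cohort) && abs(cohort$prevalence - p) > 1e-12) {
    stop("cohort prevalence does not match the confusion rates", call. = FALSE)
  }
  maximum <- min(rad$tp, ai$tp) + min(rad$fp, ai$fp)
  minimum <- max(0, rad$tp + ai$tp - p) + max(0, rad$fp + ai$fp - (1 - p))
  # float dust can push a forced-equal minimum a few ulp past the maximum
  minimum <- min(minimum, maximum)
  structure(list(minimum = minimum, maximum = maximum),
            class = "overlap_bounds")
}

# Per-stratum Frechet-extreme joint cells; used by both the analytic model
# and the cohort simulator so the two routes share no arithmetic beyond this.
stratum_joint_cell <- function(p_rad, p_ai, mode, lambda = NULL) {
  lo <- max(0, p_rad + p_ai - 1)
  hi <- min(p_rad, p_ai)
  switch(mode,
    max_overlap = hi,
    min_overlap = lo,
    independent = p_rad * p_ai,
    fixed_overlap = lo + lambda * (hi - lo),
    stop("unknown coupling mode: ", mode, call. = FALSE))
}

#' Adaptive-protocol recall rate
#'
#' Recall rate of the adaptive strategy for a given radiologist/AI overlap:
#' the fraction of people the radiologist flags on the abbreviated protocol
#' who were not already given the full protocol by the AI, i.e.
#' `tp_rad + fp_rad - overlap`. Substituting the maximum feasible overlap
#' yields the best-case (lower) recall limit; the minimum overlap yields the
#' worst-case (upper) limit.
#'
#' @param rad Radiologist `confusion_rates`.
#' @param overlap Probability that both readers flag the same person; must
#'   lie within the feasible Frechet range for some AI reader (at minimum,
#'   within `[0, tp_rad + fp_rad]`).
#' @param bounds Optional `overlap_bounds`; when supplied, `overlap` is
#'   checked against it.
#' @return Recall rate as a fraction.
#' @export
rr_adaptive <- function(rad, overlap, bounds = NULL) {
  stopifnot(inherits(rad, "confusion_rates"))
  check_probability(overlap, "overlap")
  tol <- 1e-9
  if (!is.null(bounds)) {
    if (overlap < bounds$minimum - tol || overlap > bounds$maximum + tol) {
      stop("overlap ", overlap, " outside feasible range [",
           bounds$minimum, ", ", bounds$maximum, "]", call. = FALSE)
    }
  } else if (overlap > flag_rate(rad) + tol) {
    stop("overlap ", overlap, " exceeds the radiologist flag rate ",
         flag_rate(rad), call. = FALSE)
  }
  max(0, flag_rate(rad) - overlap)
}

#' Adaptive-protocol expected duration
#'
#' Expected scanner time per screened person under the adaptive strategy:
#' AI-flagged individuals receive the full protocol immediately, AI-negative
#' individuals receive the abbreviated protocol, and recalled individuals
#' (rate `rr`) return for an additional full-protocol visit:
#' `t_full * (tp_ai + fp_ai + rr) + t_abbr * (tn_ai + fn_ai)`.
#'
#' @param ai AI `confusion_rates`.
#' @param rr Adaptive recall rate (fraction in `[0, 1]`), typically from
#'   [rr_adaptive()].
#' @param timing A [protocol_timing()].
#' @return Expected protocol duration in seconds.
#' @export
epd_adaptive <- function(ai, rr, timing) {
  stopifnot(inherits(ai, "confusion_rates"), inherits(timing, "protocol_timing"))
  check_probability(rr, "rr")
  timing$t_full * (ai$tp + ai$fp + rr) + timing$t_abbr * (ai$tn + ai$fn)
}

#' Abbreviated-only baselines
#'
#' Under the abbreviated-only strategy every person receives the abbreviated
#' scan and everyone the radiologist flags returns for a full-protocol visit,
#' so the recall rate is the radiologist flag rate `tp + fp` and the expected
#' duration is `t_abbr + (tp + fp) * t_full`.
#'
#' @param rad Radiologist `confusion_rates`.
#' @param timing A [protocol_timing()].
#' @return `rr_abbreviated_only()`: recall rate as a fraction.
#' @export
rr_abbreviated_only <- function(rad) {
  stopifnot(inherits(rad, "confusion_rates"))
  flag_rate(rad)
}

#' @rdname rr_abbreviated_only
#' @return `epd_abbreviated_only()`: expected duration in seconds.
#' @export
epd_abbreviated_only <- function(rad, timing) {
  stopifnot(inherits(rad, "confusion_rates"), inherits(timing, "protocol_timing"))
  timing$t_abbr + flag_rate(rad) * timing$t_full
}

#' Full-only strategy metrics
#'
#' Everyone is scanned with the full protocol up front: no one is ever
#' recalled (RR = 0) and the expected duration equals the full-protocol
#' duration.
#'
#' @param timing A [protocol_timing()].
#' @return A `scenario_metrics` object with `strategy = "full_only"`,
#'   `rr = 0` and `epd = t_full`.
#' @export
metrics_full_only <- function(timing) {
  stopifnot(inherits(timing, "protocol_timing"))
  scenario_metrics("full_only", rr = 0, epd = timing$t_full)
}

scenario_metrics <- function(strategy, rr, epd) {
  stopifnot(strategy %in% c("abbreviated_only", "full_only", "adaptive"))
  if (length(rr) == 2L || length(epd) == 2L) {
    stopifnot(length(rr) == 2L, length(epd) == 2L,
              rr[1] <= rr[2] + 1e-12, epd[1] <= epd[2] + 1e-9)
    names(rr) <- names(epd) <- c("lower", "upper")
  }
  structure(list(strategy = strategy, rr = rr, epd = epd),
            class = "scenario_metrics")
}

#' @export
print.scenario_metrics <- function(x, ...) {
  fmt <- function(v, unit) {
    if (length(v) == 2L) sprintf("[%.6g, %.6g]%s", v[1], v[2], unit)
    else sprintf("%.6g%s", v, unit)
  }
  cat(sprintf("<scenario_metrics> %s: RR %s, EPD %s\n", x$strategy,
              fmt(x$rr, ""), fmt(x$epd, " s")))
  invisible(x)
}

#' Best-/worst-case limits of the adaptive strategy
#'
#' Convenience wrapper around the whole analytic chain: builds both readers'
#' confusion rates, computes the Frechet overlap bounds, and converts them
#' into recall-rate and expected-duration limits. Maximum overlap gives the
#' best case (lower RR, lower EPD); minimum overlap the worst case.
#'
#' @param rad_op Radiologist [operating_point()] on the abbreviated protocol.
#' @param ai_op AI [operating_point()].
#' @param cohort A [cohort()].
#' @param timing A [protocol_timing()].
#' @return A `scenario_metrics` object with `strategy = "adaptive"` and
#'   length-2 `rr` and `epd` fields (`lower`, `upper`).
#' @examples
#' adaptive_bounds(operating_point(0.90, 0.92), operating_point(0.80, 0.80),
#'                 cohort(0.0146), protocol_timing(262, 776))
#' @export
adaptive_bounds <- function(rad_op, ai_op, cohort, timing) {
  rad <- confusion_rates(rad_op, cohort)
  ai <- confusion_rates(ai_op, cohort)
  ov <- overlap_bounds(rad, ai)
  rr_lower <- rr_adaptive(rad, ov$maximum, ov)
  rr_upper <- rr_adaptive(rad, ov$minimum, ov)
  epd_lower <- epd_adaptive(ai, rr_lower, timing)
  epd_upper <- epd_adaptive(ai, rr_upper, timing)
  scenario_metrics("adaptive",
                   rr = c(rr_lower, rr_upper),
                   epd = c(epd_lower, epd_upper))
}
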