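band_modes <- c("emulation", "restricted_limits")

#' "Most likely" performance band from an agreement-accuracy interval
#'
#' The theoretical adaptive limits span everything between the Frechet
#' extremes; the literature suggests an AI trained to emulate radiologist
#' decisions agrees with the radiologist on roughly 75%-91% of cases (mean
#' accuracy 83.4%, n = 14). This function converts such an agreement
#' interval into a band of plausible adaptive performance along a sweep.
#'
#' Two documented constructions are offered. In `"emulation"` mode (the
#' default) the AI reproduces each radiologist decision independently with
#' per-person agreement probability \eqn{q} in the interval, so the overlap
#' is \eqn{q (tp_r + fp_r)}, the AI flag rate is
#' \eqn{q (tp_r + fp_r) + (1-q)(1 - tp_r - fp_r)}, and RR/EPD follow the
#' adaptive formulas; the band is the envelope over \eqn{q} (both metrics
#' are linear in \eqn{q}, so the endpoints suffice). In
#' `"restricted_limits"` mode the band is the envelope of the theoretical
#' limits over AI operating points confined to `interval x interval` (a
#' swept AI parameter keeps its grid value). Either band is clipped to the
#' theoretical limits of the sweep configuration at every grid value.
#'
#' @param spec A [sweep_spec()].
#' @param agreement_interval Two ordered fractions `[low, high]`; defaults
#'   to the configuration's `band_interval` (0.75-0.91).
#' @param mode `"emulation"` or `"restricted_limits"`.
#' @return A `likely_band` object: a data.frame with columns `value`,
#'   `rr_band_lower`, `rr_band_upper`, `epd_band_lower`, `epd_band_upper`,
#'   plus the theoretical `rr_adaptive_lower/upper` and
#'   `epd_adaptive_lower/upper` columns used for clipping; attributes
#'   `"mode"` and `"agreement_interval"`.
#' @examples
#' bd <- likely_band(sweep_spec("ai_sensitivity", grid = c(0.5, 0.8, 1)))
#' bd$rr_band_lower
#' @export
likely_band <- function(spec, agreement_interval = NULL, mode = NULL) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (is.null(agreement_interval)) agreement_interval <- spec$config$band_interval
  if (is.null(mode)) mode <- spec$config$band_mode
  if (!is.character(mode) || length(mode) != 1L || !mode %in% band_modes) {
    stop("unknown band mode '", paste(mode, collapse = ","),
         "'; available modes: ", paste(band_modes, collapse = ", "),
         call. = FALSE)
  }
  q <- as.numeric(agreement_interval)
  if (length(q) != 2L || anyNA(q) || q[1] > q[2] || q[1] < 0 || q[2] > 1) {
    stop("'agreement_interval' must be ordered fractions [low, high] in [0, 1]",
         call. = FALSE)
  }
  limits <- run_sweep(spec)
  band <- vapply(seq_along(spec$grid), function(i) {
    cfg <- substitute_parameter(spec$config, spec$parameter, spec$grid[i])
    raw <- if (mode == "emulation") {
      band_emulation(cfg, q)
    } else {
      band_restricted(cfg, q, spec$parameter)
    }
    # clipping contract: the band never leaves the theoretical limits
    c(rr_band_lower = min(max(raw["rr_lo"], limits$rr_adaptive_lower[i]),
                          limits$rr_adaptive_upper[i]),
      rr_band_upper = max(min(raw["rr_hi"], limits$rr_adaptive_upper[i]),
                          limits$rr_adaptive_lower[i]),
      epd_band_lower = min(max(raw["epd_lo"], limits$epd_adaptive_lower[i]),
                           limits$epd_adaptive_upper[i]),
      epd_band_upper = max(min(raw["epd_hi"], limits$epd_adaptive_upper[i]),
                           limits$epd_adaptive_lower[i]))
  }, numeric(4L))
  out <- data.frame(value = spec$grid, t(band),
                    rr_adaptive_lower = limits$rr_adaptive_lower,
                    rr_adaptive_upper = limits$rr_adaptive_upper,
                    epd_adaptive_lower = limits$epd_adaptive_lower,
                    epd_adaptive_upper = limits$epd_adaptive_upper)
  attr(out, "mode") <- mode
  attr(out, "agreement_interval") <- q
  attr(out, "spec") <- spec
  class(out) <- c("likely_band", "data.frame")
  out
}

# Emulation-mode metrics at agreement q: both RR and EPD are linear in q, so
# the envelope over [low, high] is attained at the endpoints.
band_emulation <- function(cfg, q) {
  coh <- config_cohort(cfg)
  timing <- suppressWarnings(config_timing(cfg))
  rad <- confusion_rates(config_rad_op(cfg), coh)
  f <- flag_rate(rad)
  eval_q <- function(qi) {
    rr <- (1 - qi) * f
    ai_flag <- qi * f + (1 - qi) * (1 - f)
    epd <- timing$t_full * (ai_flag + rr) + timing$t_abbr * (1 - ai_flag)
    c(rr = rr, epd = epd)
  }
  m <- vapply(q, eval_q, numeric(2L))
  c(rr_lo = min(m["rr", ]), rr_hi = max(m["rr", ]),
    epd_lo = min(m["epd", ]), epd_hi = max(m["epd", ]))
}

# Restricted-limits mode: envelope of the theoretical limits over AI
# operating points inside [low, high]^2; a swept AI parameter keeps the
# value already substituted into cfg.
band_restricted <- function(cfg, q, swept_parameter) {
  coh <- config_cohort(cfg)
  timing <- suppressWarnings(config_timing(cfg))
  rad_op <- config_rad_op(cfg)
  axis <- seq(q[1], q[2], length.out = 21L)
  se <- if (swept_parameter == "ai_sensitivity") cfg$ai_sensitivity else axis
  sp <- if (swept_parameter == "ai_specificity") cfg$ai_specificity else axis
  grid <- expand.grid(se = se, sp = sp)
  m <- vapply(seq_len(nrow(grid)), function(i) {
    ad <- adaptive_bounds(rad_op, operating_point(grid$se[i], grid$sp[i]),
                          coh, timing)
    c(ad$rr, ad$epd)
  }, numeric(4L))
  c(rr_lo = min(m[1, ]), rr_hi = max(m[2, ]),
    epd_lo = min(m[3, ]), epd_hi = max(m[4, ]))
}
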