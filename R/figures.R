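#' Render sweep figures
#'
#' Draws the standard two-panel figure for a sweep: recall rate (top) and
#' expected protocol duration (bottom) against the swept parameter, with the
#' abbreviated-only baseline in red, the full-only baseline in blue, the
#' adaptive theoretical limits in green with the feasible region shaded, and
#' (optionally) a darker band between dotted lines marking the estimated
#' most likely range. Duration sweeps can be drawn on a
#' percentage-of-full-protocol-duration axis.
#'
#' A band that leaves the theoretical limits is rejected before any device
#' is opened, so a rendering failure never corrupts numeric outputs already
#' on disk.
#'
#' @param results A `sweep_result` from [run_sweep()].
#' @param band Optional `likely_band` from [likely_band()] on the same grid.
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"svg"`.
#' @param normalize Draw EPD as a percentage of the full-protocol duration.
#' @return Path of the file written (named `fig_<parameter>.<format>`),
#'   invisibly.
#' @export
render_figures <- function(results, band = NULL, dir = ".",
                           format = c("png", "svg"), normalize = FALSE) {
  format <- match.arg(format)
  stopifnot(inherits(results, "sweep_result"))
  if (nrow(results) < 2L) {
    stop("need a sweep with at least 2 grid points to draw", call. = FALSE)
  }
  spec <- attr(results, "spec")
  if (!is.null(band)) {
    if (!isTRUE(all.equal(band$value, results$value))) {
      stop("band grid does not match the sweep grid", call. = FALSE)
    }
    tol <- 1e-9
    if (any(band$rr_band_lower < band$rr_adaptive_lower - tol) ||
        any(band$rr_band_upper > band$rr_adaptive_upper + tol) ||
        any(band$epd_band_lower < band$epd_adaptive_lower - tol) ||
        any(band$epd_band_upper > band$epd_adaptive_upper + tol)) {
      stop("band lies outside the theoretical limits; refusing to draw",
           call. = FALSE)
    }
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  file <- file.path(dir, paste0("fig_", spec$parameter, ".", format))
  if (format == "png") {
    grDevices::png(file, width = 1400, height = 1800, res = 200)
  } else {
    grDevices::svg(file, width = 7, height = 9)
  }
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  # restore par while the device is still open, then close it
  on.exit({
    graphics::par(old)
    grDevices::dev.off()
  }, add = TRUE)

  x <- results$value
  t_full <- if (spec$parameter == "t_full") x else spec$config$t_full
  scale_epd <- function(y) if (normalize) 100 * y / t_full else y

  panel <- function(lower, upper, abbr, full, ylab, b_lo = NULL, b_hi = NULL) {
    ylim <- range(lower, upper, abbr, full)
    graphics::plot(NA, xlim = range(x), ylim = ylim,
                   xlab = spec$parameter, ylab = ylab)
    graphics::polygon(c(x, rev(x)), c(lower, rev(upper)),
                      col = grDevices::adjustcolor("darkgreen", 0.15),
                      border = NA)
    if (!is.null(b_lo)) {
      graphics::polygon(c(x, rev(x)), c(b_lo, rev(b_hi)),
                        col = grDevices::adjustcolor("darkgreen", 0.35),
                        border = NA)
      graphics::lines(x, b_lo, col = "darkgreen", lty = 3)
      graphics::lines(x, b_hi, col = "darkgreen", lty = 3)
    }
    graphics::lines(x, lower, col = "darkgreen", lwd = 2)
    graphics::lines(x, upper, col = "darkgreen", lwd = 2)
    graphics::lines(x, abbr, col = "red", lwd = 2)
    graphics::lines(x, full, col = "blue", lwd = 2)
    graphics::legend("topright", bty = "n", cex = 0.7,
                     legend = c("adaptive limits", "abbreviated-only",
                                "full-only"),
                     col = c("darkgreen", "red", "blue"), lwd = 2)
  }
  panel(results$rr_adaptive_lower, results$rr_adaptive_upper,
        results$rr_abbr_only, results$rr_full_only,
        ylab = "recall rate (fraction)",
        b_lo = band$rr_band_lower, b_hi = band$rr_band_upper)
  panel(scale_epd(results$epd_adaptive_lower),
        scale_epd(results$epd_adaptive_upper),
        scale_epd(results$epd_abbr_only), scale_epd(results$epd_full_only),
        ylab = if (normalize) "EPD (% of full protocol)" else "EPD (s)",
        b_lo = if (is.null(band)) NULL else scale_epd(band$epd_band_lower),
        b_hi = if (is.null(band)) NULL else scale_epd(band$epd_band_upper))
  invisible(file)
}
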