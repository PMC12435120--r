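#' Reader operating point
#'
#' An operating point characterises a reader (radiologist or AI model) by its
#' sensitivity and specificity on the abbreviated protocol.
#'
#' @param sensitivity Probability of flagging a diseased individual, in
#'   \eqn{[0, 1]}.
#' @param specificity Probability of not flagging a disease-free individual,
#'   in \eqn{[0, 1]}.
#' @return An object of class `operating_point`: a named list with elements
#'   `sensitivity` and `specificity`.
#' @examples
#' operating_point(0.90, 0.92)  # Table-1 radiologist on the abbreviated protocol
#' @export
operating_point <- function(sensitivity, specificity) {
  check_probability(sensitivity, "sensitivity")
  check_probability(specificity, "specificity")
  structure(list(sensitivity = sensitivity, specificity = specificity),
            class = "operating_point")
}

#' Screened cohort
#'
#' A cohort is described by the per-person probability of malignancy
#' (prevalence) and, optionally, a finite size. All analytic computations use
#' the rates-only (per-person, N = 1) convention; a finite `size` is needed
#' only by the cohort simulator.
#'
#' @param prevalence Probability of malignancy per screened person, in
#'   \eqn{[0, 1]}.
#' @param size Optional positive integer cohort size; `NULL` (default) marks a
#'   rates-only cohort.
#' @return An object of class `cohort`.
#' @examples
#' cohort(0.0146)            # screening malignancy rate, rates-only
#' cohort(0.0146, size = 1e6)
#' @export
cohort <- function(prevalence, size = NULL) {
  check_probability(prevalence, "prevalence")
  if (!is.null(size)) {
    if (!is.numeric(size) || length(size) != 1L || !is.finite(size) ||
        size < 1 || size != floor(size)) {
      stop("'size' must be a positive integer or NULL", call. = FALSE)
    }
    size <- as.double(size)
  }
  structure(list(prevalence = prevalence, size = size), class = "cohort")
}

#' Protocol timing
#'
#' Acquisition durations, in seconds, of the abbreviated and full MRI
#' protocols. `t_abbr > t_full` is permitted (duration sweeps cross this
#' line) but flagged with a warning since it is physically unusual.
#'
#' @param t_abbr Abbreviated-protocol duration in seconds, > 0.
#' @param t_full Full-protocol duration in seconds, > 0.
#' @return An object of class `protocol_timing`.
#' @examples
#' protocol_timing(262, 776)  # Table-1 durations
#' @export
protocol_timing <- function(t_abbr, t_full) {
  check_positive(t_abbr, "t_abbr")
  check_positive(t_full, "t_full")
  if (t_abbr > t_full) {
    warning("t_abbr (", t_abbr, " s) exceeds t_full (", t_full,
            " s); model remains well defined", call. = FALSE)
  }
  structure(list(t_abbr = t_abbr, t_full = t_full), class = "protocol_timing")
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop("'", name, "' must be a single number in [0, 1], got ",
         deparse(substitute(x, parent.frame())), " = ",
         paste(format(x), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("'", name, "' must be a single positive number", call. = FALSE)
  }
  invisible(TRUE)
}

as_operating_point <- function(x) {
  if (inherits(x, "operating_point")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(operating_point(x[[1]], x[[2]]))
  if (is.list(x) && all(c("sensitivity", "specificity") %in% names(x))) {
    return(operating_point(x$sensitivity, x$specificity))
  }
  stop("cannot interpret input as an operating point", call. = FALSE)
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("<operating_point> sensitivity %.4g, specificity %.4g\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> prevalence %.4g, size %s\n", x$prevalence,
              if (is.null(x$size)) "rates-only" else format(x$size)))
  invisible(x)
}

#' @export
print.protocol_timing <- function(x, ...) {
  cat(sprintf("<protocol_timing> t_abbr %g s, t_full %g s\n",
              x$t_abbr, x$t_full))
  invisible(x)
}
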