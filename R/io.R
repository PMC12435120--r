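# Flatten the package's result objects to a plain data.frame for CSV.
as_result_table <- function(result) {
  if (inherits(result, "scenario_metrics")) {
    rr <- if (length(result$rr) == 2L) result$rr else rep(result$rr, 2L)
    epd <- if (length(result$epd) == 2L) result$epd else rep(result$epd, 2L)
    data.frame(strategy = result$strategy,
               rr_lower = rr[[1]], rr_upper = rr[[2]], rr_unit = "fraction",
               epd_lower = epd[[1]], epd_upper = epd[[2]],
               epd_unit = "seconds")
  } else if (inherits(result, "bounds_report")) {
    result$results
  } else if (inherits(result, "empirical_metrics")) {
    data.frame(rr = result$rr, rr_unit = "fraction", epd = result$epd,
               epd_unit = "seconds", n = result$counts$n,
               recalled = result$counts$recalled,
               overlap = result$counts$overlap)
  } else if (is.data.frame(result)) {
    as.data.frame(result)
  } else {
    stop("cannot serialize an object of class ",
         paste(class(result), collapse = "/"), call. = FALSE)
  }
}

as_result_list <- function(result) {
  if (inherits(result, "scenario_metrics")) {
    list(strategy = result$strategy,
         rr = as.list(signif9(result$rr)), rr_unit = "fraction",
         epd = as.list(signif9(result$epd)), epd_unit = "seconds")
  } else if (inherits(result, "bounds_report")) {
    list(n = result$n, sampling = result$sampling, seed = result$seed,
         analytic = as_result_list(result$analytic),
         overlap_bounds = list(minimum = signif9(result$overlap_bounds$minimum),
                               maximum = signif9(result$overlap_bounds$maximum)),
         all_within_bounds = result$all_within_bounds,
         extremes_attained = result$extremes_attained,
         n_violations = nrow(result$violations),
         results = df_signif9(result$results))
  } else if (inherits(result, "empirical_metrics")) {
    list(rr = signif9(result$rr), rr_unit = "fraction",
         epd = signif9(result$epd), epd_unit = "seconds",
         counts = lapply(result$counts, function(v)
           if (is.numeric(v) && !is.null(names(v))) as.list(v) else v))
  } else if (is.data.frame(result)) {
    df_signif9(result)
  } else {
    stop("cannot serialize an object of class ",
         paste(class(result), collapse = "/"), call. = FALSE)
  }
}

signif9 <- function(x) if (is.numeric(x)) signif(x, 9L) else x
df_signif9 <- function(df) {
  df <- as.data.frame(df)
  df[] <- lapply(df, signif9)
  df
}

#' Write a result object to CSV and/or JSON
#'
#' Serialises sweep results, scenario metrics, likely bands, empirical
#' metrics or bounds reports with a stable column order and floating-point
#' values at 9 significant digits, so that deterministic inputs yield
#' byte-identical output files. Rates are written as fractions; durations in
#' seconds (column names and unit columns say which).
#'
#' @param result A `sweep_result`, `likely_band`, `scenario_metrics`,
#'   `empirical_metrics` or `bounds_report`.
#' @param path Output file path without extension (or with a `.csv`/`.json`
#'   extension matching a single requested format).
#' @param format Character vector, subset of `c("csv", "json")`.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(result, path, format = c("csv", "json")) {
  format <- match.arg(format, c("csv", "json"), several.ok = TRUE)
  ext <- tools::file_ext(path)
  if (ext %in% c("csv", "json")) {
    format <- ext
    path <- sub("\\.(csv|json)$", "", path)
  }
  written <- character(0)
  if ("csv" %in% format) {
    f <- paste0(path, ".csv")
    df <- as_result_table(result)
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], function(v) formatC(v, digits = 9L, format = "g"))
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  }
  if ("json" %in% format) {
    f <- paste0(path, ".json")
    jsonlite::write_json(as_result_list(result), f, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, f)
  }
  invisible(written)
}
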