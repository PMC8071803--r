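# Readers and writers: CSV traces and idealization tables.

#' Read a conductance trace
#'
#' Reads a plain-text trace with columns `(time, conductance)` or
#' `(time, current, voltage)` -- in the latter case the conductance is the
#' current divided by the voltage (80 pA at 80 mV is 1 nS). Sampling must be
#' equidistant; the sampling rate is inferred from the time column.
#'
#' Axon Binary Format (`format = "abf"`) is not bundled: recordings should be
#' exported to CSV (two columns, time and conductance) by the acquisition
#' software or a dedicated ABF reader first.
#'
#' @param path File path.
#' @param format `"csv"` (default) or `"abf"`.
#' @param tol Maximum relative deviation of time steps from their median
#'   before the trace is rejected as non-equidistant.
#' @return A tibble (`time`, `conductance`) with attribute `sample_rate`.
#' @export
read_trace <- function(path, format = c("csv", "abf"), tol = 1e-6) {
  format <- match.arg(format)
  if (format == "abf") {
    abort(paste0(
      "no ABF reader is available in this installation; ",
      "export the recording to CSV (columns time, conductance) and use format = 'csv'"
    ))
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (ncol(df) < 2L) abort("trace CSV needs at least two numeric columns")
  if (ncol(df) >= 3L && all(c("current", "voltage") %in% names(df))) {
    df <- tibble(time = df[[1L]], conductance = df$current / df$voltage)
  } else {
    df <- tibble(time = df[[1L]], conductance = df[[2L]])
  }
  if (!is.numeric(df$time) || !is.numeric(df$conductance)) {
    abort("trace columns must be numeric")
  }
  dt <- diff(df$time)
  step <- median(dt)
  bad <- which(abs(dt - step) > tol * step)
  if (length(bad) > 0L) {
    abort(sprintf("trace is not equidistantly sampled: first offending step at row %d",
                  bad[1L] + 1L))
  }
  tibble::new_tibble(df, sample_rate = 1 / step, class = "patchseg_trace")
}

#' Write an idealization to CSV
#'
#' Writes the fitted segments with columns `leftEnd`, `rightEnd`, `value`
#' (plus `noiseLevel` and `deconvolved` when available). The first and last
#' segments are dropped by default because their true start and end cannot be
#' identified from the data. Values of segments flagged as not deconvolvable
#' can be blanked to `NA`.
#'
#' @param fit An `ms_fit` object.
#' @param path Output file path.
#' @param keep_boundary Keep the first and last segment (default `FALSE`).
#' @param na_no_deconvolution Blank the `value` of segments in
#'   non-deconvolvable clusters (default `FALSE`).
#' @return The path, invisibly. With fewer than three segments and
#'   `keep_boundary = FALSE` an empty table is written with a warning.
#' @export
write_idealization <- function(fit, path, keep_boundary = FALSE,
                               na_no_deconvolution = FALSE) {
  stopifnot(inherits(fit, "ms_fit"))
  seg <- fit$segments
  out <- tibble(leftEnd = seg$left_end, rightEnd = seg$right_end, value = seg$value)
  if (!is.null(seg[["noise_level"]])) out$noiseLevel <- seg[["noise_level"]]
  out$deconvolved <- seg$deconvolved
  if (na_no_deconvolution && length(fit$no_deconvolution) > 0L) {
    out$value[fit$no_deconvolution] <- NA_real_
  }
  if (!keep_boundary) {
    if (nrow(out) < 3L) {
      warn("fewer than three segments: nothing remains after dropping the boundary segments")
      out <- out[0L, ]
    } else {
      out <- out[-c(1L, nrow(out)), ]
    }
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Read an idealization written by [write_idealization()]
#'
#' @param path File path.
#' @return A tibble with columns `left_end`, `right_end`, `value` and any
#'   further stored columns.
#' @export
read_idealization <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df)[names(df) == "leftEnd"] <- "left_end"
  names(df)[names(df) == "rightEnd"] <- "right_end"
  as_tibble(df)
}
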