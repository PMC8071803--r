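# JSMURF-style multiscale detection on scales above the filter length.

#' Multiscale idealization on scales above the filter length (JSMURF)
#'
#' Fits the step signal with the minimal number of conductance changes such
#' that, for every fitted segment, the local mean over every dyadic
#' sub-interval -- after dropping the first `m` samples of the interval, which
#' is where the filter transition lives -- stays within a scale-penalized,
#' Monte-Carlo calibrated band around the segment level. Means are
#' standardized by the noise level and the correlation-aware variance of a
#' mean of correlated samples. The probability of one or more false-positive
#' changes on model-conform data is bounded by `config$alpha`.
#'
#' Under homogeneous noise a single robust global noise estimate is used;
#' under heterogeneous noise each candidate segment is studentized by its own
#' estimate.
#'
#' @param trace A trace tibble (`time`, `conductance`) or numeric vector of
#'   conductances.
#' @param filter A [lowpass_filter()].
#' @param config A [method_config()]; its `noise`, `alpha`, `r` and `seed`
#'   fields are used.
#' @param store A [critval_store()] for the Monte-Carlo calibration cache.
#' @param critval Optional pre-computed critical value, bypassing the
#'   Monte-Carlo calibration (used in tests and when calibrating externally).
#' @param messages Progress-message interval for the Monte-Carlo simulation.
#' @return An `ms_fit` object; see [tidy.ms_fit()].
#' @seealso [jules()], [hilde()], [deconvolve_locally()], [idealize()]
#' @export
jsmurf <- function(trace, filter, config = method_config("jsmurf"),
                   store = critval_store(), critval = NULL, messages = 0L) {
  y <- trace_values(trace)
  m <- filter$m
  if (length(y) <= 2L * (m + 1L)) {
    abort(sprintf("trace too short: need more than 2(m + 1) = %d samples", 2L * (m + 1L)))
  }
  q <- critval %||% get_critval(config, length(y), filter, store, messages)$critval
  parts <- ms_fit_segments(y, filter, "jsmurf", config$noise, q)
  new_ms_fit(parts, filter, "jsmurf", config$noise, config$alpha, q, length(y))
}

#' Robust noise-level estimation from filtered recordings
#'
#' Estimates the (post-filter) noise standard deviation from differences of
#' observations `m + 1` samples apart, which are uncorrelated beyond the
#' truncated kernel length; jumps affect only a small fraction of the
#' differences and are suppressed by a median-absolute-deviation scale. The
#' estimate is scaled by `sqrt(2 (1 - rho(m + 1)))` (with `rho(m + 1) = 0` for
#' the truncated kernel, i.e. `sqrt(2)`).
#'
#' With `fit = "global"` (default) one global level is returned. With a fitted
#' idealization, the estimator is applied segment-wise with the first `m`
#' samples of each segment dropped; segments too short to estimate are marked
#' and inherit the mean of their neighbours.
#'
#' @param trace Trace tibble or numeric vector.
#' @param filter A [lowpass_filter()].
#' @param fit `"global"` or an `ms_fit` object.
#' @return For `"global"`, a single noise level. Otherwise a tibble with one
#'   row per segment: `segment`, `noise_level`, `inherited`.
#' @export
estimate_noise <- function(trace, filter, fit = "global") {
  y <- trace_values(trace)
  if (identical(fit, "global")) {
    s <- noise_sd_estimate(y, filter)
    if (is.na(s)) abort("trace too short for noise estimation")
    return(s)
  }
  stopifnot(inherits(fit, "ms_fit"))
  ctx <- list(y = y, m = filter$m)
  seg <- fit$segments
  est <- vapply(seq_len(nrow(seg)), function(j) {
    segment_noise_estimate(ctx, seg$left_index[j], seg$right_index[j])
  }, numeric(1))
  inherited <- is.na(est)
  if (all(inherited)) abort("all segments too short for noise estimation")
  for (j in which(inherited)) {
    nb <- c(j - 1L, j + 1L)
    nb <- nb[nb >= 1L & nb <= length(est)]
    est[j] <- mean(est[nb], na.rm = TRUE)
  }
  # second pass in case a neighbour was itself missing
  while (any(is.na(est))) {
    for (j in which(is.na(est))) {
      nb <- c(j - 1L, j + 1L)
      nb <- nb[nb >= 1L & nb <= length(est)]
      est[j] <- mean(est[nb], na.rm = TRUE)
    }
  }
  tibble(segment = seq_along(est), noise_level = est, inherited = inherited)
}
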