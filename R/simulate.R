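# Synthetic traces from the filtered observation model: piecewise-constant
# conductance convolved with the truncated Bessel kernel plus coloured
# Gaussian noise whose autocorrelation equals the kernel ACF exactly.

#' Simulate a filtered patchclamp trace
#'
#' Draws `Y_i = (F_m * f)(i / f_s) + eps_i` where `f` is the step signal
#' `truth`, `F_m` the truncated kernel of `filter`, and `eps` a stationary
#' (piecewise-stationary under heterogeneous noise) Gaussian sequence whose
#' autocorrelation equals `filter$acf` and whose marginal standard deviation
#' equals the governing noise level. The noise level is interpreted as the
#' post-filter marginal standard deviation, i.e. what one estimates from quiet
#' stretches of a recorded (already filtered) trace.
#'
#' Coloured noise is generated as a moving average of white noise with the
#' filter's spectral-factorization weights, so the noise ACF matches the
#' kernel ACF exactly up to lag `m`. Under heterogeneous noise the level of a
#' sample is the level of the segment containing its time stamp, so samples in
#' the transition after a change inherit the right segment's level.
#'
#' @param truth A [step_signal()]; its support must cover `(0, n / sample_rate]`.
#' @param filter A [lowpass_filter()].
#' @param n Number of samples.
#' @param sigma Noise level in nS, or `NULL` to use `truth$noise_level`
#'   (heterogeneous noise). `sigma = 0` returns the noise-free convolution.
#' @param seed Integer seed; the trace is deterministic given the seed.
#' @return A tibble with columns `time` and `conductance` and attribute
#'   `sample_rate`.
#' @examples
#' fil <- lowpass_filter(4, 0.1, 1e4)
#' tr <- simulate_trace(step_signal(0, 0, 1), fil, n = 100, sigma = 0.2, seed = 1)
#' @export
simulate_trace <- function(truth, filter, n, sigma = NULL, seed = 1L) {
  truth <- validate_step_signal(truth)
  stopifnot(inherits(filter, "lowpass_filter"))
  fs <- filter$sample_rate
  n <- as.integer(n)
  if (n < 1L) abort("`n` must be at least 1")
  if (truth$right_end[nrow(truth)] < n / fs - 1e-12) {
    abort("`truth` must span at least `n / sample_rate` seconds")
  }
  if (is.null(sigma) && is.null(truth[["noise_level"]])) {
    abort("provide `sigma` or a `noise_level` column in `truth`")
  }
  tt <- seq_len(n) / fs
  mean_part <- convolve_step_signal(truth, filter, tt)
  s <- if (is.null(sigma)) step_signal_value_at(truth, tt, "noise_level") else sigma
  if (any(s < 0)) abort("noise levels must be non-negative")
  eps <- if (all(s == 0)) 0 else coloured_noise(n, filter, seed) * s
  tibble::new_tibble(
    tibble(time = tt, conductance = mean_part + eps),
    sample_rate = fs, class = "patchseg_trace"
  )
}

#' Simulate a pure-noise trace for Monte-Carlo calibration
#'
#' Equivalent to [simulate_trace()] with constant truth 0 and unit noise
#' level: `n` samples of coloured Gaussian noise with autocorrelation
#' `filter$acf` and marginal standard deviation 1.
#'
#' @inheritParams simulate_trace
#' @return A tibble with columns `time` and `conductance`.
#' @export
simulate_null <- function(n, filter, seed = 1L) {
  stopifnot(inherits(filter, "lowpass_filter"))
  n <- as.integer(n)
  tibble::new_tibble(
    tibble(time = seq_len(n) / filter$sample_rate,
           conductance = coloured_noise(n, filter, seed)),
    sample_rate = filter$sample_rate, class = "patchseg_trace"
  )
}

# stationary unit-variance Gaussian sequence with ACF = filter$acf
coloured_noise <- function(n, filter, seed) {
  b <- filter$ma_weights
  m <- length(b) - 1L
  w <- withr::with_seed(as.integer(seed), rnorm(n + m))
  if (m == 0L) return(w[seq_len(n)] * b)
  eps <- stats::filter(w, b, method = "convolution", sides = 1)
  as.numeric(eps[(m + 1L):(m + n)])
}

trace_values <- function(trace) {
  if (is.data.frame(trace)) {
    if (!"conductance" %in% names(trace)) abort("trace must have a `conductance` column")
    trace$conductance
  } else {
    as.numeric(trace)
  }
}
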