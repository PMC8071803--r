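# Analogue Bessel low-pass filters: truncated kernel, step response, exact ACF.
#
# The kernel is represented through the pole/residue (partial fraction) form of
# the transfer function, so the impulse response, step response and all overlap
# integrals (autocovariances) have closed forms as sums of exponentials.

#' Construct a truncated analogue low-pass Bessel filter
#'
#' Builds the analogue Bessel filter of a patchclamp amplifier from its pole
#' count and normalized cutoff frequency, truncates its kernel after `m`
#' sampling steps, and precomputes everything the idealization methods need:
#' the step response, the autocorrelation `rho(0..m)` of digitized filtered
#' white noise, and moving-average weights that reproduce that autocorrelation
#' exactly in simulation.
#'
#' The truncation length `m` is chosen as the smallest integer such that the
#' autocorrelation of the *untruncated* analogue kernel is below
#' `acf_threshold` at every lag of `m` samples or more. For the common
#' hardware configuration of a 4-pole Bessel filter with normalized cutoff 0.1
#' and threshold `1e-3` this gives `m = 11`.
#'
#' @param poles Number of filter poles; one of 2, 4, 6, 8.
#' @param cutoff Normalized cutoff frequency as a fraction of the sampling
#'   rate, in (0, 0.5). The -3 dB frequency of the filter in Hz is
#'   `cutoff * sample_rate`.
#' @param sample_rate Sampling rate \eqn{f_s} in Hz.
#' @param acf_threshold Truncation threshold for the kernel autocorrelation,
#'   in (0, 1). Default `1e-3`.
#' @param kind Filter family. Only `"bessel"` is supported.
#'
#' @return An object of class `lowpass_filter`: a list with elements `kind`,
#'   `poles`, `cutoff`, `sample_rate`, `m` (truncation length in samples),
#'   `len` (kernel support `m / sample_rate` in seconds), `acf` (numeric
#'   vector of length `m + 1`, the autocorrelation of digitized noise filtered
#'   with the truncated kernel, `acf[1] = 1`), `acf_untruncated`,
#'   `step_response` (vectorized function of time in seconds, 0 before the
#'   jump, 1 from `m / sample_rate` on), `kernel` (vectorized truncated,
#'   renormalized impulse response), `ma_weights` (moving-average weights for
#'   noise simulation) and `fingerprint` (stable identifier for cache keying).
#'
#' @examples
#' fil <- lowpass_filter(poles = 4, cutoff = 0.1, sample_rate = 5e4)
#' fil$m                        # 11
#' kernel_acf(fil)
#' @export
lowpass_filter <- function(poles = 4L, cutoff = 0.1, sample_rate,
                           acf_threshold = 1e-3, kind = "bessel") {
  if (!identical(kind, "bessel")) {
    abort(sprintf("filter family '%s' is not implemented; only 'bessel' is supported", kind))
  }
  if (!poles %in% c(2L, 4L, 6L, 8L)) {
    abort("`poles` must be one of 2, 4, 6, 8")
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff >= 0.5) {
    abort("`cutoff` must be a normalized frequency in (0, 0.5)")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    abort("`sample_rate` must be a positive sampling rate in Hz")
  }
  if (!is.numeric(acf_threshold) || length(acf_threshold) != 1L ||
      acf_threshold <= 0 || acf_threshold >= 1) {
    abort("`acf_threshold` must be in (0, 1)")
  }

  p <- bessel_poles(as.integer(poles)) * 2 * pi * cutoff * sample_rate
  r <- pole_residues(p)

  ## truncation rule on the untruncated analogue ACF
  g0 <- acv_exp_sum(p, r, 0)
  rho_at <- function(h) acv_exp_sum(p, r, h / sample_rate) / g0
  ## scan lags until an exponential envelope guarantees no further crossing
  env_c <- sum(abs(outer(r, r) / outer(p, p, `+`))) / abs(g0)
  decay <- max(Re(p)) # < 0
  h_stop <- ceiling(log(acf_threshold / env_c / 10) / decay * sample_rate)
  h_stop <- max(h_stop, 2L)
  rho_u <- vapply(seq_len(h_stop), rho_at, numeric(1))
  above <- which(abs(rho_u) >= acf_threshold)
  m <- if (length(above) == 0L) 0L else as.integer(max(above) + 1L)
  rho_u <- c(1, rho_u)

  trunc_len <- m / sample_rate
  ## integral of the untruncated kernel over [0, T]: raw step response at T
  step_raw <- function(t) {
    tt <- pmax(t, 0)
    vapply(tt, function(x) Re(sum(r * (exp(p * x) - 1) / p)), numeric(1))
  }
  norm_const <- if (m == 0L) 1 else step_raw(trunc_len)

  step_response <- function(t) {
    if (m == 0L) return(as.numeric(t > 0))
    s <- step_raw(pmin(pmax(t, 0), trunc_len)) / norm_const
    s[t >= trunc_len] <- 1
    s[t <= 0] <- 0
    s
  }
  kernel <- function(t) {
    out <- numeric(length(t))
    ok <- t >= 0 & t <= trunc_len & m > 0L
    if (any(ok)) {
      out[ok] <- vapply(t[ok], function(x) Re(sum(r * exp(p * x))), numeric(1)) / norm_const
    }
    out
  }

  ## ACF of the truncated kernel at integer sample lags (closed form)
  if (m == 0L) {
    acf_t <- 1
  } else {
    gT <- vapply(0:m, function(h) acv_trunc_exp_sum(p, r, h / sample_rate, trunc_len),
                 numeric(1))
    acf_t <- gT / gT[1]
  }

  fil <- structure(
    list(
      kind = kind,
      poles = as.integer(poles),
      cutoff = cutoff,
      sample_rate = sample_rate,
      acf_threshold = acf_threshold,
      m = m,
      len = trunc_len,
      acf = acf_t,
      acf_untruncated = rho_u,
      step_response = step_response,
      kernel = kernel,
      ma_weights = ma_weights_from_acf(acf_t),
      fingerprint = sprintf("bessel-p%d-c%.6g-m%d", as.integer(poles), cutoff, m)
    ),
    class = "lowpass_filter"
  )
  fil
}

#' @export
print.lowpass_filter <- function(x, ...) {
  cat(sprintf(
    "<lowpass_filter> %s, %d poles, normalized cutoff %.4g (%.6g Hz at fs = %.6g Hz)\n",
    x$kind, x$poles, x$cutoff, x$cutoff * x$sample_rate, x$sample_rate
  ))
  cat(sprintf("  truncation: m = %d samples (%.3g s), acf threshold %.3g\n",
              x$m, x$len, x$acf_threshold))
  invisible(x)
}

#' Autocorrelation of digitized noise filtered with the truncated kernel
#'
#' Returns the normalized autocovariance at integer sample lags of
#' continuous-time white noise passed through the truncated kernel and sampled
#' at the filter's sampling rate. This is the correlation structure of the
#' recording noise that all detection statistics standardize against.
#'
#' @param filter A [lowpass_filter()] object.
#' @return A tibble with columns `lag` (0 to `m`) and `acf` (`acf[lag = 0]` is 1).
#' @export
kernel_acf <- function(filter) {
  stopifnot(inherits(filter, "lowpass_filter"))
  tibble(lag = 0:filter$m, acf = filter$acf)
}

#' Convolve a piecewise-constant signal with the filter kernel
#'
#' Evaluates the convolution of a step signal with the truncated low-pass
#' kernel at arbitrary times, computed exactly as a finite sum of
#' step-response differences over the jumps of the signal (no numerical
#' convolution of sampled sequences). A constant signal is reproduced exactly
#' because the truncated kernel is renormalized to unit integral.
#'
#' The first segment's level is extended backwards in time, so evaluation
#' within the first kernel length after the signal start is well defined.
#'
#' @param signal A [step_signal()] tibble (columns `left_end`, `right_end`,
#'   `value`).
#' @param filter A [lowpass_filter()] object.
#' @param eval_times Numeric vector of times in seconds; must lie within the
#'   signal support.
#' @return Numeric vector of convolved conductances at `eval_times`.
#' @export
convolve_step_signal <- function(signal, filter, eval_times) {
  signal <- validate_step_signal(signal)
  stopifnot(inherits(filter, "lowpass_filter"))
  t0 <- signal$left_end[1]
  t1 <- signal$right_end[nrow(signal)]
  if (any(eval_times < t0 - 1e-12) || any(eval_times > t1 + 1e-12)) {
    abort("`eval_times` must lie within the signal support")
  }
  out <- rep(signal$value[1], length(eval_times))
  if (nrow(signal) > 1L) {
    jumps <- diff(signal$value)
    taus <- signal$left_end[-1]
    for (j in seq_along(jumps)) {
      out <- out + jumps[j] * filter$step_response(eval_times - taus[j])
    }
  }
  out
}

#' Attenuation of a short peak by the low-pass filter
#'
#' For a rectangular peak of unit amplitude and duration `l` samples, returns
#' the largest mean of the filtered response over any window of `window`
#' consecutive samples (default `l + m`, the support of the causal response of
#' the peak), maximized over the continuous phase of the peak relative to the
#' sampling grid (phase resolved at 1/100 of a sample). Peaks shorter than the
#' filter length have attenuation < 1: their filtered amplitude never reaches
#' the true level, which is why the local tests and the deconvolution must
#' correct for this factor.
#'
#' @param filter A [lowpass_filter()] object.
#' @param l Peak duration in samples (positive integer).
#' @param window Test-window length in samples; defaults to `l + m`.
#' @return The attenuation factor in (0, 1].
#' @export
peak_attenuation <- function(filter, l, window = NULL) {
  stopifnot(inherits(filter, "lowpass_filter"), l >= 1)
  fs <- filter$sample_rate
  l <- as.integer(l)
  w <- as.integer(window %||% (l + filter$m))
  span <- l + filter$m + w + 2L
  best <- 0
  for (phase in seq(0, 1 - 1e-9, by = 1 / 100)) {
    tt <- (seq_len(span) - phase) / fs
    resp <- filter$step_response(tt) - filter$step_response(tt - l / fs)
    cs <- c(0, cumsum(resp))
    means <- (cs[(w + 1):(span + 1)] - cs[1:(span - w + 1)]) / w
    best <- max(best, max(means))
  }
  min(best, 1)
}

## ---- internal filter math ----------------------------------------------

# poles of the Bessel filter normalized so that the -3 dB frequency is omega = 1
bessel_poles <- function(n) {
  k <- 0:n
  coef <- factorial(2 * n - k) / (2^(n - k) * factorial(k) * factorial(n - k))
  p <- polyroot(coef)
  A <- Re(prod(-p))
  gain2 <- function(w) A^2 / abs(prod(complex(real = 0, imaginary = w) - p))^2
  w3 <- uniroot(function(w) gain2(w) - 0.5, c(1e-6, 10), tol = 1e-12)$root
  p / w3
}

pole_residues <- function(p) {
  A <- prod(-p)
  vapply(seq_along(p), function(k) A / prod(p[k] - p[-k]), complex(1))
}

# int_0^Inf h(u) h(u + d) du for h(t) = sum r_k exp(p_k t)
acv_exp_sum <- function(p, r, d) {
  Re(sum(outer(r, r) * exp(outer(rep(1, length(p)), p * d)) / (-outer(p, p, `+`))))
}

# int_0^{T - d} h(u) h(u + d) du (kernel truncated at T)
acv_trunc_exp_sum <- function(p, r, d, T) {
  if (d >= T) return(0)
  ps <- outer(p, p, `+`)
  Re(sum(outer(r, r) * exp(outer(rep(1, length(p)), p * d)) * (exp(ps * (T - d)) - 1) / ps))
}

# moving-average weights b_0..b_m with sum b_k b_{k+h} = rho(h) exactly,
# obtained by spectral factorization of the symmetrized ACF polynomial
ma_weights_from_acf <- function(rho) {
  m <- length(rho) - 1L
  if (m == 0L) return(1)
  coefs <- c(rev(rho[-1]), rho)
  rt <- polyroot(coefs)
  inside <- rt[Mod(rt) < 1]
  if (length(inside) != m) {
    abort("spectral factorization of the kernel ACF failed (roots on the unit circle)")
  }
  b <- 1
  for (z in inside) b <- c(0, b) - c(z * b, 0)
  b <- Re(b)
  b / sqrt(sum(b^2))
}
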