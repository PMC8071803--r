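# Truncated Bessel kernels: truncation rule, ACF, step response, convolution.

test_that("truncation rule reproduces the hardware example (m = 11)", {
  fil <- lowpass_filter(4, 0.1, 5e4, acf_threshold = 1e-3)
  expect_identical(fil$m, 11L)
  # normalized cutoff 0.1 at 50 kHz is a 5 kHz time-domain cutoff
  expect_equal(fil$cutoff * fil$sample_rate, 5000)
  # the ACF of the untruncated kernel is below the threshold from lag m on
  rho_u <- fil$acf_untruncated
  expect_lt(max(abs(rho_u[-seq_len(fil$m)])), 1e-3)
  expect_gte(abs(rho_u[fil$m]), 1e-3) # lag m - 1 still above: m is minimal
})

test_that("closed-form ACF agrees with a quadrature oracle", {
  fil <- std_filter()
  fs <- fil$sample_rate
  # oracle: trapezoid integration of the impulse-response overlap on a
  # 1000x-oversampled grid, kernel evaluated far beyond the truncation point
  H <- 40L
  tt <- seq(0, H / fs, length.out = H * 1000L + 1L)
  dt <- tt[2L] - tt[1L]
  # impulse response from the step response by numerical differentiation
  hv <- diff(fil$step_response(tt)) / dt
  # renormalize: the truncated step response is scaled; undo for the oracle
  acv <- function(lag) {
    sh <- lag * 1000L
    sum(hv[seq_len(length(hv) - sh)] * hv[(1L + sh):length(hv)]) * dt
  }
  rho_oracle <- vapply(0:12, acv, numeric(1)) / acv(0L)
  expect_equal(fil$acf[2L], rho_oracle[2L], tolerance = 1e-4)
  expect_equal(fil$acf[1:12], rho_oracle[1:12], tolerance = 1e-3)

  # truncation scan at threshold 1e-2: quadrature ACF of an effectively
  # untruncated kernel (threshold 1e-8), then scan for the smallest m such
  # that all lags >= m fall below the threshold
  fil_long <- lowpass_filter(4, 0.1, 1e4, acf_threshold = 1e-8)
  tt2 <- seq(0, (fil_long$m + 2) / 1e4, length.out = (fil_long$m + 2) * 1000L + 1L)
  hv2 <- diff(fil_long$step_response(tt2)) / (tt2[2L] - tt2[1L])
  acv2 <- function(lag) {
    sh <- lag * 1000L
    sum(hv2[seq_len(length(hv2) - sh)] * hv2[(1L + sh):length(hv2)])
  }
  rho2 <- vapply(0:(fil_long$m + 1L), acv2, numeric(1)) / acv2(0L)
  oracle_m <- max(which(abs(rho2[-1L]) >= 1e-2))
  fil2 <- lowpass_filter(4, 0.1, 1e4, acf_threshold = 1e-2)
  expect_identical(fil2$m, oracle_m + 1L)
})

test_that("kernel ACF is normalized and vanishes beyond the truncation length", {
  fil <- std_filter()
  acf_tbl <- kernel_acf(fil)
  expect_equal(acf_tbl$acf[1L], 1)
  expect_identical(nrow(acf_tbl), fil$m + 1L)
  # lag m + 1 of the truncated kernel is exactly zero (disjoint supports)
  expect_lt(abs(fil$acf_untruncated[fil$m + 2L]), 1e-3)
})

test_that("m is monotone non-increasing in the ACF threshold and 0 in the limit", {
  ths <- c(1e-4, 1e-3, 1e-2, 1e-1)
  ms <- vapply(ths, function(th) lowpass_filter(4, 0.1, 1e4, acf_threshold = th)$m,
               integer(1))
  expect_true(all(diff(ms) <= 0))
  # threshold above every lag >= 1: kernel collapses to (almost) a delta
  fil0 <- lowpass_filter(4, 0.1, 1e4, acf_threshold = 0.95)
  expect_identical(fil0$m, 0L)
  sig <- step_signal(c(1, 3), c(0, 0.05), c(0.05, 0.1))
  tt <- c(0.02, 0.07)
  expect_equal(convolve_step_signal(sig, fil0, tt), c(1, 3))
})

test_that("convolution is exact on constants, linear, and bounded for a jump", {
  fil <- std_filter()
  fs <- fil$sample_rate
  sig1 <- step_signal(c(0, 1), c(0, 0.05), c(0.05, 0.1))
  sig2 <- step_signal(c(2, -1), c(0, 0.05), c(0.05, 0.1))
  tt <- seq(0.049, 0.06, by = 1 / fs)
  c1 <- convolve_step_signal(sig1, fil, tt)
  c2 <- convolve_step_signal(sig2, fil, tt)
  mix <- step_signal(3 * sig1$value - 2 * sig2$value, sig1$left_end, sig1$right_end)
  expect_equal(convolve_step_signal(mix, fil, tt), 3 * c1 - 2 * c2,
               tolerance = 1e-12)
  # constant signal is reproduced exactly anywhere in the support
  expect_equal(convolve_step_signal(step_signal(2.5, 0, 1), fil, c(0.1, 0.9)),
               c(2.5, 2.5))
  # a single jump stays between the two levels up to the Bessel overshoot
  # (about 0.8% for 4 poles)
  tt_fine <- seq(0.049, 0.053, length.out = 2000)
  cv <- convolve_step_signal(sig1, fil, tt_fine)
  expect_gte(min(cv), -1e-2)
  expect_lte(max(cv), 1 + 1e-2)
  # step response limits: 0 before the jump, 1 beyond the kernel length
  expect_equal(convolve_step_signal(sig1, fil, 0.05), 0, tolerance = 1e-12)
  expect_equal(convolve_step_signal(sig1, fil, 0.05 + fil$m / fs), 1,
               tolerance = 2e-3)
  expect_error(convolve_step_signal(sig1, fil, 0.2), "support")
})

test_that("a sub-filter-length peak is attenuated by the convolution", {
  fil <- std_filter()
  fs <- fil$sample_rate
  len <- 0.5 * fil$m / fs
  sig <- step_signal(c(0, -1, 0), c(0, 0.05, 0.05 + len), c(0.05, 0.05 + len, 0.1))
  tt <- seq(0.049, 0.054, length.out = 3000)
  cv <- convolve_step_signal(sig, fil, tt)
  expect_gt(min(cv), -1) # the filtered signal does not reach the true level
  expect_lt(min(cv), -0.2) # but the event is clearly visible
})

test_that("peak attenuation grows with peak length and is at most 1", {
  fil <- std_filter()
  at <- vapply(c(1L, 3L, 6L, 11L, 22L), peak_attenuation, numeric(1), filter = fil)
  expect_true(all(diff(at) > 0))
  expect_true(all(at > 0 & at <= 1))
})

test_that("invalid filter specifications are rejected", {
  expect_error(lowpass_filter(4, 0.1, 1e4, kind = "butterworth"), "not implemented")
  expect_error(lowpass_filter(3, 0.1, 1e4), "poles")
  expect_error(lowpass_filter(4, 0.7, 1e4), "cutoff")
  expect_error(lowpass_filter(4, 0.1, 1e4, acf_threshold = 1.5), "acf_threshold")
  expect_error(lowpass_filter(4, 0.1, 1e4, acf_threshold = 0), "acf_threshold")
})
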