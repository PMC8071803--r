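# Large-scale multiscale detection (jsmurf) and noise estimation.

test_that("a noise-free filtered jump yields exactly one change near the truth", {
  fil <- std_filter()
  fs <- fil$sample_rate
  truth <- step_signal(c(0, 1), c(0, 0.05), c(0.05, 0.3))
  tr <- simulate_trace(truth, fil, n = 2048, sigma = 0, seed = 1)
  cv <- test_critval("jsmurf", 2048L)
  fit <- jsmurf(tr, fil, method_config("jsmurf", r = 400, seed = 11),
                test_store(), critval = cv$critval)
  expect_identical(nrow(fit$segments), 2L)
  expect_lte(abs(fit$segments$right_index[1L] - 0.05 * fs), fil$m)
  expect_equal(fit$segments$value, c(0, 1), tolerance = 1e-6)
})

test_that("the fit is translation and scale equivariant", {
  fil <- std_filter()
  truth <- step_signal(c(0, 1, 0.3), c(0, 0.05, 0.12), c(0.05, 0.12, 0.3))
  tr <- simulate_trace(truth, fil, n = 2048, sigma = 0.15, seed = 8)
  cfg <- method_config("jsmurf", r = 400, seed = 11)
  q <- test_critval("jsmurf", 2048L)$critval
  f0 <- jsmurf(tr$conductance, fil, cfg, test_store(), critval = q)
  f_shift <- jsmurf(tr$conductance + 5, fil, cfg, test_store(), critval = q)
  f_scale <- jsmurf(tr$conductance * 3.7, fil, cfg, test_store(), critval = q)
  expect_identical(f_shift$segments$right_index, f0$segments$right_index)
  expect_equal(f_shift$segments$value, f0$segments$value + 5, tolerance = 1e-9)
  expect_identical(f_scale$segments$right_index, f0$segments$right_index)
  expect_equal(f_scale$segments$value, f0$segments$value * 3.7, tolerance = 1e-9)
  expect_equal(f_scale$sigma, f0$sigma * 3.7, tolerance = 1e-9)
})

test_that("the dynamic program matches brute-force enumeration on tiny instances", {
  fil <- tiny_filter()
  expect_identical(fil$m, 3L)
  n <- 40L
  fs <- fil$sample_rate
  cases <- list(
    list(truth = step_signal(0, 0, 1), sigma = 0.5, seed = 4, q = 1.0),
    list(truth = step_signal(c(0, 3), c(0, 18 / fs), c(18 / fs, 1)),
         sigma = 0.4, seed = 5, q = 1.0),
    list(truth = step_signal(c(0, 3, 0), c(0, 12 / fs, 26 / fs),
                             c(12 / fs, 26 / fs, 1)), sigma = 0.4, seed = 6, q = 0.8),
    list(truth = step_signal(c(1, -2), c(0, 22 / fs), c(22 / fs, 1)),
         sigma = 1.2, seed = 7, q = 2.0),
    list(truth = step_signal(0, 0, 1), sigma = 1, seed = 8, q = 0.3)
  )
  for (cs in cases) {
    y <- simulate_trace(cs$truth, fil, n = n, sigma = cs$sigma, seed = cs$seed)$conductance
    fit <- jsmurf(y, fil, method_config("jsmurf", seed = 1, r = 150),
                  test_store(), critval = cs$q)
    oracle <- oracle_min_k_fit(y, fil, cs$q, max_k = 3L)
    expect_false(is.null(oracle))
    expect_identical(nrow(fit$segments) - 1L, oracle$K)
    # the boundaries are least-squares optimal among minimal-K segmentations
    rss_fit <- sum(vapply(seq_len(nrow(fit$segments)), function(j) {
      yy <- y[fit$segments$left_index[j]:fit$segments$right_index[j]]
      sum((yy - mean(yy))^2)
    }, numeric(1)))
    expect_lte(rss_fit, oracle$rss + 1e-9)
  }
})

test_that("noise estimation is accurate and robust to gross outliers", {
  fil <- std_filter()
  n <- 1e5
  y <- simulate_null(n, fil, seed = 31)$conductance * 2
  expect_lt(abs(estimate_noise(y, fil) - 2), 3 * 2 / sqrt(n / (fil$m + 1)))
  # 1% gross outliers of size 100 sigma barely move the estimate
  y_out <- y
  idx <- seq(50L, n, by = 100L)
  y_out[idx] <- y_out[idx] + 200
  expect_lt(abs(estimate_noise(y_out, fil) - 2), 0.2)
  expect_gt(sd(y_out), 10) # a non-robust estimate would be far off
  # noise-free data
  expect_equal(estimate_noise(rep(1, 100), fil), 0)
})

test_that("segment-wise noise estimates recover heterogeneous levels", {
  fil <- std_filter()
  truth <- step_signal(c(0, 2, 0), c(0, 0.15, 0.3), c(0.15, 0.3, 0.5),
                       noise_level = c(0.1, 0.3, 0.1))
  tr <- simulate_trace(truth, fil, n = 4096, seed = 4)
  cfg <- method_config("jsmurf", noise = "heterogeneous", r = 300, seed = 11)
  cv <- test_critval("jsmurf", 4096L, r = 300, noise = "heterogeneous")
  fit <- jsmurf(tr, fil, cfg, test_store(), critval = cv$critval)
  expect_identical(nrow(fit$segments), 3L)
  est <- estimate_noise(tr, fil, fit)
  expect_equal(est$noise_level, c(0.1, 0.3, 0.1), tolerance = 0.15)
  expect_false(any(est$inherited))
  expect_equal(fit$segments$value, c(0, 2, 0), tolerance = 0.1)
})

test_that("detection power is non-decreasing in event length", {
  fil <- std_filter()
  fs <- fil$sample_rate
  n <- 1024L
  cv <- test_critval("jsmurf", n)
  cfg <- method_config("jsmurf", r = 400, seed = 11)
  lens <- c(24L, 60L, 150L)
  amp <- 0.9
  power <- vapply(lens, function(L) {
    truth <- step_signal(c(0, amp, 0), c(0, 0.03, 0.03 + L / fs),
                         c(0.03, 0.03 + L / fs, n / fs + 0.1))
    mean(vapply(1:40, function(i) {
      tr <- simulate_trace(truth, fil, n = n, sigma = 1, seed = 5000 + 97 * L + i)
      nrow(jsmurf(tr, fil, cfg, test_store(), critval = cv$critval)$segments) > 1L
    }, logical(1)))
  }, numeric(1))
  expect_lte(power[1L], power[2L] + 0.125)
  expect_lte(power[2L], power[3L] + 0.125)
  expect_gt(power[3L], power[1L] - 0.125)
})

test_that("short traces are rejected", {
  fil <- std_filter()
  expect_error(jsmurf(rnorm(20), fil, method_config("jsmurf", r = 150)), "too short")
})
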