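# Short-event detection: jules (all scales + postfilter) and hilde
# (jsmurf stage + matched local tests).

test_that("the postfilter collapses the noise-free staircase of a filtered jump", {
  fil <- std_filter()
  fs <- fil$sample_rate
  truth <- step_signal(c(0, 1), c(0, 500.37 / fs), c(500.37 / fs, 0.3))
  tr <- simulate_trace(truth, fil, n = 2048, sigma = 0, seed = 1)
  cv <- test_critval("jules", 2048L)
  fit <- jules(tr, fil, method_config("jules", r = 400, seed = 11),
               test_store(), critval = cv$critval)
  expect_identical(nrow(fit$segments), 2L)
  expect_equal(fit$segments$value, c(0, 1), tolerance = 1e-3)
  expect_lte(abs(fit$segments$right_index[1L] - 500), fil$m)
})

test_that("a noise-free 2-sample peak gives two changes with attenuated middle level", {
  fil <- std_filter()
  fs <- fil$sample_rate
  truth <- step_signal(c(0, 1, 0), c(0, 0.05, 0.05 + 2 / fs),
                       c(0.05, 0.05 + 2 / fs, 0.3))
  tr <- simulate_trace(truth, fil, n = 2048, sigma = 0, seed = 1)
  cv <- test_critval("jules", 2048L)
  fit <- jules(tr, fil, method_config("jules", r = 400, seed = 11),
               test_store(), critval = cv$critval)
  expect_identical(nrow(fit$segments), 3L)
  v <- fit$segments$value
  expect_gt(v[2L], max(v[1L], v[3L])) # middle level between/above the flanks
  expect_lt(v[2L], 1)                 # but attenuated toward the baseline
  expect_equal(v[c(1L, 3L)], c(0, 0), tolerance = 1e-3)
})

test_that("the incremental-step postfilter is idempotent", {
  m <- 11L
  # synthetic staircase parts: up-run with short intermediate segments,
  # a genuine peak, and a long genuine segment
  parts <- list(
    starts = c(1L, 51L, 53L, 55L, 120L, 123L, 200L),
    ends = c(50L, 52L, 54L, 119L, 122L, 199L, 300L),
    value = c(0, 0.3, 0.7, 1, 2.5, 1, 0.2),
    noise_level = rep(NA_real_, 7L),
    noise_inherited = rep(FALSE, 7L),
    sigma = 1
  )
  once <- patchseg:::postfilter_increments(parts, m)
  twice <- patchseg:::postfilter_increments(once, m)
  expect_identical(once, twice)
  # the 0 -> 1 staircase collapsed, the peak at 120 survived
  expect_true(2.5 %in% once$value)
  expect_lt(length(once$value), 7L)
})

test_that("jules refuses heterogeneous noise", {
  expect_error(method_config("jules", noise = "heterogeneous"), "homogeneous")
  fil <- std_filter()
  cfg <- method_config("jules", r = 150)
  cfg$noise <- "heterogeneous"
  expect_error(jules(rnorm(100), fil, cfg), "hilde")
})

test_that("hilde with an empty scale set equals jsmurf at alpha1", {
  fil <- std_filter()
  truth <- step_signal(c(0, 1), c(0, 0.05), c(0.05, 0.2))
  tr <- simulate_trace(truth, fil, n = 1024, sigma = 0.2, seed = 3)
  cfg_h <- method_config("hilde", r = 300, seed = 11, scales = integer(0), l_max = 5L)
  cv_h <- get_critval(cfg_h, 1024L, fil, test_store())
  fit_h <- hilde(tr, fil, cfg_h, test_store(), critval = cv_h)
  cfg_1 <- method_config("jsmurf", alpha = 0.01, r = 300, seed = 11)
  fit_1 <- jsmurf(tr, fil, cfg_1, test_store(), critval = cv_h$stage1)
  expect_identical(fit_h$segments$right_index, fit_1$segments$right_index)
  expect_equal(fit_h$segments$value, fit_1$segments$value)
  expect_identical(fit_h$method, "hilde")
})

test_that("hilde finds sub-filter-length peaks that the large-scale stage misses", {
  fil <- std_filter()
  fs <- fil$sample_rate
  n <- 1024L
  cfg_h <- method_config("hilde", r = 400, seed = 11, scales = 1L, l_max = 1L)
  cv <- get_critval(cfg_h, n, fil, test_store())
  cfg_1 <- method_config("jsmurf", alpha = 0.01, r = 400, seed = 11)
  tpl <- patchseg:::peak_template(fil, 1L)
  A <- 1.15 * cv$local[[1L]] / tpl$amp_scale # just above the local threshold
  truth <- step_signal(c(0, A, 0), c(0, 0.05, 0.05 + 1 / fs),
                       c(0.05, 0.05 + 1 / fs, 0.2))
  reps <- 30L
  s1_level <- 0L
  h_found <- 0L
  stage1_subset <- TRUE
  for (i in seq_len(reps)) {
    tr <- simulate_trace(truth, fil, n = n, sigma = 1, seed = 7000 + i)
    f1 <- jsmurf(tr, fil, cfg_1, test_store(), critval = cv$stage1)
    fh <- hilde(tr, fil, cfg_h, test_store(), critval = cv)
    # stage-1 alone never recovers the peak's conductance level
    if (any(f1$segments$value > A / 2)) s1_level <- s1_level + 1L
    seg <- fh$segments
    if (nrow(seg) > 1L && any(seg$left_index <= 0.05 * fs + 1 + fil$m &
                              seg$right_index >= 0.05 * fs & seg$value > A / 2)) {
      h_found <- h_found + 1L
    }
    # stage-1 detections are a subset of the final detection set
    if (!all(f1$segments$right_index[-nrow(f1$segments)] %in%
             fh$segments$right_index)) {
      stage1_subset <- FALSE
    }
  }
  expect_identical(s1_level, 0L)
  expect_gte(h_found, reps %/% 3L)
  expect_true(stage1_subset)
})

test_that("hilde detection probability decreases as the peak shrinks below the filter length", {
  fil <- std_filter()
  fs <- fil$sample_rate
  n <- 1024L
  scales <- c(2L, 5L, 9L)
  cfg_h <- method_config("hilde", r = 400, seed = 11, scales = scales, l_max = 9L)
  cv <- get_critval(cfg_h, n, fil, test_store())
  A <- 1.1 * cv$local[[2L]] / patchseg:::peak_template(fil, 5L)$amp_scale
  power <- vapply(scales, function(l) {
    truth <- step_signal(c(0, A, 0), c(0, 0.05, 0.05 + l / fs),
                         c(0.05, 0.05 + l / fs, 0.2))
    mean(vapply(1:30, function(i) {
      tr <- simulate_trace(truth, fil, n = n, sigma = 1, seed = 9000 + 31 * l + i)
      nrow(hilde(tr, fil, cfg_h, test_store(), critval = cv)$segments) > 1L
    }, logical(1)))
  }, numeric(1))
  expect_lte(power[1L], power[2L] + 0.15)
  expect_lte(power[2L], power[3L] + 0.15)
  expect_gt(power[3L], power[1L] - 0.15)
})
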