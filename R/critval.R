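# Monte-Carlo calibration of critical values, with a persistent plain-text
# cache so each (statistic family, n, filter, scales, r) simulation runs once.
# Null statistics are simulated with unit noise level; because every statistic
# is standardized by a scale-equivariant noise estimate, one simulation serves
# all noise levels.

#' Create or open a critical-value cache
#'
#' @param path Directory for the cache files (one self-describing JSON file
#'   per key). Created if missing. Defaults to a session-local directory.
#' @return A `critval_store` object.
#' @export
critval_store <- function(path = file.path(tempdir(), "patchseg-critval")) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort(sprintf("cannot create cache directory '%s'", path))
  structure(list(path = path), class = "critval_store")
}

#' @export
print.critval_store <- function(x, ...) {
  files <- list.files(x$path, pattern = "\\.json$")
  cat(sprintf("<critval_store> %s (%d cached simulation(s))\n", x$path, length(files)))
  invisible(x)
}

store_key <- function(family, n, filter, scales, r) {
  sprintf("%s_n%d_r%d_%s_s%s", family, as.integer(n), as.integer(r),
          filter$fingerprint, paste(scales, collapse = "-"))
}

store_read <- function(store, key) {
  file <- file.path(store$path, paste0(key, ".json"))
  if (!file.exists(file)) return(NULL)
  obj <- tryCatch(jsonlite::read_json(file, simplifyVector = TRUE), error = function(e) NULL)
  if (is.null(obj) || !identical(obj$key, key) || is.null(obj$samples)) {
    warn(sprintf("corrupted critical-value cache entry '%s'; re-simulating", key))
    return(NULL)
  }
  samples <- obj$samples
  if (is.data.frame(samples)) samples <- as.list(samples)
  lapply(samples, as.numeric)
}

# samples are serialized as %.17g strings so reloading is bit-identical
store_write <- function(store, key, samples) {
  file <- file.path(store$path, paste0(key, ".json"))
  obj <- list(version = 1L, key = key,
              samples = lapply(samples, function(v) sprintf("%.17g", v)))
  jsonlite::write_json(obj, file, auto_unbox = TRUE)
  invisible(file)
}

# conservative empirical quantile ("higher" interpolation) of a sorted sample
quantile_higher <- function(sorted, p) {
  idx <- min(max(1L, as.integer(ceiling(p * length(sorted)))), length(sorted))
  sorted[idx]
}

#' Monte-Carlo critical values for a detection method
#'
#' Looks up (or simulates and caches) the null distribution of the method's
#' detection statistics for traces of length `n` under `filter`, and returns
#' the critical values at the configured error levels. The simulation is
#' deterministic given `config$seed` and the cache key; a cached sample is
#' reused for any error level without re-simulation.
#'
#' For `jsmurf` and `jules` the statistic is the smallest critical value at
#' which a pure-noise trace is idealized without any change, so thresholding
#' at the `(1 - alpha)` empirical quantile gives family-wise error `alpha` by
#' construction. For `hilde`, `alpha1` calibrates the large-scale multiscale
#' statistic and `alpha2` is split equally (Bonferroni) across the local-test
#' scales.
#'
#' @param config A [method_config()].
#' @param n Trace length in samples.
#' @param filter A [lowpass_filter()].
#' @param store A [critval_store()].
#' @param messages If a positive integer, print a progress message every
#'   `messages` Monte-Carlo repetitions.
#' @return For `jsmurf`/`jules`, a list with elements `critval` (scalar) and
#'   `sample`. For `hilde`, a list with `stage1` (scalar critical value at
#'   `alpha1`), `local` (named vector of per-scale critical values at the
#'   `alpha2` split) and the underlying sorted samples.
#' @export
get_critval <- function(config, n, filter, store = critval_store(), messages = 0L) {
  stopifnot(inherits(config, "method_config"), inherits(filter, "lowpass_filter"))
  if (config$r < 100L) abort("`r` must be at least 100: the quantile error would be too large")
  n <- as.integer(n)
  if (config$method %in% c("jsmurf", "jules")) {
    sample <- null_sample_multiscale(config$method, config, n, filter, store, messages)
    list(critval = quantile_higher(sample, 1 - config$alpha), sample = sample)
  } else {
    stage1_cfg <- config
    stage1_cfg$method <- "jsmurf"
    s1 <- null_sample_multiscale("jsmurf", stage1_cfg, n, filter, store, messages)
    sc <- resolve_scales(config, filter)
    if (length(sc$scales) == 0L) {
      return(list(stage1 = quantile_higher(s1, 1 - config$alpha1),
                  local = numeric(0), stage1_sample = s1,
                  local_samples = list(), scales = integer(0)))
    }
    loc <- null_sample_local(config, n, filter, sc$scales, store, messages)
    p <- 1 - config$alpha2 / length(sc$scales)
    list(
      stage1 = quantile_higher(s1, 1 - config$alpha1),
      local = setNames(vapply(loc, quantile_higher, numeric(1), p = p),
                       paste0("l", sc$scales)),
      stage1_sample = s1, local_samples = loc, scales = sc$scales
    )
  }
}

null_sample_multiscale <- function(method, config, n, filter, store, messages = 0L) {
  scales <- dyadic_scales(n, if (method == "jsmurf") filter$m + 2L else 1L)
  family <- paste(method, substr(config$noise, 1, 3), sep = "-")
  key <- store_key(family, n, filter, scales, config$r)
  cached <- store_read(store, key)
  if (!is.null(cached)) return(cached$stat)
  seed0 <- derive_seed(config$seed, key)
  stat <- numeric(config$r)
  for (i in seq_len(config$r)) {
    y <- coloured_noise(n, filter, derive_seed(seed0, paste0("rep", i)))
    stat[i] <- multiscale_null_stat(y, filter, method, config$noise)
    if (messages > 0L && i %% messages == 0L) {
      message(sprintf("critval [%s]: %d / %d repetitions", family, i, config$r))
    }
  }
  stat <- sort(stat)
  store_write(store, key, list(stat = stat))
  stat
}

null_sample_local <- function(config, n, filter, scales, store, messages = 0L) {
  family <- paste("hilde-local", substr(config$noise, 1, 3), sep = "-")
  key <- store_key(family, n, filter, scales, config$r)
  cached <- store_read(store, key)
  if (!is.null(cached)) return(cached)
  seed0 <- derive_seed(config$seed, key)
  templates <- lapply(scales, peak_template, filter = filter)
  stats <- matrix(NA_real_, nrow = config$r, ncol = length(scales))
  for (i in seq_len(config$r)) {
    y <- coloured_noise(n, filter, derive_seed(seed0, paste0("rep", i)))
    stats[i, ] <- local_max_stats(y, filter, scales, level = mean(y),
                                  sigma = noise_sd_estimate(y, filter),
                                  templates = templates)
    if (messages > 0L && i %% messages == 0L) {
      message(sprintf("critval [%s]: %d / %d repetitions", family, i, config$r))
    }
  }
  out <- lapply(seq_along(scales), function(s) sort(stats[, s]))
  names(out) <- paste0("l", scales)
  store_write(store, key, out)
  out
}

# Whitened matched-filter template for a peak of length l samples: the test
# window spans the causal response (l + m samples); weights are
# Sigma^{-1} r normalized to unit null variance, so the statistic
# sum(g * (y - c)) / sigma is standard normal under the null and has mean
# amplitude * amp_scale for a unit peak aligned with the grid.
peak_template <- function(filter, l) {
  m <- filter$m
  w <- l + m
  fs <- filter$sample_rate
  tt <- seq_len(w) / fs
  r <- filter$step_response(tt) - filter$step_response(tt - l / fs)
  rho <- filter$acf
  Sig <- outer(seq_len(w), seq_len(w), function(i, j) {
    d <- abs(i - j)
    ifelse(d <= m, rho[d + 1L], 0)
  })
  gi <- solve(Sig, r)
  amp_scale <- sqrt(drop(crossprod(r, gi)))
  list(g = gi / amp_scale, amp_scale = amp_scale, w = w, response = r)
}

# matched-filter statistics for all windows [i, i + w - 1] in [from, to]
local_scan <- function(y, template, level, sigma, from = 1L, to = length(y)) {
  w <- template$w
  if (to - from + 1L < w) return(NULL)
  yy <- y[from:to] - level
  Tstat <- stats::filter(yy, rev(template$g), method = "convolution", sides = 1)
  Tstat <- as.numeric(Tstat[w:length(yy)]) / sigma
  list(start = from:(to - w + 1L), stat = Tstat)
}

# per-scale maxima of the absolute matched-filter statistic
local_max_stats <- function(y, filter, scales, level, sigma, from = 1L, to = length(y),
                            templates = NULL) {
  templates <- templates %||% lapply(scales, peak_template, filter = filter)
  vapply(seq_along(scales), function(s) {
    sc <- local_scan(y, templates[[s]], level, sigma, from, to)
    if (is.null(sc)) return(-Inf)
    max(abs(sc$stat))
  }, numeric(1))
}
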