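# Shared fixtures: filters are memoized per session, Monte-Carlo calibrations
# are cached in one session-wide store so each simulation runs once.

.fixtures <- new.env(parent = emptyenv())

# the standard hardware filter: 4-pole Bessel, normalized cutoff 0.1
std_filter <- function(sample_rate = 1e4) {
  key <- paste0("std", sample_rate)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- lowpass_filter(4, 0.1, sample_rate)
  }
  .fixtures[[key]]
}

# small filter (m = 3) for brute-force-sized instances
tiny_filter <- function() {
  if (is.null(.fixtures$tiny)) {
    .fixtures$tiny <- lowpass_filter(2, 0.2, 1e4, acf_threshold = 1e-2)
  }
  .fixtures$tiny
}

test_store <- function() {
  if (is.null(.fixtures$store)) {
    .fixtures$store <- critval_store(file.path(tempdir(), "patchseg-test-cache"))
  }
  .fixtures$store
}

# calibrated critical values shared across test files
test_critval <- function(method, n, r = 400, noise = "homogeneous", seed = 11,
                         filter = std_filter(), ...) {
  cfg <- method_config(method, noise = noise, r = r, seed = seed, ...)
  get_critval(cfg, n, filter, test_store())
}

# ---- independent brute-force oracle for the minimal-jump fit ---------------
# Direct re-implementation from the definitions: dyadic interval lengths,
# means computed by plain sums with the first `drop` samples of each interval
# ignored, feasibility by interval intersection, exhaustive enumeration of all
# change sets up to max_k.

oracle_scales <- function(n, min_len) {
  out <- integer(0)
  L <- min_len
  while (L <= n) {
    out <- c(out, L)
    L <- 2L * L
  }
  out
}

oracle_sd_factor <- function(k, rho) {
  s <- 0
  for (h in seq_len(min(k - 1L, length(rho) - 1L))) {
    s <- s + 2 * (k - h) * rho[h + 1L]
  }
  sqrt((k + s) / k^2)
}

# feasibility of one segment [a, b] for level bracket purposes
oracle_segment_ok <- function(y, a, b, filter, q, sigma, drop, min_len, eps) {
  n <- length(y)
  lo <- -Inf
  hi <- Inf
  for (L in oracle_scales(n, min_len)) {
    if (L > b - a + 1L) next
    pen <- sqrt(2 * log(exp(1) * n / L))
    if (q + pen < 0) return(FALSE)
    v <- oracle_sd_factor(L - drop, filter$acf)
    t <- sigma * v * (q + pen) + eps
    for (i in a:(b - L + 1L)) {
      M <- mean(y[(i + drop):(i + L - 1L)])
      lo <- max(lo, M - t)
      hi <- min(hi, M + t)
      if (lo > hi) return(FALSE)
    }
  }
  TRUE
}

# exhaustive minimal-K search; returns K, the best boundaries and their RSS
oracle_min_k_fit <- function(y, filter, q, max_k = 3L) {
  n <- length(y)
  m <- filter$m
  drop <- m
  min_len <- m + 2L
  sigma <- mad(y[(m + 2L):n] - y[seq_len(n - m - 1L)]) / sqrt(2)
  eps <- 1e-7 * diff(range(y)) + 1e-12
  seg_ok <- function(a, b) oracle_segment_ok(y, a, b, filter, q, sigma, drop, min_len, eps)
  rss <- function(a, b) sum((y[a:b] - mean(y[a:b]))^2)
  for (K in 0:max_k) {
    best <- NULL
    combs <- if (K == 0L) list(integer(0)) else
      utils::combn(n - 1L, K, simplify = FALSE)
    for (bnd in combs) {
      starts <- c(1L, bnd + 1L)
      ends <- c(bnd, n)
      if (all(mapply(seg_ok, starts, ends))) {
        r <- sum(mapply(rss, starts, ends))
        if (is.null(best) || r < best$rss) best <- list(bounds = bnd, rss = r)
      }
    }
    if (!is.null(best)) return(list(K = K, bounds = best$bounds, rss = best$rss))
  }
  NULL
}
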