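# Multiscale machinery shared by jsmurf / jules / hilde:
#   - dyadic interval system,
#   - correlation-aware standardization of local means,
#   - scale penalties and the calibration (null) statistic,
#   - feasibility of a constant fit on a segment and the minimal-jump fit
#     (greedy bound + dynamic program with least-squares tie-break).
#
# The interval system uses all start positions and lengths on a dyadic grid.
# Feasibility of a segment is then down-closed (every interval constraint of
# [a, b] is also a constraint of [a, b + 1]), which makes the greedy sweep
# provably minimal in the number of jumps and allows a per-scale min/max
# reduction of the calibration statistic.

# interval lengths: min_len, 2 min_len, 4 min_len, ... <= n
dyadic_scales <- function(n, min_len) {
  out <- integer(0)
  L <- as.integer(min_len)
  while (L <= n) {
    out <- c(out, L)
    L <- 2L * L
  }
  out
}

# standard deviation of the mean of k consecutive noise samples with unit
# marginal sd and autocorrelation rho (rho[1] = lag 0)
mean_sd_factor <- function(k, rho) {
  m <- length(rho) - 1L
  h <- seq_len(min(k - 1L, m))
  s <- if (length(h) == 0L) 0 else 2 * sum((k - h) * rho[h + 1L])
  sqrt((k + s) / k^2)
}

scale_penalty <- function(n, L) sqrt(2 * log(exp(1) * n / L))

# context bundling everything the fit and the statistics need
ms_context <- function(y, filter, method, noise, q = NA_real_) {
  n <- length(y)
  m <- filter$m
  drop <- if (method == "jsmurf") m else 0L
  min_len <- if (method == "jsmurf") m + 2L else 1L
  scales <- dyadic_scales(n, min_len)
  if (length(scales) == 0L) {
    abort(sprintf("trace too short: %d samples with filter length m = %d", n, m))
  }
  k <- scales - drop
  v <- vapply(k, mean_sd_factor, numeric(1), rho = filter$acf)
  pen <- scale_penalty(n, scales)
  sigma <- noise_sd_estimate(y, filter)
  list(
    y = y, cs = c(0, cumsum(y)), cs2 = c(0, cumsum(y^2)),
    n = n, m = m, drop = drop, scales = scales, v = v, pen = pen,
    q = q, sigma = sigma, noise = noise, filter = filter,
    eps = 1e-7 * diff(range(y)) + 1e-12
  )
}

# rolling means over windows [i, i + L - 1], keeping samples i + drop .. i + L - 1
rolling_kept_means <- function(ctx, a, b, L) {
  idx <- a:(b - L + 1L)
  (ctx$cs[idx + L] - ctx$cs[idx + ctx$drop]) / (L - ctx$drop)
}

# robust noise level from lag-(m+1) differences, MAD-based
noise_sd_estimate <- function(y, filter) {
  m <- filter$m
  n <- length(y)
  if (n < m + 3L) return(NA_real_)
  d <- y[(m + 2L):n] - y[seq_len(n - m - 1L)]
  mad(d) / sqrt(2)
}

# segment-local noise level (heterogeneous regime): same estimator on the
# segment with the first m samples dropped when the segment follows a change
segment_noise_estimate <- function(ctx, a, b) {
  a_eff <- if (a > 1L) a + ctx$m else a
  if (b - a_eff + 1L < 2L * (ctx$m + 1L)) return(NA_real_)
  yy <- ctx$y[a_eff:b]
  d <- yy[(ctx$m + 2L):length(yy)] - yy[seq_len(length(yy) - ctx$m - 1L)]
  mad(d) / sqrt(2)
}

segment_sigma <- function(ctx, a, b) {
  if (ctx$noise == "homogeneous") return(ctx$sigma)
  s <- segment_noise_estimate(ctx, a, b)
  if (is.na(s)) ctx$sigma else s
}

# Is a constant level consistent with all interval constraints inside [a, b]?
# Returns the feasible level interval (lo > hi means infeasible).
segment_level_bounds <- function(ctx, a, b) {
  len <- b - a + 1L
  lo <- -Inf
  hi <- Inf
  sig <- segment_sigma(ctx, a, b)
  for (s in seq_along(ctx$scales)) {
    L <- ctx$scales[s]
    if (L > len) break
    tq <- ctx$q + ctx$pen[s]
    if (tq < 0) return(c(1, 0)) # critical value below the penalty: nothing fits
    M <- rolling_kept_means(ctx, a, b, L)
    t <- sig * ctx$v[s] * tq + ctx$eps
    lo <- max(lo, max(M) - t)
    hi <- min(hi, min(M) + t)
    if (lo > hi) return(c(lo, hi))
  }
  c(lo, hi)
}

segment_feasible <- function(ctx, a, b) {
  bounds <- segment_level_bounds(ctx, a, b)
  bounds[1] <= bounds[2]
}

# largest b >= a such that [a, b] is feasible (feasibility is down-closed in b
# for the homogeneous statistic; binary search)
max_feasible_end <- function(ctx, a) {
  if (segment_feasible(ctx, a, ctx$n)) return(ctx$n)
  lo <- a
  hi <- ctx$n
  while (lo < hi) {
    mid <- lo + as.integer(ceiling((hi - lo) / 2))
    if (segment_feasible(ctx, a, mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

min_feasible_start <- function(ctx, b) {
  if (segment_feasible(ctx, 1L, b)) return(1L)
  lo <- 1L
  hi <- b
  while (lo < hi) {
    mid <- as.integer(floor((lo + hi) / 2))
    if (segment_feasible(ctx, mid, b)) hi <- mid else lo <- mid + 1L
  }
  hi
}

# smallest critical value for which the trace admits a 0-change fit: the
# calibration statistic. Computed via the per-scale min/max reduction and a
# 1-D convex minimization over the level c.
multiscale_null_stat <- function(y, filter, method = c("jsmurf", "jules"),
                                 noise = "homogeneous") {
  method <- match.arg(method)
  ctx <- ms_context(y, filter, method, noise)
  sig <- segment_sigma(ctx, 1L, ctx$n)
  stats_per_scale <- lapply(seq_along(ctx$scales), function(s) {
    M <- rolling_kept_means(ctx, 1L, ctx$n, ctx$scales[s])
    list(max = max(M), min = min(M), w = sig * ctx$v[s], pen = ctx$pen[s])
  })
  objective <- function(c) {
    max(vapply(stats_per_scale, function(st) {
      max(st$max - c, c - st$min) / st$w - st$pen
    }, numeric(1)))
  }
  opt <- optimize(objective, range(y), tol = 1e-10)
  # polish: the objective is piecewise linear; evaluate at the optimum
  opt$objective
}

# minimal-jump fit subject to all interval constraints at critical value q
ms_fit_segments <- function(y, filter, method, noise, q) {
  ctx <- ms_context(y, filter, method, noise, q = q)
  n <- ctx$n

  ## forward greedy: latest possible segment ends (minimal number of jumps)
  fwd <- integer(0)
  a <- 1L
  repeat {
    b <- max_feasible_end(ctx, a)
    fwd <- c(fwd, b)
    if (b >= n) break
    a <- b + 1L
  }
  K <- length(fwd) - 1L
  if (K == 0L) return(finish_fit(ctx, integer(0)))

  ## backward greedy: earliest possible segment starts
  bwd <- integer(0)
  b <- n
  repeat {
    a <- min_feasible_start(ctx, b)
    bwd <- c(a, bwd)
    if (a <= 1L) break
    b <- a - 1L
  }
  if (length(bwd) - 1L != K) {
    # non-monotone feasibility (possible under segment-local studentization):
    # fall back to the forward greedy boundaries
    return(finish_fit(ctx, fwd[seq_len(K)]))
  }
  lower <- bwd[-1L] - 1L     # earliest boundary positions
  upper <- fwd[seq_len(K)]   # latest boundary positions

  ## dynamic program over the boundary windows, least-squares tie-break
  rss <- function(a, b) {
    s <- ctx$cs[b + 1L] - ctx$cs[a]
    ctx$cs2[b + 1L] - ctx$cs2[a] - s^2 / (b - a + 1L)
  }
  cand <- lapply(seq_len(K), function(j) lower[j]:upper[j])
  cost <- vector("list", K)
  back <- vector("list", K)
  cost[[1L]] <- vapply(cand[[1L]], function(e) {
    if (segment_feasible(ctx, 1L, e)) rss(1L, e) else Inf
  }, numeric(1))
  if (K > 1L) {
    for (j in 2L:K) {
      cost[[j]] <- rep(Inf, length(cand[[j]]))
      back[[j]] <- rep(NA_integer_, length(cand[[j]]))
      for (ie in seq_along(cand[[j]])) {
        e <- cand[[j]][ie]
        prev <- cand[[j - 1L]]
        ok <- which(prev < e & is.finite(cost[[j - 1L]]))
        for (ip in ok) {
          if (!segment_feasible(ctx, prev[ip] + 1L, e)) next
          val <- cost[[j - 1L]][ip] + rss(prev[ip] + 1L, e)
          if (val < cost[[j]][ie]) {
            cost[[j]][ie] <- val
            back[[j]][ie] <- ip
          }
        }
      }
    }
  }
  final <- vapply(seq_along(cand[[K]]), function(ie) {
    e <- cand[[K]][ie]
    if (!is.finite(cost[[K]][ie])) return(Inf)
    if (!segment_feasible(ctx, e + 1L, n)) return(Inf)
    cost[[K]][ie] + rss(e + 1L, n)
  }, numeric(1))
  if (all(!is.finite(final))) {
    # the greedy path is always feasible, so this cannot happen for the
    # homogeneous statistic; guard for the studentized variant
    return(finish_fit(ctx, fwd[seq_len(K)]))
  }
  ie <- which.min(final)
  bounds <- integer(K)
  bounds[K] <- cand[[K]][ie]
  if (K > 1L) {
    for (j in K:2L) {
      ie <- back[[j]][ie]
      bounds[j - 1L] <- cand[[j - 1L]][ie]
    }
  }
  finish_fit(ctx, bounds)
}

# assemble the fitted step signal from boundary indices
finish_fit <- function(ctx, bounds) {
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, ctx$n)
  value <- numeric(length(starts))
  noise_level <- rep(NA_real_, length(starts))
  inherited <- rep(FALSE, length(starts))
  for (j in seq_along(starts)) {
    bl <- segment_level_bounds(ctx, starts[j], ends[j])
    mu <- (ctx$cs[ends[j] + 1L] - ctx$cs[starts[j]]) / (ends[j] - starts[j] + 1L)
    value[j] <- min(max(mu, bl[1]), bl[2])
    if (ctx$noise == "heterogeneous") {
      noise_level[j] <- segment_noise_estimate(ctx, starts[j], ends[j])
    }
  }
  if (ctx$noise == "heterogeneous") {
    for (j in seq_along(starts)) {
      if (is.na(noise_level[j])) {
        nb <- c(j - 1L, j + 1L)
        nb <- nb[nb >= 1L & nb <= length(starts)]
        cands <- noise_level[nb]
        noise_level[j] <- if (all(is.na(cands))) ctx$sigma else mean(cands, na.rm = TRUE)
        inherited[j] <- TRUE
      }
    }
  }
  list(starts = starts, ends = ends, value = value,
       noise_level = noise_level, noise_inherited = inherited,
       sigma = ctx$sigma)
}
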