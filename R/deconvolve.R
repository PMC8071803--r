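# Filter-aware local deconvolution: time-continuous refinement of isolated
# single changes and isolated peaks by least squares against the convolved
# step model; clusters of three or more close changes are flagged instead.

#' Local deconvolution of an idealization
#'
#' Refines the change times and conductance levels of a grid-resolution
#' idealization using the known filter kernel. Each detected change is
#' classified by its distance to its neighbours: isolated single changes are
#' refined by least squares over `(tau, c_left, c_right)` against the
#' convolved two-level step; isolated pairs (peaks) jointly over
#' `(tau1, tau2, c_left, c_mid, c_right)`. Change times are searched on a
#' continuous grid refined to a resolution of `1/(100 f_s)`. Neighbours must
#' be at least `3 m / f_s` apart under homogeneous noise and `5 m / f_s` under
#' heterogeneous noise for a change to count as isolated; clusters of three or
#' more close changes are left at grid resolution and flagged (see
#' [mark_no_deconvolution()]), with a warning.
#'
#' Under heterogeneous noise, residuals are weighted by the segment-wise noise
#' levels, samples in a transition inheriting the right segment's level.
#'
#' @param fit An `ms_fit` from [jsmurf()], [jules()] or [hilde()].
#' @param trace The trace the fit was computed from.
#' @param filter A [lowpass_filter()].
#' @return The refined `ms_fit`; change counts are unchanged, `deconvolved`
#'   marks refined changes, and `attr`ibute-like field `no_deconvolution`
#'   holds indices of segments in non-deconvolvable clusters.
#' @export
deconvolve_locally <- function(fit, trace, filter) {
  stopifnot(inherits(fit, "ms_fit"), inherits(filter, "lowpass_filter"))
  y <- trace_values(trace)
  n <- length(y)
  fs <- filter$sample_rate
  m <- filter$m
  seg <- fit$segments
  K <- nrow(seg) - 1L
  if (K == 0L) return(fit)
  iso <- if (fit$noise == "heterogeneous") 5L * m else 3L * m
  ev <- seg$right_index[-nrow(seg)] # change boundaries (last index of left segment)

  ## cluster changes that are closer than the isolation distance
  cluster_id <- cumsum(c(1L, diff(ev) >= iso))
  cluster_sizes <- table(cluster_id)

  values <- seg$value
  left_time <- seg$left_end
  deconvolved <- rep(FALSE, nrow(seg))
  no_deco <- integer(0)
  weights <- if (fit$noise == "heterogeneous") seg$noise_level else NULL

  value_votes <- vector("list", nrow(seg))
  for (cid in unique(cluster_id)) {
    members <- which(cluster_id == cid)
    if (length(members) == 1L) {
      j <- members
      e <- ev[j]
      prev_e <- if (j > 1L) ev[j - 1L] else 0L
      next_e <- if (j < K) ev[j + 1L] else n
      res <- deconvolve_single(y, filter, e, prev_e, next_e, seg, j, weights)
      left_time[j + 1L] <- res$tau
      value_votes[[j]] <- c(value_votes[[j]], res$c_left)
      value_votes[[j + 1L]] <- c(value_votes[[j + 1L]], res$c_right)
      deconvolved[j + 1L] <- TRUE
    } else if (length(members) == 2L) {
      j <- members[1L]
      e1 <- ev[j]; e2 <- ev[j + 1L]
      prev_e <- if (j > 1L) ev[j - 1L] else 0L
      next_e <- if (j + 1L < K) ev[j + 2L] else n
      res <- deconvolve_pair(y, filter, e1, e2, prev_e, next_e, seg, j, weights)
      left_time[j + 1L] <- res$tau1
      left_time[j + 2L] <- res$tau2
      value_votes[[j]] <- c(value_votes[[j]], res$c_left)
      value_votes[[j + 1L]] <- res$c_mid   # the peak level is owned by this fit
      value_votes[[j + 2L]] <- c(value_votes[[j + 2L]], res$c_right)
      deconvolved[c(j + 1L, j + 2L)] <- TRUE
    } else {
      # interior segments of the cluster cannot be deconvolved
      no_deco <- c(no_deco, members[-1L]) # segments strictly inside the cluster
    }
  }
  if (length(no_deco) > 0L) {
    warn("at least one segment could not be deconvolved since two or more successive short segments occurred")
  }
  for (j in seq_along(value_votes)) {
    if (length(value_votes[[j]]) > 0L) values[j] <- mean(value_votes[[j]])
  }
  seg$value <- values
  seg$left_end <- left_time
  seg$right_end <- c(left_time[-1L], seg$right_end[nrow(seg)])
  seg$deconvolved <- deconvolved
  fit$segments <- seg
  fit$no_deconvolution <- sort(unique(no_deco))
  fit
}

#' Segments flagged as not deconvolvable
#'
#' Returns the indices of segments that lie inside clusters of three or more
#' close changes, which the local deconvolution leaves at grid resolution.
#' Downstream export can blank these values (see [write_idealization()]).
#'
#' @param fit An `ms_fit` object.
#' @return Integer vector of segment indices (possibly empty).
#' @export
mark_no_deconvolution <- function(fit) {
  stopifnot(inherits(fit, "ms_fit"))
  fit$no_deconvolution
}

## window for a local fit around boundary indices [e_lo, e_hi]: reaches to the
## neighbouring events, with a buffer of m samples past the previous
## transition
deco_window <- function(e_lo, e_hi, prev_e, next_e, n, m) {
  wl <- max(1L, prev_e + m + 1L)
  wr <- min(n, next_e)
  wl:wr
}

weights_at <- function(seg, weights, idx, fs) {
  if (is.null(weights)) return(rep(1, length(idx)))
  s <- step_signal_value_at(seg, idx / fs, "noise_level")
  1 / pmax(s, 1e-12)^2
}

# least squares for a single change: linear in (c_left, c_right) given tau
deconvolve_single <- function(y, filter, e, prev_e, next_e, seg, j, weights) {
  fs <- filter$sample_rate
  idx <- deco_window(e, e, prev_e, next_e, length(y), filter$m)
  tt <- idx / fs
  w <- weights_at(seg, weights, idx, fs)
  yy <- y[idx]
  fit_at <- function(tau) {
    S <- filter$step_response(tt - tau)
    X <- cbind(1 - S, S)
    xtx <- crossprod(X * w, X)
    beta <- tryCatch(solve(xtx, crossprod(X * w, yy)), error = function(e) NULL)
    if (is.null(beta)) return(list(rss = Inf))
    r <- yy - X %*% beta
    list(rss = sum(w * r^2), c_left = beta[1L], c_right = beta[2L])
  }
  tau <- refine_tau(function(tau) fit_at(tau)$rss, centre = e / fs, fs = fs)
  res <- fit_at(tau)
  list(tau = tau, c_left = res$c_left, c_right = res$c_right, rss = res$rss)
}

# joint least squares for an isolated peak (two changes)
deconvolve_pair <- function(y, filter, e1, e2, prev_e, next_e, seg, j, weights) {
  fs <- filter$sample_rate
  idx <- deco_window(e1, e2, prev_e, next_e, length(y), filter$m)
  tt <- idx / fs
  w <- weights_at(seg, weights, idx, fs)
  yy <- y[idx]
  fit_at <- function(tau1, tau2) {
    if (tau2 <= tau1 + 1e-9 / fs) return(list(rss = Inf))
    S1 <- filter$step_response(tt - tau1)
    S2 <- filter$step_response(tt - tau2)
    X <- cbind(1 - S1, S1 - S2, S2)
    xtx <- crossprod(X * w, X)
    beta <- tryCatch(solve(xtx, crossprod(X * w, yy)), error = function(e) NULL)
    if (is.null(beta)) return(list(rss = Inf))
    r <- yy - X %*% beta
    list(rss = sum(w * r^2), c_left = beta[1L], c_mid = beta[2L], c_right = beta[3L])
  }
  best <- refine_tau2(function(t1, t2) fit_at(t1, t2)$rss,
                      centre1 = e1 / fs, centre2 = e2 / fs, fs = fs)
  res <- fit_at(best[1L], best[2L])
  list(tau1 = best[1L], tau2 = best[2L],
       c_left = res$c_left, c_mid = res$c_mid, c_right = res$c_right, rss = res$rss)
}

# nested grid search, three levels, final resolution 1/(100 fs)
refine_tau <- function(obj, centre, fs) {
  step <- 1 / (4 * fs)
  g <- seq(centre - 2 / fs, centre + 2 / fs, by = step)
  vals <- vapply(g, obj, numeric(1))
  best <- g[which.min(vals)]
  for (lev in 2:3) {
    new_step <- step / 5
    g <- seq(best - step, best + step, by = new_step)
    vals <- vapply(g, obj, numeric(1))
    best <- g[which.min(vals)]
    step <- new_step
  }
  best
}

refine_tau2 <- function(obj, centre1, centre2, fs) {
  step <- 1 / (4 * fs)
  g1 <- seq(centre1 - 2 / fs, centre1 + 2 / fs, by = step)
  g2 <- seq(centre2 - 2 / fs, centre2 + 2 / fs, by = step)
  best <- c(centre1, centre2)
  for (lev in 1:3) {
    if (lev > 1L) {
      new_step <- step / 5
      g1 <- seq(best[1L] - step, best[1L] + step, by = new_step)
      g2 <- seq(best[2L] - step, best[2L] + step, by = new_step)
      step <- new_step
    }
    vals <- outer(g1, g2, Vectorize(function(a, b) obj(a, b)))
    ij <- arrayInd(which.min(vals), dim(vals))
    best <- c(g1[ij[1L]], g2[ij[2L]])
  }
  best
}
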