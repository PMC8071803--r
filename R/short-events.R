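# Detection of events at and below the filter length: JULES (all scales +
# incremental-step postfilter) and HILDE (JSMURF stage + local tests).

#' All-scale multiscale idealization with incremental-step postfilter (JULES)
#'
#' Applies the multiscale criterion to all dyadic scales down to single
#' samples (no transition samples are dropped; standardization uses the full
#' noise autocorrelation) and then removes the staircase artifact of filtered
#' jumps: any maximal run of two or more consecutive changes that is monotone
#' in level and whose intermediate segments are each shorter than the filter
#' length is collapsed to a single change at the start of the run. Homogeneous
#' noise only; the family-wise error of false detections is approximately
#' `config$alpha`.
#'
#' @inheritParams jsmurf
#' @return An `ms_fit` object.
#' @export
jules <- function(trace, filter, config = method_config("jules"),
                  store = critval_store(), critval = NULL, messages = 0L) {
  if (config$noise != "homogeneous") {
    abort("`jules` assumes homogeneous noise; use `hilde` for heterogeneous noise")
  }
  y <- trace_values(trace)
  m <- filter$m
  if (length(y) <= 2L * (m + 1L)) {
    abort(sprintf("trace too short: need more than 2(m + 1) = %d samples", 2L * (m + 1L)))
  }
  cfg <- config
  cfg$method <- "jules"
  q <- critval %||% get_critval(cfg, length(y), filter, store, messages)$critval
  parts <- ms_fit_segments(y, filter, "jules", "homogeneous", q)
  parts <- postfilter_increments(parts, m)
  new_ms_fit(parts, filter, "jules", "homogeneous", config$alpha, q, length(y))
}

# collapse monotone staircases whose intermediate segments are shorter than
# the filter length; iterated to a fixed point (the operation is idempotent).
# Monotone is taken up to a 2% tolerance of the run's net change, which covers
# the small overshoot of the Bessel step response (about 0.8% for 4 poles)
# that would otherwise leave a spurious settling step behind.
postfilter_increments <- function(parts, m, tol = 0.02) {
  repeat {
    K <- length(parts$starts) - 1L
    if (K < 2L) return(parts)
    delta <- diff(parts$value)
    seg_len <- parts$ends - parts$starts + 1L
    collapsed <- FALSE
    j <- 1L
    while (j <= K - 1L) {
      # grow a run of changes with short intermediate segments that is
      # monotone up to counter-movements below tol * |net change|
      jj <- j
      while (jj + 1L <= K && seg_len[jj + 1L] < m) {
        net <- parts$value[jj + 2L] - parts$value[j]
        run <- delta[j:(jj + 1L)]
        counter <- run[sign(run) != sign(net)]
        if (net == 0 || (length(counter) > 0L && any(abs(counter) > tol * abs(net)))) break
        jj <- jj + 1L
      }
      if (jj > j) {
        keep <- setdiff(seq_along(parts$starts), (j + 1L):jj)
        value <- parts$value[keep]
        starts <- parts$starts[keep]
        ends <- parts$ends[keep]
        # left segment of the run keeps its end; the right side absorbs the
        # intermediate segments
        starts[j + 1L] <- parts$ends[j] + 1L
        parts$starts <- starts
        parts$ends <- ends
        parts$value <- value
        parts$noise_level <- parts$noise_level[keep]
        parts$noise_inherited <- parts$noise_inherited[keep]
        collapsed <- TRUE
        break
      }
      j <- j + 1L
    }
    if (!collapsed) return(parts)
  }
}

#' Idealization with local short-event tests (HILDE)
#'
#' Three-stage idealization designed for events at and below the filter
#' length: (1) a large-scale multiscale fit ([jsmurf()]) at error level
#' `alpha1`; (2) inside each fitted segment, windows of each length
#' `l` in `config$scales` (default `1:l_max`, `l_max` defaulting to the filter
#' truncation length `m`) are tested against the segment level, standardized
#' by the noise level and the correlation-aware variance; per-scale critical
#' values are Monte-Carlo calibrated at the equal `alpha2 / #scales` split.
#' Significant windows become peak candidates (two changes) whose level is
#' corrected by the kernel attenuation factor for a peak of that length.
#' Overlapping detections at one scale are merged; across scales the smallest
#' significant scale wins. Overall family-wise error is approximately
#' `alpha1 + alpha2`. Supports homogeneous and heterogeneous noise.
#'
#' @inheritParams jsmurf
#' @param critval Optional list with elements `stage1` and `local` as returned
#'   by [get_critval()], bypassing calibration.
#' @return An `ms_fit` object.
#' @export
hilde <- function(trace, filter, config = method_config("hilde"),
                  store = critval_store(), critval = NULL, messages = 0L) {
  y <- trace_values(trace)
  m <- filter$m
  n <- length(y)
  sc <- resolve_scales(config, filter)
  scales <- sc$scales
  cv <- critval %||% get_critval(config, n, filter, store, messages)
  stage1_cfg <- config
  stage1_cfg$method <- "jsmurf"
  stage1 <- jsmurf(y, filter, stage1_cfg, store, critval = cv$stage1)
  if (length(scales) == 0L) {
    stage1$method <- "hilde"
    stage1$alpha <- config$alpha
    return(stage1)
  }
  crit_local <- cv$local
  templates <- lapply(scales, peak_template, filter = filter)

  seg <- stage1$segments
  skipped <- FALSE
  out_starts <- integer(0); out_ends <- integer(0); out_value <- numeric(0)
  out_nl <- numeric(0)
  for (j in seq_len(nrow(seg))) {
    a <- seg$left_index[j]; b <- seg$right_index[j]; c0 <- seg$value[j]
    sig <- if (config$noise == "heterogeneous") seg$noise_level[j] else stage1$sigma
    a_eff <- if (a > 1L) a + m else a
    if (a == 1L) a_eff <- a + 1L  # a peak flank needs at least one sample
    cands <- list()
    for (s in seq_along(scales)) {
      l <- scales[s]
      tpl <- templates[[s]]
      sc <- local_scan(y, tpl, c0, sig, from = a_eff, to = b)
      if (is.null(sc)) { skipped <- TRUE; next }
      stat <- abs(sc$stat)
      hit <- which(stat > crit_local[s])
      if (length(hit) == 0L) next
      # merge overlapping significant windows at this scale: group starts
      # closer than the window length, keep the strongest of each group
      grp <- cumsum(c(1L, diff(hit) > tpl$w))
      for (g in unique(grp)) {
        ih <- hit[grp == g]
        best <- ih[which.max(stat[ih])]
        w1 <- sc$start[best]
        # the window covers the causal response of a peak starting at the
        # window's first sample; the underlying peak occupies its first l
        # samples. The matched-filter score divided by amp_scale estimates
        # the (attenuation-corrected) peak amplitude.
        cands[[length(cands) + 1L]] <- list(
          scale = l, start = w1, end = min(w1 + l - 1L, b), stat = stat[best],
          value = c0 + sc$stat[best] * sig / tpl$amp_scale
        )
      }
    }
    accepted <- list()
    if (length(cands) > 0L) {
      ord <- order(vapply(cands, `[[`, numeric(1), "scale"),
                   -vapply(cands, `[[`, numeric(1), "stat"))
      for (k in ord) {
        ck <- cands[[k]]
        overlaps <- any(vapply(accepted, function(ac) {
          ck$start <= ac$end && ck$end >= ac$start
        }, logical(1)))
        if (!overlaps) accepted[[length(accepted) + 1L]] <- ck
      }
      accepted <- accepted[order(vapply(accepted, `[[`, numeric(1), "start"))]
    }
    pos <- a
    for (ac in accepted) {
      if (ac$start > pos) {
        out_starts <- c(out_starts, pos); out_ends <- c(out_ends, ac$start - 1L)
        out_value <- c(out_value, c0); out_nl <- c(out_nl, sig)
      }
      out_starts <- c(out_starts, ac$start); out_ends <- c(out_ends, min(ac$end, b))
      out_value <- c(out_value, ac$value); out_nl <- c(out_nl, sig)
      pos <- min(ac$end, b) + 1L
    }
    if (pos <= b) {
      out_starts <- c(out_starts, pos); out_ends <- c(out_ends, b)
      out_value <- c(out_value, c0); out_nl <- c(out_nl, sig)
    }
  }
  if (skipped) {
    warn("some local-test scales exceed a fitted segment length; those windows were skipped")
  }
  parts <- list(
    starts = out_starts, ends = out_ends, value = out_value,
    noise_level = if (config$noise == "heterogeneous") out_nl else
      rep(NA_real_, length(out_starts)),
    noise_inherited = rep(FALSE, length(out_starts)),
    sigma = stage1$sigma
  )
  fit <- new_ms_fit(parts, filter, "hilde", config$noise, config$alpha,
                    list(stage1 = cv$stage1, local = cv$local), length(y),
                    extra = list(stage1_changes = seg$right_index[-nrow(seg)]))
  fit
}
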