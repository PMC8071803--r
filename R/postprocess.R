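# Downstream analysis of an idealization: histograms, half-sample-mode level
# estimation, level assignment/merging and dwell-time extraction.

#' Point-amplitude, event and amplitude histogram data
#'
#' Collects the three standard conductance histograms: the raw data values
#' (point-amplitude), one entry per fitted segment level (event), and the
#' differences between consecutive levels (amplitude). Event-histogram peaks
#' are typically much narrower than point-amplitude peaks, which is what makes
#' conductance levels identifiable from an idealization.
#'
#' @param trace Trace tibble or numeric vector.
#' @param fit An `ms_fit` object (or a step-signal tibble with a `value`
#'   column).
#' @return An object of class `idealization_histograms`: a list of numeric
#'   vectors `point_amplitude`, `event`, `amplitude`, also available stacked
#'   via [tidy()]. Plot with [autoplot()].
#' @export
idealization_histograms <- function(trace, fit) {
  values <- if (inherits(fit, "ms_fit")) fit$segments$value else fit$value
  if (length(values) == 0L) abort("the idealization has no segments")
  structure(
    list(
      point_amplitude = trace_values(trace),
      event = values,
      amplitude = diff(values)
    ),
    class = "idealization_histograms"
  )
}

#' @method tidy idealization_histograms
#' @export
tidy.idealization_histograms <- function(x, ...) {
  bind_rows(
    tibble(histogram = "point_amplitude", value = x$point_amplitude),
    tibble(histogram = "event", value = x$event),
    tibble(histogram = "amplitude", value = x$amplitude)
  )
}

#' @method autoplot idealization_histograms
#' @export
autoplot.idealization_histograms <- function(object, bins = 50, ...) {
  df <- tidy.idealization_histograms(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::facet_wrap(~histogram, scales = "free") +
    ggplot2::labs(x = "conductance [nS]", y = "count")
}

#' Half-sample mode
#'
#' Robust mode estimator: repeatedly keep the half of the sorted sample
#' (`ceiling(k / 2)` contiguous points) with the smallest range until at most
#' three points remain. With three points the mean of the closer pair is
#' returned (the midpoint on a tie); with one or two, their mean. Used to read
#' conductance levels off event and point-amplitude histograms, because it is
#' insensitive to the skewed tails that filtered gating events produce.
#'
#' @param values Numeric vector with at least one finite value.
#' @return The mode estimate (scalar).
#' @export
half_sample_mode <- function(values) {
  x <- sort(values[is.finite(values)])
  if (length(x) == 0L) abort("`values` must contain at least one finite value")
  while (length(x) > 3L) {
    k <- length(x)
    h <- ceiling(k / 2)
    ranges <- x[h:k] - x[seq_len(k - h + 1L)]
    i <- which.min(ranges)
    x <- x[i:(i + h - 1L)]
  }
  if (length(x) <= 2L) return(mean(x))
  d1 <- x[2L] - x[1L]
  d2 <- x[3L] - x[2L]
  if (abs(d1 - d2) < .Machine$double.eps * max(1, abs(x[3L] - x[1L]))) {
    (x[1L] + x[3L]) / 2
  } else if (d1 < d2) {
    (x[1L] + x[2L]) / 2
  } else {
    (x[2L] + x[3L]) / 2
  }
}

#' Assign idealized levels to conductance states and merge
#'
#' Maps each fitted segment to the target conductance of the interval its
#' level falls in; segments outside every interval are marked unassigned (they
#' typically stem from artifacts). Consecutive segments assigned to the same
#' target are merged, which removes spurious events such as baseline
#' fluctuations detected as changes.
#'
#' @param fit An `ms_fit` or a step-signal tibble.
#' @param level_intervals Tibble/data frame with columns `lower`, `upper`,
#'   `level`: disjoint intervals around each conductance state and the state's
#'   conductance.
#' @return A tibble of assigned segments: `left_end`, `right_end`, `level`
#'   (NA when unassigned), `unassigned`.
#' @export
assign_levels <- function(fit, level_intervals) {
  seg <- if (inherits(fit, "ms_fit")) fit$segments else as_tibble(fit)
  li <- as_tibble(level_intervals)
  if (!all(c("lower", "upper", "level") %in% names(li))) {
    abort("`level_intervals` needs columns `lower`, `upper`, `level`")
  }
  li <- arrange(li, .data$lower)
  if (nrow(li) > 1L && any(li$lower[-1L] < li$upper[-nrow(li)])) {
    abort("`level_intervals` must be disjoint")
  }
  target <- vapply(seg$value, function(v) {
    hit <- which(v >= li$lower & v <= li$upper)
    if (length(hit) == 0L) NA_real_ else li$level[hit[1L]]
  }, numeric(1))
  out <- tibble(left_end = seg$left_end, right_end = seg$right_end,
                level = target, unassigned = is.na(target))
  ## merge consecutive segments with the same assigned level
  if (nrow(out) > 1L) {
    same <- !out$unassigned[-1L] & !out$unassigned[-nrow(out)] &
      out$level[-1L] == out$level[-nrow(out)]
    grp <- cumsum(c(1L, !same))
    out <- out |>
      mutate(grp = grp) |>
      group_by(.data$grp) |>
      summarise(left_end = min(.data$left_end), right_end = max(.data$right_end),
                level = .data$level[1L], unassigned = .data$unassigned[1L],
                .groups = "drop") |>
      select(-"grp") # nolint
    out <- out[, c("left_end", "right_end", "level", "unassigned")]
  }
  out
}

#' Dwell-time extraction and exponential rate fits
#'
#' Computes per-level dwell-time lists from an assigned idealization, fits a
#' left-truncated exponential to each level's dwell times (a crude guard
#' against missed short events: dwell times below `resolution_limit` are
#' discarded and the maximum-likelihood rate of the truncated exponential,
#' `1 / (mean(d) - t0)`, is reported), and the Pearson correlation of
#' consecutive dwell times, a quick check of the Markov assumption that dwell
#' times are independent and exponential.
#'
#' @param assigned Output of [assign_levels()] (or any tibble with `left_end`,
#'   `right_end`, `level`); unassigned segments are dropped.
#' @param resolution_limit Left-truncation point `t0` in seconds (default 0).
#' @return An object of class `dwell_analysis`: list with `dwells` (tibble
#'   `level`, `duration`), `rates` (tibble `level`, `n`, `rate` per second),
#'   and `lag1_correlation`.
#' @export
dwell_times <- function(assigned, resolution_limit = 0) {
  df <- as_tibble(assigned)
  if ("unassigned" %in% names(df)) df <- df[!df$unassigned, ]
  if (nrow(df) < 2L) abort("need at least two assigned segments")
  dwells <- tibble(level = df$level, duration = df$right_end - df$left_end)
  rates <- dwells |>
    filter(.data$duration >= resolution_limit) |>
    group_by(.data$level) |>
    summarise(n = dplyr::n(),
              rate = 1 / (mean(.data$duration) - resolution_limit),
              .groups = "drop")
  d <- dwells$duration
  lag1 <- if (length(d) >= 3L && sd(d[-length(d)]) > 0 && sd(d[-1L]) > 0) {
    stats::cor(d[-length(d)], d[-1L])
  } else {
    NA_real_
  }
  structure(list(dwells = dwells, rates = rates, lag1_correlation = lag1),
            class = "dwell_analysis")
}

#' @method tidy dwell_analysis
#' @export
tidy.dwell_analysis <- function(x, ...) x$rates

#' @method glance dwell_analysis
#' @export
glance.dwell_analysis <- function(x, ...) {
  tibble(n_dwells = nrow(x$dwells), n_levels = nrow(x$rates),
         lag1_correlation = x$lag1_correlation)
}

#' @export
print.dwell_analysis <- function(x, ...) {
  cat(sprintf("<dwell_analysis> %d dwell(s), %d level(s), lag-1 correlation %.3f\n",
              nrow(x$dwells), nrow(x$rates), x$lag1_correlation))
  print(x$rates, ...)
  invisible(x)
}
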