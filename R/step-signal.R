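# Piecewise-constant conductance signals as tidy segment tables.

#' Create a piecewise-constant conductance signal
#'
#' A step signal is the ground truth of the observation model: a
#' piecewise-constant conductance over contiguous half-open segments
#' `[left_end, right_end)`, optionally with a segment-wise noise level for the
#' heterogeneous (open-channel) noise model. Noise levels may only change
#' where the conductance changes, which this representation enforces by
#' construction.
#'
#' @param value Conductance level per segment (nS).
#' @param left_end,right_end Segment boundaries in seconds; segments must be
#'   contiguous (`right_end[i] == left_end[i + 1]`) and strictly increasing.
#' @param noise_level Optional positive noise level per segment (nS).
#' @return A tibble of class `step_signal` with one row per segment.
#' @examples
#' step_signal(value = c(0, 1, 0), left_end = c(0, 0.1, 0.12), right_end = c(0.1, 0.12, 0.5))
#' @export
step_signal <- function(value, left_end, right_end, noise_level = NULL) {
  df <- tibble(left_end = as.numeric(left_end),
               right_end = as.numeric(right_end),
               value = as.numeric(value))
  if (!is.null(noise_level)) df$noise_level <- as.numeric(noise_level)
  validate_step_signal(df)
}

validate_step_signal <- function(df) {
  df <- as_tibble(df)
  need <- c("left_end", "right_end", "value")
  if (!all(need %in% names(df))) {
    abort("a step signal needs columns `left_end`, `right_end`, `value`")
  }
  if (nrow(df) == 0L) abort("a step signal needs at least one segment")
  if (any(!is.finite(df$value)) || any(!is.finite(df$left_end)) || any(!is.finite(df$right_end))) {
    abort("step signal fields must be finite")
  }
  if (any(df$right_end <= df$left_end)) {
    abort("each segment must satisfy `left_end < right_end`")
  }
  if (nrow(df) > 1L && any(abs(df$left_end[-1] - df$right_end[-nrow(df)]) > 1e-12)) {
    abort("segments must be contiguous: `right_end[i]` must equal `left_end[i + 1]`")
  }
  if (!is.null(df[["noise_level"]]) && any(!is.na(df[["noise_level"]]) & df[["noise_level"]] <= 0)) {
    abort("`noise_level` must be positive")
  }
  class(df) <- unique(c("step_signal", class(df)))
  df
}

# level of the segment containing each time t under the [left, right) convention
step_signal_value_at <- function(signal, t, column = "value") {
  idx <- findInterval(t, signal$left_end, left.open = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(signal)] <- nrow(signal)
  signal[[column]][idx]
}
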