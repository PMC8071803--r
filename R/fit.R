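# The idealization object returned by the detection methods.

new_ms_fit <- function(parts, filter, method, noise, alpha, q, n,
                       extra = list()) {
  fs <- filter$sample_rate
  segments <- tibble(
    left_index = parts$starts,
    right_index = parts$ends,
    left_end = (parts$starts - 1L) / fs,
    right_end = parts$ends / fs,
    value = parts$value
  )
  if (noise == "heterogeneous") {
    segments$noise_level <- parts$noise_level
    segments$noise_inherited <- parts$noise_inherited
  }
  segments$deconvolved <- FALSE
  structure(
    c(list(
      segments = segments,
      method = method,
      noise = noise,
      alpha = alpha,
      critval = q,
      sigma = parts$sigma,
      n = n,
      sample_rate = fs,
      filter_fingerprint = filter$fingerprint,
      no_deconvolution = integer(0)
    ), extra),
    class = "ms_fit"
  )
}

#' @export
print.ms_fit <- function(x, ...) {
  cat(sprintf("<ms_fit> %s idealization (%s noise): %d segment(s), %d change(s)\n",
              x$method, x$noise, nrow(x$segments), nrow(x$segments) - 1L))
  cat(sprintf("  n = %d samples at %.6g Hz, alpha = %g, sigma = %.4g\n",
              x$n, x$sample_rate, x$alpha, x$sigma))
  if (length(x$no_deconvolution) > 0L) {
    cat(sprintf("  %d segment(s) could not be deconvolved\n", length(x$no_deconvolution)))
  }
  print(x$segments, ...)
  invisible(x)
}

#' Tidy an idealization into its segment table
#'
#' @param x An `ms_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per fitted segment: `left_end`, `right_end`
#'   (seconds, half-open segments), `value` (nS), sample index range, the
#'   heterogeneous noise level where applicable, and flags `deconvolved` and
#'   `no_deconvolution`.
#' @method tidy ms_fit
#' @export
tidy.ms_fit <- function(x, ...) {
  out <- x$segments
  out$no_deconvolution <- seq_len(nrow(out)) %in% x$no_deconvolution
  out
}

#' One-row summary of an idealization
#'
#' @param x An `ms_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: method, noise regime, number of samples and of
#'   changes, error level, critical value and the global noise estimate.
#' @method glance ms_fit
#' @export
glance.ms_fit <- function(x, ...) {
  tibble(
    method = x$method, noise = x$noise, n = x$n,
    n_segments = nrow(x$segments), n_changes = nrow(x$segments) - 1L,
    alpha = x$alpha, critval = x$critval[[1]], sigma = x$sigma,
    n_no_deconvolution = length(x$no_deconvolution)
  )
}

#' Step-function values of an idealization at given times
#'
#' @param fit An `ms_fit` object.
#' @param times Numeric vector of times in seconds.
#' @return Numeric vector of idealized conductances.
#' @export
fit_values_at <- function(fit, times) {
  step_signal_value_at(fit$segments, times)
}

#' Plot an idealization over the data
#'
#' Draws the recorded conductance (points), the idealized step function (red)
#' and, when a filter is supplied, the convolution of the idealization with
#' the low-pass kernel (blue) -- the standard visual check that the fit and
#' the specified filter describe the recording well.
#'
#' @param object An `ms_fit` object.
#' @param trace Optional trace tibble (`time`, `conductance`).
#' @param filter Optional [lowpass_filter()] used for the convolution overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ms_fit
#' @export
autoplot.ms_fit <- function(object, trace = NULL, filter = NULL, ...) {
  seg <- object$segments
  p <- ggplot2::ggplot()
  if (!is.null(trace)) {
    p <- p + ggplot2::geom_point(
      data = trace, ggplot2::aes(x = .data$time, y = .data$conductance),
      colour = "grey60", size = 0.4
    )
  }
  p <- p + ggplot2::geom_segment(
    data = seg,
    ggplot2::aes(x = .data$left_end, xend = .data$right_end,
                 y = .data$value, yend = .data$value),
    colour = "red", linewidth = 0.8
  )
  if (!is.null(filter) && !is.null(trace)) {
    conv <- tibble(
      time = trace$time,
      conductance = convolve_step_signal(
        seg[, c("left_end", "right_end", "value")], filter,
        pmax(trace$time, seg$left_end[1])
      )
    )
    p <- p + ggplot2::geom_line(
      data = conv, ggplot2::aes(x = .data$time, y = .data$conductance),
      colour = "blue"
    )
  }
  p + ggplot2::labs(x = "time [s]", y = "conductance [nS]")
}

#' @importFrom rlang .data
NULL
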