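# Top-level pipeline: detection followed by local deconvolution.

#' Idealize a patchclamp trace
#'
#' One-call pipeline: runs the configured detection method ([jsmurf()],
#' [jules()] or [hilde()]) and refines the result by filter-aware local
#' deconvolution ([deconvolve_locally()]). Monte-Carlo critical values are
#' cached in `store`, so repeated calls with the same trace length, filter and
#' `r` are fast.
#'
#' @param trace Trace tibble (`time`, `conductance`) or numeric vector.
#' @param filter A [lowpass_filter()] describing the hardware filter.
#' @param config A [method_config()] selecting method, noise regime and error
#'   levels.
#' @param store A [critval_store()].
#' @param deconvolve Refine change times and levels by local deconvolution
#'   (default `TRUE`).
#' @param messages Progress-message interval for Monte-Carlo simulations.
#' @return An `ms_fit`; see [tidy.ms_fit()] and [autoplot.ms_fit()].
#' @examples
#' \donttest{
#' fil <- lowpass_filter(4, 0.1, 1e4)
#' truth <- step_signal(c(0, 1, 0), c(0, 0.04, 0.06), c(0.04, 0.06, 0.11))
#' tr <- simulate_trace(truth, fil, n = 1000, sigma = 0.2, seed = 7)
#' cfg <- method_config("jsmurf", r = 200, seed = 1)
#' fit <- idealize(tr, fil, cfg)
#' tidy(fit)
#' }
#' @export
idealize <- function(trace, filter, config = method_config("jsmurf"),
                     store = critval_store(), deconvolve = TRUE, messages = 0L) {
  fit <- switch(config$method,
    jsmurf = jsmurf(trace, filter, config, store, messages = messages),
    jules = jules(trace, filter, config, store, messages = messages),
    hilde = hilde(trace, filter, config, store, messages = messages)
  )
  if (deconvolve) fit <- deconvolve_locally(fit, trace, filter)
  fit
}
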