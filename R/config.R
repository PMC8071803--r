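# Method configuration: error levels, Monte-Carlo repetitions, scales, seed.

#' Configure an idealization method
#'
#' Bundles the tuning parameters of the multiscale idealization methods. The
#' error level `alpha` bounds (approximately) the probability of detecting one
#' or more false-positive conductance changes on model-conform data. For
#' `hilde` the budget is split as `alpha = alpha1 + alpha2` between the
#' large-scale multiscale criterion (`alpha1`) and the local short-event tests
#' (`alpha2`); the defaults 0.01/0.04 put most weight on short events.
#'
#' @param method One of `"jsmurf"`, `"jules"`, `"hilde"`.
#' @param noise `"homogeneous"` or `"heterogeneous"`. `jules` supports only
#'   homogeneous noise.
#' @param alpha Overall error level in (0, 1); default 0.05. For `hilde` it is
#'   derived as `alpha1 + alpha2` and must equal their sum if given.
#' @param alpha1,alpha2 `hilde` split of the error level; defaults 0.01 and 0.04.
#' @param r Monte-Carlo repetitions for critical values; defaults to 10000 for
#'   `jsmurf`/`jules` and 1000 for `hilde`. At least 100.
#' @param l_max Largest scale (in samples) of the `hilde` local tests; `NULL`
#'   (default) resolves to the filter truncation length `m` at call time.
#' @param scales Subset of `1:l_max` at which local tests are performed;
#'   `NULL` means all of `1:l_max`.
#' @param seed Master integer seed from which all Monte-Carlo streams derive.
#' @return A `method_config` object.
#' @export
method_config <- function(method = c("jsmurf", "jules", "hilde"),
                          noise = c("homogeneous", "heterogeneous"),
                          alpha = NULL, alpha1 = 0.01, alpha2 = 0.04,
                          r = NULL, l_max = NULL, scales = NULL, seed = 1L) {
  method <- match.arg(method)
  noise <- match.arg(noise)
  if (method == "jules" && noise == "heterogeneous") {
    abort("`jules` assumes homogeneous noise; use `hilde` for heterogeneous noise")
  }
  if (method == "hilde") {
    check_prob(alpha1, "alpha1")
    check_prob(alpha2, "alpha2")
    if (is.null(alpha)) {
      alpha <- alpha1 + alpha2
    } else if (abs(alpha - (alpha1 + alpha2)) > 1e-12) {
      abort("for `hilde`, `alpha` must equal `alpha1 + alpha2`")
    }
  } else {
    alpha <- alpha %||% 0.05
  }
  check_prob(alpha, "alpha")
  r <- as.integer(r %||% if (method == "hilde") 1000L else 10000L)
  if (r < 100L) abort("`r` must be at least 100 Monte-Carlo repetitions")
  if (!is.null(l_max)) {
    l_max <- as.integer(l_max)
    if (l_max < 1L) abort("`l_max` must be a positive integer")
  }
  if (!is.null(scales)) {
    scales <- sort(unique(as.integer(scales)))
    if (length(scales) > 0L && (is.null(l_max) || any(scales < 1L | scales > l_max))) {
      if (is.null(l_max)) l_max <- max(scales)
      if (any(scales < 1L | scales > l_max)) abort("`scales` must lie in 1..l_max")
    }
  }
  structure(
    list(method = method, noise = noise, alpha = alpha,
         alpha1 = alpha1, alpha2 = alpha2, r = r,
         l_max = l_max, scales = scales, seed = as.integer(seed)),
    class = "method_config"
  )
}

#' @export
print.method_config <- function(x, ...) {
  cat(sprintf("<method_config> %s (%s noise), alpha = %g", x$method, x$noise, x$alpha))
  if (x$method == "hilde") {
    cat(sprintf(" (alpha1 = %g, alpha2 = %g, l_max = %s)", x$alpha1, x$alpha2,
                if (is.null(x$l_max)) "filter length" else x$l_max))
  }
  cat(sprintf(", r = %d, seed = %d\n", x$r, x$seed))
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || x <= 0 || x >= 1) {
    abort(sprintf("`%s` must be a probability strictly between 0 and 1", name))
  }
}

# resolve hilde scale set against a filter
resolve_scales <- function(config, filter) {
  l_max <- config$l_max %||% max(filter$m, 1L)
  scales <- config$scales %||% seq_len(l_max)
  list(l_max = l_max, scales = scales)
}

# small deterministic seed stream: derive a sub-seed from a master seed and a label
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147480009
  as.integer((as.numeric(seed) * 48271 + h) %% 2147480009)
}
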