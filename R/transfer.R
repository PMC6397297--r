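#' Piecewise dose-response transfer function
#'
#' Defines how a morphometric parameter responds to probe expression:
#' constant at `baseline` below the lower breakpoint `t1`, log-linear
#' between `t1` and `t2` (linear in log-parameter vs. log-expression,
#' continuous at both breakpoints), and constant at `plateau` above
#' `t2`. This is the three-regime structure — no effect, dose-response,
#' saturation — that the regime-detection stage is designed to recover.
#'
#' @param baseline Parameter value below `t1` (> 0).
#' @param plateau Parameter value above `t2` (> 0). May be smaller than
#'   `baseline` for parameters that decrease with expression.
#' @param t1,t2 Lower and upper breakpoints on the expression axis
#'   (`t1 < t2`, both > 0, same units as expression).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal cell-to-cell scatter applied by [sample_parameter()];
#'   the scatter has geometric mean 1.
#' @return An object of class `transfer_function`.
#' @seealso [sample_parameter()], [population_config()]
#' @examples
#' tf <- transfer_function(100, 1000, t1 = 1e4, t2 = 1e6)
#' sample_parameter(tf, 1e5)   # geometric midpoint -> sqrt(100 * 1000)
#' @export
transfer_function <- function(baseline, plateau, t1, t2, noise_cv = 0) {
  stopifnot(is.numeric(baseline), baseline > 0,
            is.numeric(plateau), plateau > 0,
            is.numeric(t1), is.numeric(t2), t1 > 0, t1 < t2,
            is.numeric(noise_cv), noise_cv >= 0)
  structure(list(baseline = baseline, plateau = plateau,
                 t1 = t1, t2 = t2, noise_cv = noise_cv),
            class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf(
    "transfer_function: %.4g -> %.4g over [%.3g, %.3g], noise_cv = %.3g\n",
    x$baseline, x$plateau, x$t1, x$t2, x$noise_cv))
  invisible(x)
}

# Deterministic piecewise value (vectorised over expression).
tf_eval <- function(tf, expression) {
  stopifnot(inherits(tf, "transfer_function"))
  if (any(expression <= 0)) stop("expression must be positive", call. = FALSE)
  le <- log10(expression)
  l1 <- log10(tf$t1); l2 <- log10(tf$t2)
  frac <- clamp((le - l1) / (l2 - l1), 0, 1)
  10^(log10(tf$baseline) + frac * (log10(tf$plateau) - log10(tf$baseline)))
}

#' Draw a parameter value from a transfer function
#'
#' Evaluates the piecewise transfer function at an expression level and
#' applies multiplicative lognormal scatter with the configured
#' coefficient of variation (geometric mean 1, so the scatter is
#' median-unbiased on the log scale). With `noise_cv = 0` the
#' deterministic piecewise value is returned. Uses the session RNG;
#' seed upstream for reproducibility.
#'
#' @param tf A [transfer_function()].
#' @param expression Positive expression level(s).
#' @return Positive parameter value(s), same length as `expression`.
#' @export
sample_parameter <- function(tf, expression) {
  v <- tf_eval(tf, expression)
  if (tf$noise_cv > 0) {
    sdlog <- sqrt(log(1 + tf$noise_cv^2))
    v <- v * exp(stats::rnorm(length(v), 0, sdlog))
  }
  v
}
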