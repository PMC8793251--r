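# Standard binomial responder analysis: p-hat = x/n with an exact
# Clopper-Pearson interval from beta quantiles.

#' Binomial point estimate of the response rate
#'
#' @param x Responder count.
#' @param n Sample size (>= 1).
#' @return `x / n`.
#' @export
standard_estimate <- function(x, n) {
  if (n < 1) stop("'n' must be >= 1")
  if (x < 0 || x > n) stop("'x' must lie in [0, n]")
  x / n
}

#' Exact Clopper-Pearson confidence interval
#'
#' Computed from beta quantiles: the lower bound is the `alpha/2` quantile of
#' `Beta(x, n - x + 1)` (0 when `x = 0`) and the upper bound the
#' `1 - alpha/2` quantile of `Beta(x + 1, n - x)` (1 when `x = n`). This is
#' equivalent to inverting the binomial tail probabilities.
#'
#' @inheritParams standard_estimate
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' clopper_pearson_ci(17, 30)   # the mCRPC case-study interval
#' @export
clopper_pearson_ci <- function(x, n, level = 0.95) {
  if (n < 1) stop("'n' must be >= 1")
  if (x < 0 || x > n) stop("'x' must lie in [0, n]")
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must be a single number in (0, 1)")
  a <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lower, upper)
}

response_result <- function(method, p_hat, ci, level, n, ...) {
  structure(
    list(method = method, p_hat = p_hat,
         ci_lower = ci[1L], ci_upper = ci[2L],
         ci_width = ci[2L] - ci[1L], level = level, n = n, ...),
    class = "response_result")
}

#' @export
print.response_result <- function(x, ...) {
  cat(sprintf("%s analysis (n = %d): p-hat = %.1f%%, %g%% CI (%.1f, %.1f%%), width %.3f\n",
              x$method, x$n, 100 * x$p_hat, 100 * x$level,
              100 * x$ci_lower, 100 * x$ci_upper, x$ci_width))
  if (!is.null(x$lambda))
    cat(sprintf("  Box-Cox lambda = %.2f on the %s scale\n",
                x$lambda, x$scale_used))
  invisible(x)
}

#' Standard responder analysis of an arm
#'
#' Dichotomises the continuous PSA reductions at the arm's threshold, then
#' estimates the response rate and its exact Clopper-Pearson interval from
#' the binary indicators alone.
#'
#' @param dataset A [psa_dataset()].
#' @param level Confidence level; default 0.95.
#' @return A `response_result` with fields `method = "standard"`, `p_hat`,
#'   `ci_lower`, `ci_upper`, `ci_width`, `level`, `n`, and `x` (responders).
#' @seealso [augmented_analysis()] for the latent-normal alternative.
#' @export
standard_analysis <- function(dataset, level = 0.95) {
  stopifnot(inherits(dataset, "psa_dataset"))
  s <- classify_responders(dataset)
  n <- length(s)
  x <- sum(s)
  response_result("standard", standard_estimate(x, n),
                  clopper_pearson_ci(x, n, level), level, n, x = x)
}
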