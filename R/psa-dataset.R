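#' Per-arm PSA percentage-change dataset
#'
#' Container for one trial arm's continuous PSA change-from-baseline values,
#' stored internally on the *percentage reduction* scale: positive values are
#' declines in PSA (a value of 80 means an 80\% fall from baseline), negative
#' values are increases. A patient is a responder when their reduction strictly
#' exceeds the dichotomisation threshold `d`.
#'
#' Published waterfall plots usually use the opposite sign ("percentage
#' change", negative = decline). The `orientation` argument states which
#' convention the *input* uses; `"change"` values are negated on construction.
#' There is no auto-detection: a silent sign flip is worse than an error.
#'
#' @param values Numeric vector of per-patient PSA changes. All values must be
#'   finite and, once on the reduction scale, at most 100 (PSA cannot fall by
#'   more than 100\%).
#' @param threshold Response threshold `d` in percent reduction (commonly 30
#'   or 50). A patient responds iff reduction `> d` (strict).
#' @param orientation `"reduction"` (positive = decline, the internal
#'   convention) or `"change"` (negative = decline; negated on construction).
#' @param arm_label Character label for the arm.
#' @param n_clipped Number of waterfall bars that were clipped at the plot
#'   ceiling (their true PSA increase exceeds the displayed value).
#' @param clip_point Plot ceiling as a percentage *increase* (e.g. 100 means
#'   bars were truncated at +100\% change), or `NULL` when no bars are clipped.
#'
#' @return An object of class `psa_dataset`: a list with elements `values`
#'   (reduction scale), `threshold`, `arm_label`, `n_clipped`, `clip_point`,
#'   and `orientation_note` (the orientation the source used).
#' @examples
#' arm <- psa_dataset(c(-30, 45, 99), threshold = 50, orientation = "change")
#' arm$values            # 30, -45, -99 on the reduction scale
#' classify_responders(arm)
#' @export
psa_dataset <- function(values, threshold,
                        orientation = c("reduction", "change"),
                        arm_label = "arm", n_clipped = 0L, clip_point = NULL) {
  orientation <- match.arg(orientation)
  values <- as.numeric(values)
  if (length(values) == 0L) stop("'values' must be non-empty")
  if (!all(is.finite(values))) stop("'values' must all be finite")
  if (orientation == "change") values <- -values
  if (any(values > 100)) {
    stop("invalid PSA reduction > 100% at position(s) ",
         paste(which(values > 100), collapse = ", "),
         " (PSA cannot fall by more than 100%); check the 'orientation' flag")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop("'threshold' must be a single finite number")
  n_clipped <- as.integer(n_clipped)
  if (is.na(n_clipped) || n_clipped < 0L) stop("'n_clipped' must be >= 0")
  if (n_clipped > length(values))
    stop("'n_clipped' exceeds the number of values")
  if (!is.null(clip_point)) {
    clip_point <- as.numeric(clip_point)
    if (!is.finite(clip_point)) stop("'clip_point' must be finite")
  }
  structure(
    list(values = values, threshold = threshold,
         arm_label = as.character(arm_label),
         n_clipped = n_clipped, clip_point = clip_point,
         orientation_note = orientation),
    class = "psa_dataset")
}

#' @export
print.psa_dataset <- function(x, ...) {
  cat(sprintf("PSA change dataset '%s': n = %d, threshold d = %g%% reduction\n",
              x$arm_label, length(x$values), x$threshold))
  cat(sprintf("  responders (reduction > d): %d\n",
              sum(classify_responders(x))))
  if (x$n_clipped > 0L)
    cat(sprintf("  clipped bars: %d at +%g%% change\n",
                x$n_clipped, x$clip_point))
  invisible(x)
}

#' Classify patients as responders
#'
#' Applies the strict dichotomisation rule: patient `i` responds iff their
#' percentage reduction `Y_i` strictly exceeds the threshold `d`. A value
#' exactly at the threshold is a non-responder.
#'
#' @param dataset A [psa_dataset()].
#' @return Integer vector of 0/1 responder indicators, one per patient.
#' @examples
#' classify_responders(psa_dataset(c(51, 90, 29), threshold = 30))
#' @export
classify_responders <- function(dataset) {
  stopifnot(inherits(dataset, "psa_dataset"))
  as.integer(dataset$values > dataset$threshold)
}
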