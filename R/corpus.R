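# Batch re-analysis of a corpus of arms, summary statistics across arms,
# the clipped-bar sensitivity analysis, and the waterfall-plot data export.

#' Re-analyse a corpus of arms
#'
#' Runs the standard and augmented analyses plus the efficiency comparison
#' for every arm, and summarises across arms: medians and IQRs (linear
#' interpolation between order statistics, `quantile` type 7) of the width
#' reduction, implied sample-size increase and estimate difference; the
#' Pearson correlation of the two point estimates; and the number of arms
#' with a strictly narrower augmented interval. Arms whose augmented fit
#' fails are reported in an exclusion table, not silently dropped.
#'
#' @param manifest Either a manifest data.frame / path (see
#'   [read_manifest()]) or a list of [psa_dataset()] objects.
#' @param base_dir Directory against which manifest `path` entries are
#'   resolved; defaults to the manifest file's directory when `manifest` is
#'   a path, else `"."`.
#' @param level Confidence level; default 0.95.
#' @param mode Implied-sample-size mode; see [implied_sample_size()].
#' @return Object of class `corpus_summary`: list with `per_arm`
#'   (data.frame, one row per successfully analysed arm),
#'   `median_width_reduction_pct` / `iqr_width_reduction_pct`,
#'   `median_ss_increase_pct` / `iqr_ss_increase_pct`,
#'   `median_estimate_difference_pct` / `iqr_estimate_difference_pct`
#'   (augmented minus standard, percentage points),
#'   `pearson_r_estimates`, `n_arms_narrower`, `n_arms`, and `exclusions`
#'   (data.frame of arm_label + reason).
#' @export
reanalyse_corpus <- function(manifest, base_dir = NULL, level = 0.95,
                             mode = c("continuous", "integer")) {
  mode <- match.arg(mode)
  if (is.character(manifest) && length(manifest) == 1L) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  if (is.data.frame(manifest)) {
    if (is.null(base_dir)) base_dir <- "."
    datasets <- vector("list", nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
      row <- manifest[i, ]
      cp <- if (!is.null(row$clip_point) && !is.na(row$clip_point))
        row$clip_point else NULL
      datasets[[i]] <- tryCatch(
        read_arm_csv(file.path(base_dir, row$path), row$threshold,
                     orientation = row$orientation,
                     arm_label = row$arm_label,
                     n_clipped = row$n_clipped, clip_point = cp),
        error = function(e) e)
    }
  } else if (is.list(manifest) &&
             all(vapply(manifest, inherits, TRUE, "psa_dataset"))) {
    datasets <- manifest
  } else {
    stop("'manifest' must be a manifest path/data.frame or a list of psa_dataset")
  }

  rows <- list()
  excl <- list()
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    label <- if (inherits(ds, "psa_dataset")) ds$arm_label
             else sprintf("arm %d", i)
    res <- tryCatch({
      if (inherits(ds, "error")) stop(conditionMessage(ds))
      st <- standard_analysis(ds, level)
      au <- suppressWarnings(augmented_analysis(ds, level))
      cmp <- compare_analyses(st, au, mode = mode)
      data.frame(
        arm_label = ds$arm_label, n = st$n, threshold = ds$threshold,
        p_standard = st$p_hat, ci_lower_standard = st$ci_lower,
        ci_upper_standard = st$ci_upper, width_standard = st$ci_width,
        p_augmented = au$p_hat, ci_lower_augmented = au$ci_lower,
        ci_upper_augmented = au$ci_upper, width_augmented = au$ci_width,
        lambda = au$lambda,
        width_reduction_pct = cmp$width_reduction_pct,
        n_implied = cmp$n_implied, ss_increase_pct = cmp$ss_increase_pct,
        stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(
        arm_label = label, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  per_arm <- if (length(rows)) do.call(rbind, rows) else
    data.frame(arm_label = character())
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(arm_label = character(), reason = character())
  if (nrow(per_arm) == 0L)
    stop("no arm could be analysed; see exclusions")

  med_iqr <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7,
                         na.rm = TRUE)
    list(median = q[2L], iqr = q[c(1L, 3L)])
  }
  wr <- med_iqr(per_arm$width_reduction_pct)
  ss <- med_iqr(per_arm$ss_increase_pct)
  dd <- med_iqr(100 * (per_arm$p_augmented - per_arm$p_standard))
  structure(
    list(per_arm = per_arm, exclusions = exclusions,
         n_arms = nrow(per_arm),
         median_width_reduction_pct = wr$median,
         iqr_width_reduction_pct = wr$iqr,
         median_ss_increase_pct = ss$median,
         iqr_ss_increase_pct = ss$iqr,
         median_estimate_difference_pct = dd$median,
         iqr_estimate_difference_pct = dd$iqr,
         pearson_r_estimates = if (nrow(per_arm) > 1L &&
                                   stats::sd(per_arm$p_standard) > 0 &&
                                   stats::sd(per_arm$p_augmented) > 0)
           stats::cor(per_arm$p_standard, per_arm$p_augmented) else NA_real_,
         n_arms_narrower = sum(per_arm$width_augmented <
                                 per_arm$width_standard)),
    class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf("Corpus of %d arm(s) (%d excluded)\n",
              x$n_arms, nrow(x$exclusions)))
  cat(sprintf("  median CI width reduction: %.1f%% (IQR [%.1f, %.1f%%])\n",
              x$median_width_reduction_pct, x$iqr_width_reduction_pct[1],
              x$iqr_width_reduction_pct[2]))
  cat(sprintf("  median implied sample-size increase: %.1f%% (IQR [%.1f, %.1f%%])\n",
              x$median_ss_increase_pct, x$iqr_ss_increase_pct[1],
              x$iqr_ss_increase_pct[2]))
  cat(sprintf("  median estimate difference (aug - std): %.1f pts (IQR [%.1f, %.1f])\n",
              x$median_estimate_difference_pct,
              x$iqr_estimate_difference_pct[1],
              x$iqr_estimate_difference_pct[2]))
  cat(sprintf("  Pearson r between estimates: %.2f; narrower augmented CI in %d/%d arms\n",
              x$pearson_r_estimates, x$n_arms_narrower, x$n_arms))
  invisible(x)
}

#' Clipped-bar sensitivity analysis
#'
#' Waterfall plots often truncate large PSA increases at a ceiling, so the
#' recorded value of a clipped bar understates the true increase. This
#' re-imputes the clipped values and reports the range of results across
#' imputations for both analysis methods. Two schemes:
#' * `"at-clip"`: clipped values placed exactly at the ceiling
#'   (deterministic, one replicate) — the displayed-value bound.
#' * `"exponential-excess"`: clipped values placed at the ceiling plus an
#'   exponential excess with mean `mean_excess` (a tail model for how far
#'   beyond the ceiling the truth may lie), repeated `n_replicates` times.
#'
#' @param dataset A [psa_dataset()] with `n_clipped > 0` and a clip point
#'   (or `n_clipped = 0`, in which case the unperturbed analysis is
#'   returned for both schemes).
#' @param scheme Imputation scheme.
#' @param n_replicates Number of imputations for the stochastic scheme
#'   (>= 2 there; ignored for `"at-clip"`).
#' @param mean_excess Mean of the exponential excess, percentage points.
#' @param seed Integer seed for the stochastic scheme.
#' @param level Confidence level.
#' @return List with one element per method (`standard`, `augmented`), each
#'   a data.frame with rows `min` and `max` over replicates of `p_hat`,
#'   `ci_lower`, `ci_upper`; plus `n_replicates` and `scheme`.
#' @export
clipped_bar_sensitivity <- function(dataset,
                                    scheme = c("at-clip", "exponential-excess"),
                                    n_replicates = 1L, mean_excess = 25,
                                    seed = NULL, level = 0.95) {
  stopifnot(inherits(dataset, "psa_dataset"))
  scheme <- match.arg(scheme)
  if (dataset$n_clipped > 0L && is.null(dataset$clip_point))
    stop("dataset has clipped bars but no clip point recorded")
  if (scheme == "exponential-excess" && n_replicates < 2L)
    stop("the stochastic scheme needs n_replicates >= 2")
  if (scheme == "at-clip") n_replicates <- 1L

  # clipped bars are those recorded at the ceiling (reduction = -clip_point)
  idx <- integer(0)
  if (dataset$n_clipped > 0L) {
    at_ceiling <- which(dataset$values == -dataset$clip_point)
    if (length(at_ceiling) < dataset$n_clipped)
      stop("fewer values at the clip point than n_clipped claims")
    idx <- at_ceiling[seq_len(dataset$n_clipped)]
  }

  analyse_once <- function(values) {
    ds <- dataset
    ds$values <- values
    st <- standard_analysis(ds, level)
    au <- suppressWarnings(augmented_analysis(ds, level))
    c(p_standard = st$p_hat, lo_standard = st$ci_lower,
      hi_standard = st$ci_upper,
      p_augmented = au$p_hat, lo_augmented = au$ci_lower,
      hi_augmented = au$ci_upper)
  }

  reps <- with_seed(seed, {
    out <- matrix(NA_real_, n_replicates, 6L)
    for (r in seq_len(n_replicates)) {
      v <- dataset$values
      if (length(idx)) {
        excess <- if (scheme == "at-clip") 0
                  else stats::rexp(length(idx), rate = 1 / mean_excess)
        v[idx] <- -(dataset$clip_point + excess)
      }
      out[r, ] <- analyse_once(v)
    }
    out
  })
  colnames(reps) <- c("p_standard", "lo_standard", "hi_standard",
                      "p_augmented", "lo_augmented", "hi_augmented")
  range_df <- function(cols) {
    m <- reps[, cols, drop = FALSE]
    df <- data.frame(p_hat = range(m[, 1L]), ci_lower = range(m[, 2L]),
                     ci_upper = range(m[, 3L]))
    rownames(df) <- c("min", "max")
    df
  }
  list(standard = range_df(1:3), augmented = range_df(4:6),
       n_replicates = n_replicates, scheme = scheme)
}

#' Waterfall-plot data export
#'
#' Plot-ready table for a waterfall chart: patients sorted by descending
#' PSA reduction (largest decline first; ties keep input order), with
#' responder and clipped flags.
#'
#' @param dataset A [psa_dataset()].
#' @return data.frame with columns `rank`, `psa_reduction`, `responder`,
#'   `clipped`.
#' @export
export_waterfall_data <- function(dataset) {
  stopifnot(inherits(dataset, "psa_dataset"))
  s <- classify_responders(dataset)
  clipped <- rep(FALSE, length(dataset$values))
  if (dataset$n_clipped > 0L && !is.null(dataset$clip_point)) {
    at <- which(dataset$values == -dataset$clip_point)
    clipped[at[seq_len(min(dataset$n_clipped, length(at)))]] <- TRUE
  }
  ord <- order(-dataset$values)   # stable: ties keep input order
  data.frame(rank = seq_along(ord),
             psa_reduction = dataset$values[ord],
             responder = s[ord],
             clipped = clipped[ord])
}
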