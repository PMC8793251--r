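# Synthetic waterfall-plot data with known ground truth.
#
# Latent model: the post/baseline PSA ratio is log-normal,
# log R ~ N(mu_log, sigma_log^2), so the percentage reduction
# Y = 100 * (1 - R) is bounded above by 100 and right-skewed — the shape
# seen in published waterfall plots. Response Y > d corresponds to
# log R < log(1 - d/100), giving a closed-form true response probability.

#' Configuration for one synthetic arm
#'
#' @param n Number of patients (>= 3).
#' @param mu_log Mean of the latent log PSA ratio (0 = no change on
#'   average; negative values mean PSA falls).
#' @param sigma_log SD of the latent log ratio, > 0. Around 0.5-1.5 matches
#'   the spread of published mCRPC waterfall plots.
#' @param threshold Response threshold `d` in percent reduction.
#' @param clip_point Optional plot ceiling as a percentage increase: bars
#'   beyond it are recorded at the ceiling and counted as clipped.
#' @param seed Optional integer seed making [generate_arm()] deterministic;
#'   `NULL` uses (and advances) the current RNG stream.
#' @param contam_prob,contam_shift Optional contamination: with probability
#'   `contam_prob` a patient's latent mean is shifted by `contam_shift`
#'   (a second latent component), for misspecification robustness checks.
#' @return Object of class `synthetic_arm_config`.
#' @export
synthetic_arm_config <- function(n, mu_log, sigma_log, threshold = 50,
                                 clip_point = NULL, seed = NULL,
                                 contam_prob = 0, contam_shift = 0) {
  if (n < 3) stop("'n' must be >= 3")
  if (sigma_log <= 0) stop("'sigma_log' must be > 0")
  if (contam_prob < 0 || contam_prob > 1) stop("'contam_prob' in [0, 1]")
  structure(
    list(n = as.integer(n), mu_log = mu_log, sigma_log = sigma_log,
         threshold = threshold, clip_point = clip_point, seed = seed,
         contam_prob = contam_prob, contam_shift = contam_shift),
    class = "synthetic_arm_config")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # initialise the RNG state so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate one synthetic arm
#'
#' Draws latent log ratios `L_i ~ N(mu_log, sigma_log^2)` and returns
#' `Y_i = 100 * (1 - exp(L_i))` as a [psa_dataset()]. If a clip point is
#' configured, increases beyond it are recorded at the ceiling (exactly what
#' a clipped waterfall bar shows) and `n_clipped` is set accordingly.
#' Deterministic under `config$seed`.
#'
#' @param config A [synthetic_arm_config()].
#' @return A [psa_dataset()].
#' @export
generate_arm <- function(config) {
  stopifnot(inherits(config, "synthetic_arm_config"))
  with_seed(config$seed, {
    mu <- rep(config$mu_log, config$n)
    if (config$contam_prob > 0) {
      hit <- stats::runif(config$n) < config$contam_prob
      mu[hit] <- mu[hit] + config$contam_shift
    }
    l <- stats::rnorm(config$n, mu, config$sigma_log)
    y <- 100 * (1 - exp(l))
    n_clipped <- 0L
    if (!is.null(config$clip_point)) {
      clipped <- y < -config$clip_point
      n_clipped <- sum(clipped)
      y[clipped] <- -config$clip_point
    }
    psa_dataset(y, config$threshold, arm_label = "synthetic",
                n_clipped = n_clipped, clip_point = config$clip_point)
  })
}

#' Closed-form true response probability of a synthetic arm
#'
#' Under the latent log-normal model, `Y > d` iff
#' `L < log(1 - d/100)`, so the exact response probability is
#' `pnorm((log(1 - d/100) - mu_log) / sigma_log)`. At `d = 100` the
#' argument is `-Inf` and the probability is 0. Contamination is accounted
#' for by mixing the two components. Clipping does not change the
#' probability because the ceiling lies on the increase side of any
#' positive reduction threshold.
#'
#' @param config A [synthetic_arm_config()].
#' @return The exact response probability.
#' @export
true_response_probability <- function(config) {
  stopifnot(inherits(config, "synthetic_arm_config"))
  cutoff <- if (config$threshold >= 100) -Inf else log(1 - config$threshold / 100)
  p0 <- stats::pnorm((cutoff - config$mu_log) / config$sigma_log)
  if (config$contam_prob > 0) {
    p1 <- stats::pnorm((cutoff - config$mu_log - config$contam_shift) /
                         config$sigma_log)
    (1 - config$contam_prob) * p0 + config$contam_prob * p1
  } else {
    p0
  }
}

#' Generate a synthetic corpus of arms
#'
#' Emulates a corpus of reverse-engineered mCRPC waterfall datasets: arm
#' sizes log-normal with median ~30, thresholds 30\% or 50\%, target
#' response rates roughly uniform over ~0-80\%, latent spreads
#' `sigma_log ~ U(0.5, 1.5)`, and a fraction of arms clipped at a +100\%
#' ceiling. Each arm's latent mean is solved from its target rate, so every
#' arm has a closed-form truth.
#'
#' @param n_arms Number of arms (>= 1).
#' @param seed Integer seed; the corpus is fully reproducible under it.
#' @param dir Optional directory: when given, one CSV per arm plus a
#'   `manifest.csv` are written there in the package's file dialect.
#' @param n_range Median and bounds for arm sizes, as
#'   `list(median, min, max)`.
#' @param p_range Range of target response rates.
#' @param sigma_range Range of latent log-ratio SDs.
#' @param thresholds Candidate thresholds, sampled uniformly.
#' @param clip_prob Probability an arm's plot is clipped.
#' @param clip_point Ceiling used for clipped arms (percent increase).
#' @return List with `datasets` (list of [psa_dataset()]), `configs`
#'   (list of [synthetic_arm_config()]), and `manifest` (data.frame in the
#'   manifest dialect, with a `true_p` column appended).
#' @export
generate_corpus <- function(n_arms, seed = 1L, dir = NULL,
                            n_range = list(median = 30, min = 10, max = 120),
                            p_range = c(0.02, 0.80),
                            sigma_range = c(0.5, 1.5),
                            thresholds = c(30, 50),
                            clip_prob = 0.35, clip_point = 100) {
  if (n_arms < 1) stop("'n_arms' must be >= 1")
  with_seed(seed, {
    ns <- pmin(pmax(round(stats::rlnorm(n_arms, log(n_range$median), 0.45)),
                    n_range$min), n_range$max)
    p_target <- stats::runif(n_arms, p_range[1], p_range[2])
    sig <- stats::runif(n_arms, sigma_range[1], sigma_range[2])
    d <- sample(thresholds, n_arms, replace = TRUE)
    clip <- stats::runif(n_arms) < clip_prob
    arm_seeds <- sample.int(.Machine$integer.max - 1L, n_arms)
    configs <- vector("list", n_arms)
    datasets <- vector("list", n_arms)
    for (i in seq_len(n_arms)) {
      # latent mean solved so the arm's true rate equals its target
      mu <- log(1 - d[i] / 100) - stats::qnorm(p_target[i]) * sig[i]
      configs[[i]] <- synthetic_arm_config(
        ns[i], mu, sig[i], threshold = d[i],
        clip_point = if (clip[i]) clip_point else NULL,
        seed = arm_seeds[i])
      arm <- generate_arm(configs[[i]])
      arm$arm_label <- sprintf("arm_%03d", i)
      datasets[[i]] <- arm
    }
    manifest <- data.frame(
      arm_label = vapply(datasets, `[[`, "", "arm_label"),
      path = sprintf("arm_%03d.csv", seq_len(n_arms)),
      threshold = d,
      orientation = "reduction",
      n_clipped = vapply(datasets, `[[`, 0L, "n_clipped"),
      clip_point = ifelse(clip, clip_point, NA_real_),
      true_p = vapply(configs, true_response_probability, 0),
      stringsAsFactors = FALSE)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      for (i in seq_len(n_arms))
        write_arm_csv(datasets[[i]], file.path(dir, manifest$path[i]))
      write_manifest(manifest, file.path(dir, "manifest.csv"))
    }
    list(datasets = datasets, configs = configs, manifest = manifest)
  })
}
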