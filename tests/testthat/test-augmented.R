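test_that("positive-scale mapping: ratio algebra, flooring, shifted mode", {
  expect_equal(to_positive_scale(psa_dataset(50, 50))$r, 0.5)
  expect_equal(to_positive_scale(psa_dataset(-40, 50))$r, 1.4)
  expect_equal(to_positive_scale(psa_dataset(50, 50))$r_threshold, 0.5)

  ds <- psa_dataset(c(100, 60, -10), 50)   # one complete response
  expect_warning(pos <- to_positive_scale(ds), "floored")
  expect_equal(pos$r[1], 1e-4)
  expect_equal(pos$floored_count, 1L)
  # classification unchanged by flooring: response iff ratio < threshold ratio
  expect_equal(as.integer(pos$r < pos$r_threshold), classify_responders(ds))

  sh <- to_positive_scale(psa_dataset(c(-120, 20, 80), 50), scale = "shifted")
  expect_true(all(sh$r > 0))
  expect_identical(sh$direction, "above")
  expect_equal(as.integer(sh$r > sh$r_threshold),
               classify_responders(psa_dataset(c(-120, 20, 80), 50)))
})

test_that("lambda selection recovers the generating transform", {
  set.seed(101)
  # log-normal data: log is the normalising transform, lambda near 0
  r_log <- exp(rnorm(500, -1, 0.8))
  expect_lt(abs(select_lambda(r_log)), 0.25)
  # already-normal positive data: identity, lambda near 1
  r_id <- rnorm(500, 10, 1)
  expect_lt(abs(select_lambda(r_id) - 1), 0.35)
  expect_error(select_lambda(rep(2, 10)), "degenerate")
  expect_error(select_lambda(c(1, 2)), "at least 3")
  expect_error(select_lambda(c(-1, 1, 2)), "positive")
})

test_that("lambda selection agrees with an independent profile-likelihood oracle", {
  # MASS::boxcox profiles the same likelihood; compare argmax on a shared grid
  set.seed(102)
  r <- exp(rnorm(80, 0, 0.6)) + 0.2
  grid <- seq(-3, 3, by = 0.01)
  bc <- MASS::boxcox(r ~ 1, lambda = grid, plotit = FALSE)
  expect_equal(select_lambda(r, grid), bc$x[which.max(bc$y)], tolerance = 0.011)
})

test_that("Box-Cox transform is monotone and classification-preserving", {
  r <- c(0.05, 0.4, 1, 1.6)
  fit1 <- boxcox_transform(r, 0.5, 1)
  expect_equal(fit1$transformed_values, r - 1)
  expect_equal(fit1$transformed_threshold, -0.5)
  fit0 <- boxcox_transform(r, 0.5, 0)
  expect_equal(fit0$transformed_values, log(r))
  set.seed(103)
  for (rep in 1:20) {
    r <- exp(rnorm(30, runif(1, -2, 0.3), runif(1, 0.3, 1.5)))
    rd <- runif(1, 0.3, 0.9)
    below <- as.integer(r < rd)
    for (lam in c(-2, -0.5, 0, 0.5, 2)) {
      bc <- boxcox_transform(r, rd, lam)
      expect_false(is.unsorted(bc$transformed_values[order(r)]))
      expect_equal(as.integer(bc$transformed_values < bc$transformed_threshold),
                   below)
    }
  }
})

test_that("normal MLE: closed form, degeneracy, parameter recovery", {
  fit <- fit_normal(c(-1, 0, 1))
  expect_equal(fit$mu, 0)
  expect_equal(fit$sigma, sqrt(2 / 3))   # divisor n, not n - 1
  expect_error(fit_normal(c(5, 5, 5)), "degenerate")
  expect_error(fit_normal(c(1, 2)), "at least 3")
  set.seed(104)
  z <- rnorm(1e4, 2, 3)
  big <- fit_normal(z)
  expect_lt(abs(big$mu - 2), 2 * 3 / sqrt(1e4))
  expect_lt(abs(big$sigma - 3), 2 * 3 / sqrt(2 * 1e4))
})

test_that("response estimate follows the fitted CDF in both directions", {
  fit <- fit_normal(c(-1, 0, 1))
  expect_equal(augmented_response_estimate(fit, 0, "above"), 0.5)
  expect_equal(augmented_response_estimate(fit, 0, "below"), 0.5)
  unit <- structure(list(mu = 0, sigma = 1, n = 100), class = "normal_fit")
  expect_equal(augmented_response_estimate(unit, 1.6448536, "above"), 0.05,
               tolerance = 1e-6)
  expect_equal(augmented_response_estimate(unit, 1.6448536, "below"), 0.95,
               tolerance = 1e-6)
})

test_that("delta-method SE: closed form at u = 0 and truncation", {
  unit <- structure(list(mu = 0, sigma = 1, n = 100), class = "normal_fit")
  ci <- delta_method_ci(unit, 0, "above")
  expect_equal(ci$se, dnorm(0) / 10, tolerance = 1e-10)
  # p-hat near 1 with small n: upper bound truncated at exactly 1
  tight <- structure(list(mu = 5, sigma = 1, n = 5), class = "normal_fit")
  hi <- delta_method_ci(tight, 0, "above")
  expect_identical(hi$upper, 1)
  expect_gte(hi$lower, 0)
  # logit-scale variant stays inside (0, 1) without truncation
  lg <- delta_method_ci(tight, 0, "above", ci_scale = "logit")
  expect_lt(lg$upper, 1)
})

test_that("delta-method SE matches numerical differentiation + Fisher information", {
  # independent route: numeric gradient of p(mu, sigma) and the information
  # matrix diag(n/sigma^2, 2n/sigma^2)
  fit <- structure(list(mu = -0.4, sigma = 0.9, n = 37), class = "normal_fit")
  dl <- -1.1
  p_of <- function(mu, sigma) pnorm((dl - mu) / sigma)
  h <- 1e-6
  g <- c((p_of(fit$mu + h, fit$sigma) - p_of(fit$mu - h, fit$sigma)) / (2 * h),
         (p_of(fit$mu, fit$sigma + h) - p_of(fit$mu, fit$sigma - h)) / (2 * h))
  v <- g[1]^2 * fit$sigma^2 / fit$n + g[2]^2 * fit$sigma^2 / (2 * fit$n)
  expect_equal(delta_method_ci(fit, dl, "below")$se, sqrt(v), tolerance = 1e-6)
})

test_that("augmented analysis is permutation-invariant and threshold-monotone", {
  arm <- hofman_like_arm()
  res <- suppressWarnings(augmented_analysis(arm))
  expect_s3_class(res, "response_result")
  expect_true(res$ci_lower >= 0 && res$ci_upper <= 1)
  set.seed(105)
  perm <- psa_dataset(sample(arm$values), arm$threshold)
  res2 <- suppressWarnings(augmented_analysis(perm))
  expect_equal(res2[c("p_hat", "ci_lower", "ci_upper", "lambda")],
               res[c("p_hat", "ci_lower", "ci_upper", "lambda")])
  # raising d (stricter response) never increases p-hat at fixed lambda
  pos <- suppressWarnings(to_positive_scale(arm))
  lam <- select_lambda(pos$r)
  p_at <- sapply(c(30, 50, 70, 90), function(d) {
    bc <- boxcox_transform(pos$r, 1 - d / 100, lam)
    augmented_response_estimate(fit_normal(bc$transformed_values),
                                bc$transformed_threshold, "below")
  })
  expect_true(all(diff(p_at) <= 0))
  expect_error(augmented_analysis(psa_dataset(c(1, 2), 50)), "at least 3")
})

test_that("augmented estimate is consistent for the generator's truth", {
  cfg <- synthetic_arm_config(1e4, mu_log = log(0.5), sigma_log = 0.8,
                              threshold = 50, seed = 106L)
  arm <- generate_arm(cfg)
  res <- suppressWarnings(augmented_analysis(arm))
  truth <- true_response_probability(cfg)
  expect_equal(truth, 0.5)   # mu_log placed at the threshold log-ratio
  expect_lt(abs(res$p_hat - truth), 2 * res$se)
})
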