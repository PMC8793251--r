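test_that("corpus summary of two identical arms collapses to the arm value", {
  arm <- hofman_like_arm()
  arm2 <- arm
  arm2$arm_label <- "copy"
  summ <- reanalyse_corpus(list(arm, arm2))
  one <- compare_analyses(standard_analysis(arm),
                          suppressWarnings(augmented_analysis(arm)))
  expect_equal(summ$median_width_reduction_pct, one$width_reduction_pct)
  expect_equal(diff(summ$iqr_width_reduction_pct), 0)
  expect_equal(summ$median_ss_increase_pct, one$ss_increase_pct)
  expect_equal(summ$n_arms_narrower, 2)
})

test_that("per-arm rows equal direct calls and ignore manifest order", {
  dir <- file.path(tempdir(), "corpus-pipe")
  corp <- generate_corpus(12, seed = 21L, dir = dir)
  summ <- reanalyse_corpus(file.path(dir, "manifest.csv"))
  expect_equal(summ$n_arms + nrow(summ$exclusions), 12)
  for (i in c(2, 7)) {
    row <- summ$per_arm[summ$per_arm$arm_label == sprintf("arm_%03d", i), ]
    st <- standard_analysis(corp$datasets[[i]])
    au <- suppressWarnings(augmented_analysis(corp$datasets[[i]]))
    expect_equal(row$p_standard, st$p_hat)
    expect_equal(row$p_augmented, au$p_hat, tolerance = 1e-6)
    expect_equal(row$width_augmented, au$ci_width, tolerance = 1e-6)
  }
  man <- read_manifest(file.path(dir, "manifest.csv"))
  shuf <- reanalyse_corpus(man[rev(seq_len(nrow(man))), ], base_dir = dir)
  expect_equal(shuf$median_width_reduction_pct,
               summ$median_width_reduction_pct)
  expect_equal(shuf$pearson_r_estimates, summ$pearson_r_estimates)
})

test_that("unreadable arms are excluded with reasons, not fatal", {
  dir <- file.path(tempdir(), "corpus-bad")
  generate_corpus(4, seed = 31L, dir = dir)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  man$path[2] <- "does-not-exist.csv"
  summ <- reanalyse_corpus(man, base_dir = dir)
  expect_equal(summ$n_arms, 3)
  expect_equal(nrow(summ$exclusions), 1)
  expect_match(summ$exclusions$reason, "not found")
})

test_that("on a well-specified corpus the augmented CI is almost always narrower", {
  corp <- generate_corpus(120, seed = 41L)
  summ <- reanalyse_corpus(corp$datasets)
  expect_gte(summ$n_arms_narrower / summ$n_arms, 0.95)
  expect_gt(summ$median_width_reduction_pct, 0)
  expect_gte(summ$pearson_r_estimates, 0.9)
})

test_that("clipped-bar sensitivity: identity, invariance, monotone ranges", {
  # no clipped bars: both schemes reproduce the unperturbed analysis
  plain <- hofman_like_arm()
  st <- standard_analysis(plain)
  out <- clipped_bar_sensitivity(plain, "at-clip")
  expect_equal(out$standard["min", "p_hat"], st$p_hat)
  expect_equal(out$standard["max", "p_hat"], st$p_hat)

  # build a clipped arm: large increases recorded at the ceiling
  vals <- c(95, 80, 62, 55, 30, 10, -5, -40, -100, -100, -100)
  clipped <- psa_dataset(vals, 50, n_clipped = 3, clip_point = 100)
  # clipped bars are increases far from d: standard p-hat cannot move
  at <- clipped_bar_sensitivity(clipped, "at-clip")
  expect_equal(at$standard["min", "p_hat"], at$standard["max", "p_hat"])
  expect_equal(at$standard["min", "p_hat"], standard_analysis(clipped)$p_hat)

  expect_error(clipped_bar_sensitivity(clipped, "exponential-excess",
                                       n_replicates = 1), ">= 2")

  # augmented ranges widen as the assumed excess beyond the ceiling grows
  spread <- sapply(c(5, 25, 80), function(m) {
    r <- clipped_bar_sensitivity(clipped, "exponential-excess",
                                 n_replicates = 60, mean_excess = m,
                                 seed = 71L)
    r$augmented["max", "p_hat"] - r$augmented["min", "p_hat"]
  })
  expect_true(all(diff(spread) > 0))
  # standard p-hat still pinned: the perturbed values stay non-responders
  r <- clipped_bar_sensitivity(clipped, "exponential-excess",
                               n_replicates = 20, seed = 72L)
  expect_equal(r$standard["min", "p_hat"], r$standard["max", "p_hat"])
})

test_that("waterfall export sorts, flags, and permutes", {
  ds <- psa_dataset(c(10, 90, -20), 50)
  tab <- export_waterfall_data(ds)
  expect_equal(tab$psa_reduction, c(90, 10, -20))
  expect_equal(tab$responder, c(1L, 0L, 0L))
  expect_equal(tab$rank, 1:3)
  # no responders at all
  none <- export_waterfall_data(psa_dataset(c(-10, 5), 50))
  expect_true(all(none$responder == 0))
  # output is a permutation of the input multiset
  set.seed(81)
  big <- psa_dataset(sample(round(runif(80, -150, 100), 2)), 30)
  expect_equal(sort(export_waterfall_data(big)$psa_reduction),
               sort(big$values))
  # clipped flags survive sorting
  cl <- psa_dataset(c(60, -100, 20), 50, n_clipped = 1, clip_point = 100)
  tcl <- export_waterfall_data(cl)
  expect_equal(tcl$clipped, c(FALSE, FALSE, TRUE))
})
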