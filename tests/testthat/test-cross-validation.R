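# Fold construction and the leakage-free cross-validation harness.

test_that("event-stratified folds balance events to within one", {
  # 16 events dealt into 10 folds: six folds with 2, four with 1
  time <- rexp(100) + 0.1
  event <- c(rep(1, 16), rep(0, 84))
  plan <- make_folds(list(time = time, event = event), k = 10, seed = 3)
  ev_counts <- as.vector(tapply(event, plan$fold, sum))
  expect_equal(sort(ev_counts), c(rep(1, 4), rep(2, 6)))
  # fold sizes are balanced too
  expect_lte(diff(range(tabulate(plan$fold, 10))), 1)
  # partition property
  expect_equal(sort(unique(plan$fold)), 1:10)
  expect_length(plan$fold, 100)
})

test_that("leave-one-out folds are singletons and plans are deterministic", {
  y <- rnorm(12)
  plan <- make_folds(y, k = 12, seed = 1)
  expect_equal(sort(plan$fold), 1:12)
  expect_identical(make_folds(y, k = 4, seed = 9),
                   make_folds(y, k = 4, seed = 9))
  expect_error(make_folds(y, k = 13), "more folds")
  expect_error(make_folds(y, k = 1), "at least 2")
})

test_that("random fold assignment differs across events-stratified seeds", {
  o <- list(time = rexp(60) + 0.1, event = rbinom(60, 1, 0.3))
  expect_false(identical(make_folds(o, 5, 1)$fold, make_folds(o, 5, 2)$fold))
})

test_that("out-of-fold estimates exist exactly once per subject", {
  co <- generate_cohort(synthetic_spec(n_subjects = 60, n_sites = 2,
                                       grid_shape = c(8, 8, 8), seed = 21))
  cv <- run_cv(co, light_config(subsample_mm = 6, seed = 5))
  expect_length(cv$lp, 60)
  expect_true(all(!is.na(cv$lp)))
  expect_equal(sort(unique(cv$fold)), 1:5)
})

test_that("cross-validation is fully deterministic", {
  co <- generate_cohort(synthetic_spec(n_subjects = 50, n_sites = 2,
                                       grid_shape = c(8, 8, 8),
                                       outcome_family = "gaussian",
                                       seed = 22))
  cfg <- light_config(family = "gaussian", subsample_mm = 6, seed = 7)
  cv1 <- run_cv(co, cfg)
  cv2 <- run_cv(co, cfg)
  expect_identical(cv1$lp, cv2$lp)
  expect_identical(cv1$model_hashes, cv2$model_hashes)
})

test_that("mutating a test fold changes its predictions, never its model", {
  co <- generate_cohort(synthetic_spec(n_subjects = 50, n_sites = 2,
                                       grid_shape = c(8, 8, 8),
                                       signal_effect = 2, seed = 23))
  cfg <- light_config(subsample_mm = NULL, sigma_mm = NULL,
                      channels = "gm_unmod", use_clinical = FALSE,
                      seed = 11)
  cv1 <- run_cv(co, cfg)
  # the sentinel is only informative if the models actually use voxels
  expect_gt(sum(cv1$models[[1]]$members[[1]]$beta != 0), 0)
  f1 <- which(cv1$fold == 1)
  co2 <- co
  set.seed(99)
  co2$volumes[f1, , , , ] <- co2$volumes[f1, , , , ] +
    array(rnorm(length(co2$volumes[f1, , , , ]), 0, 0.5),
          dim(co2$volumes[f1, , , , , drop = FALSE]))
  cv2 <- run_cv(co2, cfg)
  # fold 1's model was trained without fold-1 subjects: identical bundle
  expect_identical(cv1$model_hashes[1], cv2$model_hashes[1])
  # but fold 1's out-of-fold predictions respond to the mutation
  expect_false(isTRUE(all.equal(cv1$lp[f1], cv2$lp[f1])))
  # other folds' models trained on the mutated subjects must change
  expect_false(all(cv1$model_hashes[-1] == cv2$model_hashes[-1]))
})

test_that("gaussian signal beats the null model out of fold across seeds", {
  wins <- 0
  for (s in 1:10) {
    co <- generate_cohort(synthetic_spec(
      n_subjects = 100, n_sites = 2, grid_shape = c(8, 8, 8),
      outcome_family = "gaussian", signal_effect = 1,
      seed = 500 + s))
    cv <- run_cv(co, light_config(family = "gaussian", subsample_mm = 6,
                                  seed = s))
    if (cv$evaluation$mae < cv$evaluation$null_mae) wins <- wins + 1
  }
  expect_equal(wins, 10)
})

test_that("setting comparison: self vs self is exact, pairing is enforced", {
  co <- generate_cohort(synthetic_spec(n_subjects = 60, n_sites = 2,
                                       grid_shape = c(8, 8, 8),
                                       outcome_family = "gaussian",
                                       seed = 31))
  cfg <- light_config(family = "gaussian", subsample_mm = 6, seed = 3)
  cfg_salted <- cfg
  cfg_salted$salt <- "no-op"                # different hash, same pipeline
  cmp <- run_setting_comparison(co, list(ref = cfg, salted = cfg_salted),
                                reference = "ref")
  expect_equal(cmp$table$mae[1], cmp$table$mae[2])
  expect_equal(cmp$table$p_vs_reference[2], 1)
  expect_true(is.na(cmp$table$p_vs_reference[1]))
  # mismatched seeds break the paired design
  cfg_bad <- light_config(family = "gaussian", subsample_mm = 6, seed = 4)
  expect_error(run_setting_comparison(co, list(cfg, cfg_bad)), "share")
  # survival outcomes have no defined absolute error
  cos <- generate_cohort(synthetic_spec(n_subjects = 60, n_sites = 2,
                                        grid_shape = c(8, 8, 8), seed = 32))
  expect_error(run_setting_comparison(cos, list(light_config(seed = 1))),
               "gaussian/binomial")
})

test_that("signal model is significantly better than null predictions", {
  co <- generate_cohort(synthetic_spec(
    n_subjects = 200, n_sites = 2, grid_shape = c(8, 8, 8),
    outcome_family = "gaussian", signal_effect = 1, seed = 77))
  cfg <- light_config(family = "gaussian", subsample_mm = 6, seed = 7)
  cmp <- run_setting_comparison(co, list(main = cfg), reference = "main")
  expect_lt(cmp$table$p_vs_null[1], 0.05)
})
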