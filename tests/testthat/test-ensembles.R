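# Half-brain plans, subject bootstraps and mean aggregation.

test_that("half-brain plans are deterministic and partition the mask", {
  mask <- voxelsurv:::ellipsoid_mask(c(16, 16, 16))
  p1 <- make_half_brain_plan(mask, rep(3, 3), n_members = 18, seed = 4)
  p2 <- make_half_brain_plan(mask, rep(3, 3), n_members = 18, seed = 4)
  expect_identical(voxelsurv:::hash_of(p1), voxelsurv:::hash_of(p2))
  expect_false(identical(
    voxelsurv:::hash_of(make_half_brain_plan(mask, rep(3, 3), 18, 5)),
    voxelsurv:::hash_of(p1)))
  # each subset + the subset of the antipodal direction partition the mask
  nvox <- sum(mask)
  idx <- which(mask)
  coords <- sweep(arrayInd(idx, dim(mask)), 2, rep(3, 3), "*")
  rel <- sweep(coords, 2, p1$centroid)
  for (k in c(1, 7, 18)) {
    s <- p1$subsets[[k]]
    anti <- drop(rel %*% (-p1$directions[k, ])) >= 0
    # generic rotations put no voxel exactly on the plane
    expect_equal(sum(s) + sum(anti), nvox)
    expect_true(all(xor(s, anti)))
  }
  # union over members covers the mask
  expect_true(all(Reduce(`|`, p1$subsets)))
  # roughly half the mask on a symmetric ellipsoid
  expect_lt(abs(sum(p1$subsets[[1]]) / nvox - 0.5), 0.1)
})

test_that("degenerate masks are handled", {
  mask <- array(FALSE, c(3, 3, 3)); mask[2, 2, 2] <- TRUE
  plan <- make_half_brain_plan(mask, rep(3, 3), n_members = 3, seed = 1)
  expect_true(all(vapply(plan$subsets, all, logical(1))))
  expect_error(make_half_brain_plan(array(FALSE, c(2, 2, 2)), rep(3, 3)),
               "empty mask")
})

test_that("aggregation is the arithmetic mean with ties to low risk", {
  est <- aggregate_members(cbind(c(1, -1), c(1, 1)))
  expect_equal(est$lp, c(1, 0))
  expect_equal(as.character(est$risk_group), c("HRR", "low"))
  # identical members reproduce the member value
  m <- matrix(rep(c(0.3, -0.2), 5), 2, 5)
  expect_equal(aggregate_members(m)$lp, c(0.3, -0.2))
  # permutation invariance over members
  set.seed(2)
  lps <- matrix(rnorm(18 * 7), 7, 18)
  e1 <- aggregate_members(lps)
  e2 <- aggregate_members(lps[, sample(18)])
  expect_equal(e1$lp, e2$lp)
  expect_equal(e1$lp, rowMeans(lps))         # independent re-computation
  expect_error(aggregate_members(list()), "empty")
})

test_that("no-ensemble fit is a single member equal to the base fit", {
  co <- generate_cohort(synthetic_spec(n_subjects = 60, n_sites = 2,
                                       grid_shape = c(8, 8, 8),
                                       outcome_family = "gaussian",
                                       seed = 6))
  cfg <- voxelsurv_config(family = "gaussian", ensemble_method = "none",
                          subsample_mm = 6, inner_folds = 5)
  m <- voxelsurv(co, cfg)
  expect_length(m$members, 1)
  # base fit: the same penalized regression run directly
  prep <- voxelsurv:::prepare_features(co, cfg)
  fit2 <- voxelsurv:::fit_prepared(prep, cfg, seed_base = cfg$seed)
  expect_identical(m$members[[1]]$beta, fit2$members[[1]]$beta)
})

test_that("voxel members only select signal their half-brain contains", {
  # plant all signal in the +x half of the grid
  g <- c(8, 8, 8)
  mask <- voxelsurv:::ellipsoid_mask(g)
  right <- which(mask & (slice.index(mask, 1) >= 7))
  coords <- arrayInd(right[1:6], g)
  hits_with <- 0; n_with <- 0; hits_without <- 0; n_without <- 0
  for (s in 1:3) {
    co <- generate_cohort(synthetic_spec(
      n_subjects = 120, n_sites = 2, grid_shape = g,
      signal_coords = coords, signal_voxel_count = 6,
      signal_effect = 1.2, outcome_family = "gaussian",
      site_shift = 0, site_scale = 0, seed = 40 + s))
    cfg <- voxelsurv_config(family = "gaussian", channels = "gm_unmod",
                            sigma_mm = NULL, subsample_mm = NULL,
                            n_members = 6, use_clinical = FALSE,
                            seed = 40 + s)
    m <- voxelsurv(co, cfg)
    sig_names <- sprintf("gm_unmod_v%03d_%03d_%03d", coords[, 1],
                         coords[, 2], coords[, 3])
    sig_idx <- match(sig_names, m$meta_X$name)
    for (k in seq_along(m$members)) {
      has_sig <- any(sig_idx %in% m$members[[k]]$cols)
      chose_sig <- any(m$members[[k]]$beta[sig_idx] != 0)
      if (has_sig) { n_with <- n_with + 1
        hits_with <- hits_with + chose_sig
      } else { n_without <- n_without + 1
        hits_without <- hits_without + chose_sig
      }
    }
  }
  # members lacking every signal voxel cannot select one
  expect_equal(hits_without, 0)
  # members that do contain signal usually select it
  expect_gt(n_with, 0)
  expect_gte(hits_with / n_with, 0.7)
})

test_that("subject bootstrap members differ from the base model but plumbing holds", {
  co <- generate_cohort(synthetic_spec(n_subjects = 60, n_sites = 2,
                                       grid_shape = c(8, 8, 8),
                                       outcome_family = "gaussian",
                                       seed = 7))
  cfg <- voxelsurv_config(family = "gaussian", ensemble_method = "subjects",
                          n_members = 3, subsample_mm = 6)
  m <- voxelsurv(co, cfg)
  expect_length(m$members, 3)
  pr <- predict(m, co)
  expect_equal(dim(pr$member_lp), c(60, 3))
  expect_equal(pr$lp, rowMeans(pr$member_lp))
})
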