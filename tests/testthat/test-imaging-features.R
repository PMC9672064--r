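# Smoothing, subsampling, feature assembly and univariate screening.

test_that("a unit impulse smooths to the explicit dense-kernel convolution", {
  g <- c(16, 16, 16)
  arr <- array(0, g); arr[8, 8, 8] <- 1
  sv <- 1                                  # sigma = one voxel per axis
  sm <- voxelsurv:::gaussian_smooth_3d(arr, rep(sv, 3))
  # oracle: explicitly constructed separable kernel, dense summation
  k <- voxelsurv:::gauss_kernel(sv)
  r <- (length(k) - 1) / 2
  oracle <- array(0, g)
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    oracle[8 + dx, 8 + dy, 8 + dz] <-
      k[dx + r + 1] * k[dy + r + 1] * k[dz + r + 1]
  }
  expect_equal(sm, oracle, tolerance = 1e-12)
  # center value approximates the continuous Gaussian density peak
  expect_equal(sm[8, 8, 8], (2 * pi)^(-3 / 2) / sv^3, tolerance = 0.01)
})

test_that("smoothing conserves total intensity away from the boundary", {
  g <- c(20, 20, 20)
  set.seed(1)
  arr <- array(0, g)
  arr[9:12, 9:12, 9:12] <- runif(64)       # support >= 3 sigma from edges
  sm <- voxelsurv:::gaussian_smooth_3d(arr, rep(1.5, 3))
  expect_equal(sum(sm), sum(arr), tolerance = 1e-6)
})

test_that("a sub-voxel kernel degenerates to the identity", {
  set.seed(2)
  arr <- array(rnorm(6^3), c(6, 6, 6))
  sm <- voxelsurv:::gaussian_smooth_3d(arr, rep(0.15, 3))
  expect_equal(sm, arr, tolerance = 1e-6)
  co <- flat_cohort(noise_sd = 0.1)
  expect_error(smooth_volumes(co, -1), "positive")
})

test_that("block-mean subsampling matches an explicit loop oracle", {
  set.seed(3)
  arr <- array(rnorm(6^3), c(6, 6, 6))
  pooled <- voxelsurv:::block_mean_3d(arr, 2)
  oracle <- array(0, c(3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (l in 1:3) {
    oracle[i, j, l] <- mean(arr[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j),
                                (2 * l - 1):(2 * l)])
  }
  expect_equal(pooled, oracle, tolerance = 1e-12)
})

test_that("subsampling: identity at k=1, constants preserved, volume totals kept", {
  co <- flat_cohort(n = 6, g = c(8, 8, 8), mask_count = 512, value = 2,
                    noise_sd = 0.2)
  expect_identical(subsample_volumes(co, 3), co)
  sub <- subsample_volumes(co, 6)
  expect_equal(dim(sub$mask), c(4, 4, 4))
  # unmodulated constant would be preserved exactly
  co2 <- flat_cohort(n = 2, g = c(8, 8, 8), mask_count = 512, value = 3)
  sub2 <- subsample_volumes(co2, 6)
  expect_true(all(sub2$volumes[, 1, , , ] == 3))
  # modulated channels: block totals (volume) invariant
  tot_before <- sum(co$volumes[1, 2, , , ])
  expect_equal(sum(sub$volumes[1, 2, , , ]) / 8, tot_before / 8,
               tolerance = 1e-10)
  expect_equal(sum(sub$volumes[1, 2, , , ]), tot_before, tolerance = 1e-10)
  expect_error(subsample_volumes(co, 7), "integer multiple")
})

test_that("pooled mask follows the 50% occupancy rule", {
  co <- flat_cohort(n = 2, g = c(4, 4, 4), mask_count = 0, noise_sd = 0.1)
  co$mask <- array(FALSE, c(4, 4, 4))
  co$mask[1:2, 1:2, 1:2] <- TRUE            # one full 2x2x2 block
  co$mask[3, 3, 3] <- TRUE                  # 1/8 occupancy block
  sub <- subsample_volumes(co, 6)
  expect_true(sub$mask[1, 1, 1])
  expect_false(sub$mask[2, 2, 2])
})

test_that("feature assembly: column counts, order stability, global volumes", {
  co <- flat_cohort(n = 8, mask_count = 10, noise_sd = 0.1)
  f1 <- assemble_features(co, channels = "gm_unmod")
  expect_equal(ncol(f1$values), 10)
  expect_true(all(f1$meta$kind == "voxel"))
  f4 <- assemble_features(co, include_globals = TRUE)
  expect_equal(ncol(f4$values), 42)          # 4 x 10 voxel + 2 global
  expect_equal(tail(f4$meta$kind, 2), c("global", "global"))
  # order is deterministic across assemblies
  f4b <- assemble_features(co, include_globals = TRUE)
  expect_identical(voxelsurv:::hash_of(f4$meta),
                   voxelsurv:::hash_of(f4b$meta))
  expect_identical(colnames(f4$values), colnames(f4b$values))
  # gm_mod == 1 in a 10-voxel mask at 3 mm -> 270 mm^3
  co1 <- flat_cohort(n = 5, mask_count = 10, value = 1)
  g1 <- assemble_features(co1, include_globals = TRUE)
  expect_equal(unname(g1$values[, "global_gm_volume"]), rep(270, 5))
  expect_error(assemble_features(co, channels = "t1w"), "t1w")
  # midline flags come from the clinical table
  fm <- assemble_features(co, channels = "gm_unmod", include_midline = TRUE)
  expect_equal(ncol(fm$values), 12)
  co_nomid <- co; co_nomid$clinical$csp <- NULL
  expect_error(assemble_features(co_nomid, include_midline = TRUE),
               "midline")
})

test_that("zero-variance voxel features are excluded with a record", {
  co <- flat_cohort(n = 8, mask_count = 10, noise_sd = 0.1)
  co$volumes[, 1, 2, 1, 1] <- 5              # constant voxel, first channel
  f <- assemble_features(co, channels = "gm_unmod")
  expect_equal(ncol(f$values), 9)
  expect_equal(nrow(f$dropped), 1)
})

test_that("screening keeps everything at alpha=1 and falls back at alpha=0", {
  d <- sim_surv(n = 60, p = 8, seed = 4)
  keep_all <- screen_significant_voxels(d$X, list(time = d$time,
                                                  event = d$event),
                                        alpha = 1)
  expect_equal(keep_all, 1:8)
  fallback <- screen_significant_voxels(d$X, list(time = d$time,
                                                  event = d$event),
                                        alpha = 0)
  expect_equal(fallback, 1:8)                # empty set -> all kept
})

test_that("screening recovers planted signal voxels across seeds", {
  recalls <- vapply(1:10, function(s) {
    co <- generate_cohort(synthetic_spec(n_subjects = 200, n_sites = 2,
                                         site_shift = 0, site_scale = 0,
                                         seed = 200 + s))
    f <- assemble_features(co, channels = "gm_unmod")
    keep <- screen_significant_voxels(f, co$outcome, alpha = 0.05)
    sig_names <- sprintf("gm_unmod_v%03d_%03d_%03d",
                         co$truth$signal_coords[, 1],
                         co$truth$signal_coords[, 2],
                         co$truth$signal_coords[, 3])
    mean(sig_names %in% f$meta$name[keep])
  }, numeric(1))
  expect_gte(mean(recalls), 0.7)
})
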