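# Shared fixtures, all generated in code.

# Small survival data set with continuous times (no ties) and moderate
# signal in the first columns.
sim_surv <- function(n = 100, p = 10, beta = c(1, -0.8, rep(0, p - 2)),
                     censor_q = 0.7, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  lp <- drop(X %*% beta)
  tt <- rexp(n, exp(lp))
  cq <- quantile(tt, censor_q)
  list(X = X, time = pmin(tt, cq), event = as.numeric(tt < cq), lp = lp)
}

# Orthonormal design with exactly standardized, mutually orthogonal
# columns: X'X = n I, colMeans 0, colMeans(X^2) = 1.
ortho_design <- function(n = 64, p = 6, seed = 2) {
  set.seed(seed)
  M <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  Q <- qr.Q(qr(M))
  sqrt(n) * Q
}

# A minimal hand-built cohort (single constant-pattern volumes) for
# feature-assembly arithmetic tests.
flat_cohort <- function(n = 12, g = c(4, 4, 4), voxel = 3,
                        mask_count = 10, value = 1, noise_sd = 0,
                        seed = 1) {
  set.seed(seed)
  mask <- array(FALSE, g)
  mask[seq_len(mask_count)] <- TRUE
  vols <- array(value, c(n, 4, g))
  if (noise_sd > 0)
    vols <- vols + array(rnorm(length(vols), 0, noise_sd), dim(vols))
  clinical <- data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    site = factor(rep(c("a", "b"), length.out = n)),
    age = sample(18:50, n, TRUE), sex = rbinom(n, 1, 0.5),
    panss_pos = rnorm(n, 17, 5), panss_neg = rnorm(n, 18, 5),
    panss_gen = rnorm(n, 35, 8), gaf = rnorm(n, 50, 10),
    madrs = rnorm(n, 5, 3), ymrs = rnorm(n, 8, 4),
    dx_schizoaffective = rbinom(n, 1, 0.2), lai = rbinom(n, 1, 0.2),
    csp = rbinom(n, 1, 0.2), aai = rbinom(n, 1, 0.2))
  tt <- rexp(n, 0.05)
  structure(list(volumes = vols, channels = c("gm_unmod", "gm_mod",
                                              "wm_unmod", "wm_mod"),
                 mask = mask, voxel_size_mm = rep(voxel, 3),
                 affine = diag(c(rep(voxel, 3), 1)), clinical = clinical,
                 outcome = as_vx_outcome(list(time = pmin(tt, 24),
                                              event = as.numeric(tt < 24))),
                 truth = NULL,
                 spec = list(grid_shape = g, voxel_size_mm = voxel)),
            class = "vx_cohort")
}

# Light pipeline config for fast cross-validation tests.
light_config <- function(...) {
  voxelsurv_config(ensemble_method = "none", n_folds = 5, inner_folds = 5,
                   ...)
}

# Small null (no-signal) cohort spec on a coarse grid.
null_spec <- function(seed, n = 120, family = "survival") {
  synthetic_spec(n_subjects = n, n_sites = 2, grid_shape = c(8, 8, 8),
                 voxel_size_mm = 3, signal_voxel_count = 10,
                 signal_effect = 0, outcome_family = family, seed = seed)
}
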