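# Multi-site synthetic cohort generator with known ground truth.
#
# Emulates the data a voxel-based-morphometry relapse study produces: four
# intensity channels per subject on a common grid (unmodulated/modulated gray
# and white matter), a clinical table with symptom-scale items, additive and
# multiplicative site effects, a sparse set of signal voxels driven by a
# subject-level latent factor, and exponential relapse times with
# administrative censoring.  Every downstream stage of the package can be
# validated against the stored truth.

VX_CHANNELS <- c("gm_unmod", "gm_mod", "wm_unmod", "wm_mod")

#' Specify a synthetic multi-site cohort
#'
#' Defaults describe the package's reference benchmark: 240 subjects from 2
#' sites on a 16x16x16 grid of 3 mm voxels (mask = inscribed ellipsoid,
#' ~1800 in-mask voxels), 30 signal voxels whose intensities load on a
#' subject-level latent factor, and exponential relapse times censored
#' administratively at 24 months with the baseline hazard calibrated so that
#' roughly 20% of subjects relapse.
#'
#' @param n_subjects total subjects.
#' @param n_sites number of sites; `site_sizes` may give explicit sizes
#'   (must sum to `n_subjects`, each at least 3).
#' @param site_sizes optional integer vector of per-site sizes.
#' @param grid_shape voxel counts per axis.
#' @param voxel_size_mm isotropic voxel size (mm).
#' @param signal_voxel_count number of signal voxels (sampled inside the
#'   mask unless `signal_coords` is given).
#' @param signal_coords optional integer matrix (voxel indices, one row per
#'   signal voxel) overriding the random placement.
#' @param signal_cluster_size signal voxels are planted as compact
#'   clusters of about this many adjacent voxels, one sign per cluster
#'   (regional increases or decreases of tissue, the pattern real
#'   morphometric effects show); isolated random-signed voxels would
#'   largely cancel under smoothing and pooling.  Set to 1 for isolated
#'   voxels.
#' @param signal_effect per-voxel log-hazard coefficient magnitude; signs
#'   alternate randomly across clusters.  Zero gives a null cohort.
#' @param latent_sd_intensity intensity change per unit of the latent
#'   subject factor at signal voxels.
#' @param noise_sd i.i.d. voxel noise SD.
#' @param site_shift SD of the per-site additive intensity offset.
#' @param site_scale SD (log scale) of the per-site multiplicative factor.
#' @param censor_time administrative censoring time (months).
#' @param baseline_hazard_rate events per month at linear predictor 0;
#'   `NULL` calibrates it so the expected event fraction is
#'   `target_event_fraction`.
#' @param target_event_fraction used only when `baseline_hazard_rate` is
#'   `NULL`.
#' @param dropout_rate fraction of subjects with an additional uniform
#'   random censoring time (emulating loss to follow-up); 0 by default.
#' @param age_slope,sex_shift covariate effects of age (per year, centered)
#'   and sex on voxel intensities.
#' @param outcome_family `"survival"`, `"gaussian"` or `"binomial"`; the
#'   non-survival labels are derived from the same true linear predictor.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the spec.
#' @return an object of class `"vx_synthetic_spec"`.
#' @export
synthetic_spec <- function(n_subjects = 240, n_sites = 2, site_sizes = NULL,
                           grid_shape = c(16, 16, 16), voxel_size_mm = 3,
                           signal_voxel_count = 30, signal_coords = NULL,
                           signal_cluster_size = 6,
                           signal_effect = 0.8, latent_sd_intensity = 0.05,
                           noise_sd = 0.05, site_shift = 0.05,
                           site_scale = 0.15, censor_time = 24,
                           baseline_hazard_rate = NULL,
                           target_event_fraction = 0.2, dropout_rate = 0,
                           age_slope = 0.002, sex_shift = 0.01,
                           outcome_family = c("survival", "gaussian",
                                              "binomial"),
                           seed = 1) {
  outcome_family <- match.arg(outcome_family)
  if (is.null(site_sizes)) {
    site_sizes <- rep(n_subjects %/% n_sites, n_sites)
    rem <- n_subjects - sum(site_sizes)
    if (rem > 0) site_sizes[seq_len(rem)] <- site_sizes[seq_len(rem)] + 1L
  }
  if (sum(site_sizes) != n_subjects) stop("site_sizes must sum to n_subjects")
  if (any(site_sizes < 3))
    stop("every site needs at least 3 subjects (empirical-Bayes ",
         "harmonization needs >= 2, plus a margin of 1)")
  if (censor_time <= 0) stop("censor_time must be positive")
  if (!is.null(baseline_hazard_rate) && baseline_hazard_rate <= 0)
    stop("baseline_hazard_rate must be positive")
  if (site_scale < 0 || site_shift < 0) stop("site effect scales must be >= 0")
  spec <- list(n_subjects = as.integer(n_subjects),
               n_sites = as.integer(n_sites),
               site_sizes = as.integer(site_sizes),
               grid_shape = as.integer(grid_shape),
               voxel_size_mm = voxel_size_mm,
               signal_voxel_count = as.integer(signal_voxel_count),
               signal_coords = signal_coords,
               signal_cluster_size = as.integer(signal_cluster_size),
               signal_effect = signal_effect,
               latent_sd_intensity = latent_sd_intensity,
               noise_sd = noise_sd, site_shift = site_shift,
               site_scale = site_scale, censor_time = censor_time,
               baseline_hazard_rate = baseline_hazard_rate,
               target_event_fraction = target_event_fraction,
               dropout_rate = dropout_rate, age_slope = age_slope,
               sex_shift = sex_shift, outcome_family = outcome_family,
               seed = as.integer(seed))
  class(spec) <- "vx_synthetic_spec"
  spec
}

# Inscribed-ellipsoid brain mask for a grid.
ellipsoid_mask <- function(grid_shape) {
  ctr <- (grid_shape + 1) / 2
  semi <- (grid_shape - 1) / 2
  idx <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                     z = seq_len(grid_shape[3]))
  d <- ((idx$x - ctr[1]) / semi[1])^2 + ((idx$y - ctr[2]) / semi[2])^2 +
    ((idx$z - ctr[3]) / semi[3])^2
  array(d <= 1, dim = grid_shape)
}

# Smooth deterministic spatial base patterns (tissue-probability-like).
base_pattern <- function(grid_shape, which = c("gm", "wm")) {
  which <- match.arg(which)
  g <- grid_shape
  xx <- (seq_len(g[1]) - 0.5) / g[1]
  yy <- (seq_len(g[2]) - 0.5) / g[2]
  zz <- (seq_len(g[3]) - 0.5) / g[3]
  f <- if (which == "gm") {
    outer(outer(sin(pi * xx), cos(pi * yy)), sin(pi * zz))
  } else {
    outer(outer(cos(pi * xx / 2), sin(pi * yy)), cos(pi * zz / 2))
  }
  0.45 + 0.15 * f
}

#' Plant additive and multiplicative site effects into volumes
#'
#' Draws one additive offset `a_s ~ N(0, shift_scale^2)` and one
#' multiplicative factor `m_s ~ LogNormal(0, scale_scale^2)` per site and
#' transforms every voxel of every channel of site-`s` subjects as
#' `x' = m_s * (x + a_s)`.
#'
#' @param volumes 5-D array (subject, channel, x, y, z).
#' @param site_labels per-subject site labels (at least 2 distinct).
#' @param shift_scale,scale_scale nonnegative effect scales.
#' @param seed integer seed.
#' @return list with the transformed `volumes` and the drawn per-site
#'   `shift` and `scale` vectors.
#' @export
plant_site_effects <- function(volumes, site_labels, shift_scale,
                               scale_scale, seed = 1) {
  if (scale_scale < 0 || shift_scale < 0)
    stop("effect scales must be nonnegative")
  sites <- unique(site_labels)
  if (length(sites) < 2) stop("need at least 2 sites to plant site effects")
  with_seed(seed, {
    shift <- setNames(rnorm(length(sites), 0, shift_scale), sites)
    scl <- setNames(exp(rnorm(length(sites), 0, scale_scale)), sites)
  })
  if (shift_scale == 0) shift[] <- 0
  if (scale_scale == 0) scl[] <- 1
  for (s in sites) {
    i <- which(site_labels == s)
    volumes[i, , , , ] <- scl[[s]] * (volumes[i, , , , , drop = FALSE] +
                                        shift[[s]])
  }
  list(volumes = volumes, shift = shift, scale = scl)
}

# Calibrate the baseline hazard so the expected event fraction under
# administrative censoring matches the target:  E_i[1 - exp(-r e^lp_i T)].
calibrate_baseline_hazard <- function(lp, censor_time, target) {
  f <- function(logr) mean(1 - exp(-exp(logr + lp) * censor_time)) - target
  exp(stats::uniroot(f, c(-25, 10), tol = 1e-12)$root)
}

#' Generate a synthetic multi-site cohort
#'
#' Voxel intensities are a smooth spatial base pattern plus age and sex
#' effects plus (at signal voxels) a subject-level latent factor, plus
#' i.i.d. noise; modulated channels equal the unmodulated ones times a
#' subject-level warp factor; per-site additive and multiplicative effects
#' are applied last.  Relapse times are exponential with hazard
#' `baseline_hazard_rate * exp(lp_i)` where `lp_i` sums the true voxel
#' coefficients times the (pre-site-effect) signal-voxel intensities,
#' censored administratively at `censor_time`.  Gaussian and binomial labels
#' derive from the same `lp_i`.  Deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `"vx_cohort"`: a list with `volumes`
#'   (subject x channel x grid array), `channels`, `mask`, `voxel_size_mm`,
#'   `affine`, `clinical` (data frame), `outcome`, `truth`, and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "vx_synthetic_spec"))
  g <- spec$grid_shape
  mask <- ellipsoid_mask(g)
  mask_idx <- which(mask)
  if (spec$signal_voxel_count > length(mask_idx))
    stop("signal_voxel_count exceeds in-mask voxels")
  n <- spec$n_subjects
  site <- factor(rep(paste0("site", seq_len(spec$n_sites)), spec$site_sizes))
  base_gm <- base_pattern(g, "gm")
  base_wm <- base_pattern(g, "wm")

  cohort <- with_seed(spec$seed, {
    # signal placement: compact clusters with one sign each
    if (is.null(spec$signal_coords)) {
      csz <- max(1L, spec$signal_cluster_size %||% 6L)
      n_clusters <- max(1L, ceiling(spec$signal_voxel_count / csz))
      mask_coords <- arrayInd(mask_idx, g)
      centers <- sample(mask_idx, n_clusters)
      taken <- integer(0)
      cluster_id <- integer(0)
      for (ci in seq_len(n_clusters)) {
        ctr <- arrayInd(centers[ci], g)
        d2 <- rowSums(sweep(mask_coords, 2, as.numeric(ctr))^2)
        want <- min(csz, spec$signal_voxel_count - length(taken))
        cand <- order(d2)
        cand <- cand[!(mask_idx[cand] %in% taken)][seq_len(want)]
        taken <- c(taken, mask_idx[cand])
        cluster_id <- c(cluster_id, rep(ci, want))
        if (length(taken) >= spec$signal_voxel_count) break
      }
      ord <- order(taken)
      sig_lin <- taken[ord]
      cluster_id <- cluster_id[ord]
      cluster_sign <- sample(c(-1, 1), n_clusters, replace = TRUE)
      sgn <- cluster_sign[cluster_id]
    } else {
      sig_lin <- g[1] * g[2] * (spec$signal_coords[, 3] - 1) +
        g[1] * (spec$signal_coords[, 2] - 1) + spec$signal_coords[, 1]
      if (!all(sig_lin %in% mask_idx))
        stop("signal_coords must lie inside the mask")
      sgn <- sample(c(-1, 1), length(sig_lin), replace = TRUE)
    }
    beta_true <- spec$signal_effect * sgn

    age <- pmin(pmax(round(rnorm(n, 24.2, 7.4)), 12), 59)
    sex <- rbinom(n, 1, 0.34)          # 1 = female
    u <- rnorm(n)                      # latent relapse-propensity factor
    warp <- rnorm(n, 0, 0.02)          # subject-level modulation factor

    nv <- prod(g)
    vols <- array(0, dim = c(n, 4, g))
    lp <- numeric(n)
    for (i in seq_len(n)) {
      gm <- base_gm + spec$age_slope * (age[i] - 24.2) +
        spec$sex_shift * sex[i] + array(rnorm(nv, 0, spec$noise_sd), g)
      wm <- base_wm + spec$age_slope * (age[i] - 24.2) +
        spec$sex_shift * sex[i] + array(rnorm(nv, 0, spec$noise_sd), g)
      gm[sig_lin] <- gm[sig_lin] + spec$latent_sd_intensity * sgn * u[i]
      lp[i] <- sum(beta_true * (gm[sig_lin] - base_gm[sig_lin]))
      vols[i, 1, , , ] <- gm
      vols[i, 2, , , ] <- gm * (1 + warp[i])
      vols[i, 3, , , ] <- wm
      vols[i, 4, , , ] <- wm * (1 + warp[i])
    }

    site_params <- list(shift = setNames(rep(0, spec$n_sites),
                                         levels(site)),
                        scale = setNames(rep(1, spec$n_sites), levels(site)))
    if (spec$n_sites >= 2 && (spec$site_shift > 0 || spec$site_scale > 0)) {
      planted <- plant_site_effects(vols, site, spec$site_shift,
                                    spec$site_scale,
                                    seed = spec$seed + 1000L)
      vols <- planted$volumes
      site_params <- planted[c("shift", "scale")]
    }

    rate <- spec$baseline_hazard_rate %||%
      calibrate_baseline_hazard(lp, spec$censor_time,
                                spec$target_event_fraction)
    T_lat <- rexp(n, rate * exp(lp))
    cens <- rep(spec$censor_time, n)
    if (spec$dropout_rate > 0) {
      drop_i <- runif(n) < spec$dropout_rate
      cens[drop_i] <- runif(sum(drop_i), 0, spec$censor_time)
    }
    time <- pmin(T_lat, cens)
    event <- as.numeric(T_lat <= cens)
    time <- pmax(time, 1e-6)

    outcome <- switch(spec$outcome_family,
      survival = as_vx_outcome(list(time = time, event = event)),
      gaussian = as_vx_outcome(40 + 10 * lp + rnorm(n, 0, 5),
                               family = "gaussian"),
      binomial = as_vx_outcome(rbinom(n, 1, stats::plogis(2 * lp)),
                               family = "binomial"))

    clinical <- data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      site = site, age = age, sex = sex,
      panss_pos = pmax(7, round(rnorm(n, 17.6, 7.9))),
      panss_neg = pmax(7, round(rnorm(n, 18.2, 8.5))),
      panss_gen = pmax(16, round(rnorm(n, 35.9, 12.7))),
      gaf = pmin(pmax(round(rnorm(n, 50.5, 19.7)), 1), 100),
      madrs = pmax(0, round(rnorm(n, 5, 6))),
      ymrs = pmax(0, round(rnorm(n, 7.9, 10.2))),
      dx_schizoaffective = rbinom(n, 1, 0.053),
      lai = rbinom(n, 1, 0.066),
      csp = rbinom(n, 1, 0.05),
      aai = rbinom(n, 1, 0.10),
      stringsAsFactors = FALSE)

    sig_arr <- arrayInd(sig_lin, g)
    affine <- diag(c(rep(spec$voxel_size_mm, 3), 1))
    structure(list(volumes = vols, channels = VX_CHANNELS, mask = mask,
                   voxel_size_mm = rep(spec$voxel_size_mm, 3),
                   affine = affine, clinical = clinical, outcome = outcome,
                   truth = list(signal_lin = sig_lin, signal_coords = sig_arr,
                                beta = beta_true, lp = lp, u = u,
                                baseline_hazard_rate = rate,
                                site_shift = site_params$shift,
                                site_scale = site_params$scale),
                   spec = spec),
              class = "vx_cohort")
  })
  cohort
}

#' @export
print.vx_cohort <- function(x, ...) {
  o <- x$outcome
  cat("Synthetic cohort:", x$spec$n_subjects, "subjects,",
      x$spec$n_sites, "sites,", sum(x$mask), "in-mask voxels (",
      paste(x$spec$grid_shape, collapse = "x"), "grid @",
      x$spec$voxel_size_mm, "mm)\n")
  if (o$family == "survival")
    cat("Outcome: survival,", sum(o$event), "events /",
        length(o$event), "subjects, censored at", x$spec$censor_time,
        "months\n")
  else cat("Outcome:", o$family, "\n")
  invisible(x)
}

#' Subset a cohort by subject index
#'
#' @param cohort a `"vx_cohort"`.
#' @param idx integer or logical subject index.
#' @return the cohort restricted to those subjects (truth linear
#'   predictors subset alongside when present).
#' @export
subset_cohort <- function(cohort, idx) {
  co <- cohort
  co$volumes <- co$volumes[idx, , , , , drop = FALSE]
  co$clinical <- co$clinical[idx, , drop = FALSE]
  co$outcome <- subset_outcome(as_vx_outcome(co$outcome), idx)
  if (!is.null(co$truth)) {
    co$truth$lp <- co$truth$lp[idx]
    co$truth$u <- co$truth$u[idx]
  }
  co
}

#' Write a cohort to disk (NIfTI volumes + CSV clinical + JSON truth)
#'
#' One gzipped NIfTI file per subject and channel
#' (`sub-<id>_chan-<gm|wm>_<unmod|mod>.nii.gz`), the mask as
#' `mask.nii.gz`, the clinical table as `clinical.csv`, and the ground truth
#' as `truth.json`.
#'
#' @param cohort a `"vx_cohort"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(cohort$clinical)
  vdim <- cohort$voxel_size_mm
  for (i in seq_len(n)) {
    for (ch in seq_along(cohort$channels)) {
      fn <- file.path(dir, sprintf("%s_chan-%s.nii.gz",
                                   cohort$clinical$subject_id[i],
                                   cohort$channels[ch]))
      img <- RNifti::asNifti(array(cohort$volumes[i, ch, , , ],
                                   dim = cohort$spec$grid_shape),
                             pixdim = vdim)
      RNifti::writeNifti(img, fn)
    }
  }
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(cohort$mask),
                                           dim = cohort$spec$grid_shape),
                                     pixdim = vdim),
                     file.path(dir, "mask.nii.gz"))
  write.csv(cbind(cohort$clinical,
                  time = cohort$outcome$time %||% NA,
                  event = cohort$outcome$event %||% NA,
                  y = cohort$outcome$y %||% NA),
            file.path(dir, "clinical.csv"), row.names = FALSE)
  truth <- cohort$truth
  truth$signal_coords <- unname(apply(truth$signal_coords, 1, identity,
                                      simplify = FALSE))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
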