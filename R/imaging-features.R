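# Voxel feature engineering: Gaussian smoothing, block-mean subsampling,
# feature-matrix assembly, and univariate significance screening.
# The pipeline order is fixed: smooth first, then subsample.

# FWHM convention: FWHM = 2 sqrt(2 ln 2) sigma ~= 2.3548 sigma.
#' @export
fwhm_from_sigma <- function(sigma_mm) 2 * sqrt(2 * log(2)) * sigma_mm

# 1-D discrete Gaussian kernel, truncated at ceil(4 sigma) voxels and
# normalized to unit sum.  sigma below ~0.15 voxels degenerates to identity.
gauss_kernel <- function(sigma_vox) {
  r <- ceiling(4 * sigma_vox)
  if (sigma_vox <= 0.05 || r < 1) return(1)
  w <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  w / sum(w)
}

# Separable 3-D Gaussian convolution with zero padding outside the grid.
gaussian_smooth_3d <- function(arr, sigma_vox) {
  g <- dim(arr)
  smooth_axis1 <- function(a, sv) {
    k <- gauss_kernel(sv)
    if (length(k) == 1) return(a)
    d1 <- dim(a)[1]
    r <- (length(k) - 1) / 2
    K <- matrix(0, d1, d1)
    for (off in -r:r) {
      idx <- which(seq_len(d1) + off >= 1 & seq_len(d1) + off <= d1)
      K[cbind(idx, idx + off)] <- k[off + r + 1]
    }
    array(K %*% matrix(a, d1, length(a) / d1), dim = dim(a))
  }
  arr <- smooth_axis1(arr, sigma_vox[1])
  arr <- aperm(smooth_axis1(aperm(arr, c(2, 1, 3)), sigma_vox[2]),
               c(2, 1, 3))
  aperm(smooth_axis1(aperm(arr, c(3, 2, 1)), sigma_vox[3]), c(3, 2, 1))
}

#' Smooth cohort volumes with an isotropic Gaussian kernel
#'
#' Per-channel 3-D Gaussian convolution with per-axis sigma (in voxels) of
#' `sigma_mm / voxel_size_mm`, zero padding outside the grid.  The
#' corresponding FWHM is `2 sqrt(2 ln 2) * sigma_mm`.
#'
#' @param cohort a `"vx_cohort"`.
#' @param sigma_mm kernel sigma in mm (> 0).
#' @return the cohort with smoothed volumes (values outside the mask zeroed).
#' @export
smooth_volumes <- function(cohort, sigma_mm) {
  if (sigma_mm <= 0) stop("sigma_mm must be positive")
  if (any(cohort$voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  sv <- sigma_mm / cohort$voxel_size_mm
  n <- dim(cohort$volumes)[1]
  for (i in seq_len(n)) {
    for (ch in seq_along(cohort$channels)) {
      sm <- gaussian_smooth_3d(array(cohort$volumes[i, ch, , , ],
                                     dim(cohort$mask)), sv)
      sm[!cohort$mask] <- 0
      cohort$volumes[i, ch, , , ] <- sm
    }
  }
  cohort$smoothed_sigma_mm <- sigma_mm
  cohort
}

pool_axis1 <- function(a, k) {
  d <- dim(a)
  colMeans(array(a, c(k, d[1] / k, d[2], d[3])), dims = 1)
}

block_mean_3d <- function(arr, k) {
  a <- pool_axis1(arr, k)
  a <- aperm(pool_axis1(aperm(a, c(2, 1, 3)), k), c(2, 1, 3))
  aperm(pool_axis1(aperm(a, c(3, 2, 1)), k), c(3, 2, 1))
}

#' Subsample cohort volumes by block-mean pooling
#'
#' Pools k x k x k blocks (k = `target_voxel_mm / voxel_size_mm`, which must
#' be an integer) by their mean; the pooled mask voxel is true iff at least
#' 50% of its source block is inside the mask; modulated channels are
#' additionally multiplied by k^3 so block totals (absolute volume) are
#' preserved.
#'
#' @param cohort a `"vx_cohort"`.
#' @param target_voxel_mm target voxel size, an integer multiple of the
#'   current size.
#' @return the subsampled cohort (grid, mask, affine updated).
#' @export
subsample_volumes <- function(cohort, target_voxel_mm) {
  ratio <- target_voxel_mm / cohort$voxel_size_mm[1]
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("target voxel size must be an integer multiple of the current size")
  k <- as.integer(round(ratio))
  if (k == 1) return(cohort)
  g <- dim(cohort$mask)
  if (any(g %% k != 0)) stop("grid shape not divisible by pooling factor")
  gnew <- g %/% k
  newmask <- block_mean_3d(array(as.numeric(cohort$mask), g), k) >= 0.5
  if (!any(newmask))
    stop("pooling to ", target_voxel_mm, " mm leaves no in-mask voxel ",
         "(no block reaches 50% occupancy); use a finer target")
  n <- dim(cohort$volumes)[1]
  newvols <- array(0, c(n, length(cohort$channels), gnew))
  modulated <- grepl("_mod$", cohort$channels)
  for (i in seq_len(n)) {
    for (ch in seq_along(cohort$channels)) {
      b <- block_mean_3d(array(cohort$volumes[i, ch, , , ], g), k)
      if (modulated[ch]) b <- b * k^3
      newvols[i, ch, , , ] <- b
    }
  }
  cohort$volumes <- newvols
  cohort$mask <- newmask
  cohort$voxel_size_mm <- cohort$voxel_size_mm * k
  cohort$affine <- diag(c(cohort$voxel_size_mm, 1))
  cohort$spec$grid_shape <- gnew
  cohort$subsample_factor <- k
  cohort
}

#' Assemble the voxel / global / midline feature matrix
#'
#' Concatenates, in fixed order: in-mask voxel features for each selected
#' channel, then (optionally) global gray matter volume and global brain
#' volume computed from the modulated maps, then (optionally) the midline
#' binary flags from the clinical table.  Zero-variance voxel columns are
#' excluded (recorded in the `dropped` element).  Clinical features are
#' appended later by the covariate-preparation step, not here.
#'
#' @param cohort a `"vx_cohort"` (already smoothed/subsampled as desired).
#' @param channels character subset of the cohort's channels.
#' @param include_globals add global GM volume (`sum(gm_mod) * voxel
#'   volume`) and global brain volume (`sum(gm_mod + wm_mod) * voxel
#'   volume`).
#' @param include_midline add the `csp` and `aai` binary flags.
#' @return class `"vx_features"`: list with `values` (subjects x features),
#'   `meta` (per-column kind/channel/voxel coordinates/name),
#'   `subject_ids`, `site`, and `dropped` (meta of excluded zero-variance
#'   columns).
#' @export
assemble_features <- function(cohort, channels = cohort$channels,
                              include_globals = FALSE,
                              include_midline = FALSE) {
  missing_ch <- setdiff(channels, cohort$channels)
  if (length(missing_ch))
    stop("channel(s) not present: ", paste(missing_ch, collapse = ", "))
  n <- dim(cohort$volumes)[1]
  mask_lin <- which(cohort$mask)
  coords <- arrayInd(mask_lin, dim(cohort$mask))
  nv <- length(mask_lin)
  blocks <- list(); metas <- list()
  for (ch in channels) {
    ci <- match(ch, cohort$channels)
    m <- matrix(cohort$volumes[, ci, , , ], n, prod(dim(cohort$mask)))
    blocks[[ch]] <- m[, mask_lin, drop = FALSE]
    metas[[ch]] <- data.frame(
      kind = "voxel", channel = ch,
      ix = coords[, 1], iy = coords[, 2], iz = coords[, 3],
      name = sprintf("%s_v%03d_%03d_%03d", ch, coords[, 1], coords[, 2],
                     coords[, 3]),
      stringsAsFactors = FALSE)
  }
  values <- do.call(cbind, blocks)
  meta <- do.call(rbind, metas)
  if (include_globals) {
    need <- c("gm_mod", "wm_mod")
    miss <- setdiff(need, cohort$channels)
    if (length(miss))
      stop("global volumes need channel(s): ", paste(miss, collapse = ", "))
    vvol <- prod(cohort$voxel_size_mm)
    gm <- matrix(cohort$volumes[, match("gm_mod", cohort$channels), , , ],
                 n, prod(dim(cohort$mask)))[, mask_lin, drop = FALSE]
    wm <- matrix(cohort$volumes[, match("wm_mod", cohort$channels), , , ],
                 n, prod(dim(cohort$mask)))[, mask_lin, drop = FALSE]
    gvol <- rowSums(gm) * vvol
    bvol <- rowSums(gm + wm) * vvol
    values <- cbind(values, gvol, bvol)
    meta <- rbind(meta, data.frame(kind = "global", channel = NA,
                                   ix = NA, iy = NA, iz = NA,
                                   name = c("global_gm_volume",
                                            "global_brain_volume")))
  }
  if (include_midline) {
    if (!all(c("csp", "aai") %in% names(cohort$clinical)))
      stop("midline flags csp/aai missing from the clinical table")
    values <- cbind(values, cohort$clinical$csp, cohort$clinical$aai)
    meta <- rbind(meta, data.frame(kind = "midline", channel = NA,
                                   ix = NA, iy = NA, iz = NA,
                                   name = c("csp", "aai")))
  }
  colnames(values) <- meta$name
  # zero-variance voxel features are unusable under lasso standardization
  v <- apply(values, 2, var)
  drop_i <- which(v < 1e-20 & meta$kind == "voxel")
  dropped <- meta[drop_i, , drop = FALSE]
  if (length(drop_i)) {
    vx_note("excluding ", length(drop_i), " zero-variance voxel features")
    values <- values[, -drop_i, drop = FALSE]
    meta <- meta[-drop_i, , drop = FALSE]
  }
  structure(list(values = values, meta = meta,
                 subject_ids = cohort$clinical$subject_id,
                 site = cohort$clinical$site, dropped = dropped),
            class = "vx_features")
}

#' @export
print.vx_features <- function(x, ...) {
  cat("Feature matrix:", nrow(x$values), "subjects x", ncol(x$values),
      "features (", sum(x$meta$kind == "voxel"), "voxel )\n")
  invisible(x)
}

#' Univariate screening of voxel features
#'
#' Keeps voxel columns whose univariate association with the outcome has
#' P < `alpha`: a per-voxel Cox score test for survival outcomes, a
#' correlation t-test for gaussian, and a two-sample t-test for binomial.
#' Non-voxel columns are always kept.  If no voxel survives, all voxels are
#' kept (with a note) rather than returning an empty model.
#'
#' @param features a `"vx_features"` (or plain matrix of voxel features).
#' @param outcome anything accepted by [as_vx_outcome()].
#' @param alpha two-sided significance threshold (exclusive bound).
#' @return integer vector of retained column indices.
#' @export
screen_significant_voxels <- function(features, outcome, alpha = 0.05) {
  outcome <- as_vx_outcome(outcome)
  if (inherits(features, "vx_features")) {
    vals <- features$values
    is_voxel <- features$meta$kind == "voxel"
  } else {
    vals <- as.matrix(features)
    is_voxel <- rep(TRUE, ncol(vals))
  }
  vi <- which(is_voxel)
  x <- vals[, vi, drop = FALSE]
  n <- nrow(x)
  p_val <- if (outcome$family == "survival") {
    z <- cox_score_z(x, outcome$time, outcome$event)
    2 * pnorm(-abs(z))
  } else if (outcome$family == "gaussian") {
    r <- suppressWarnings(stats::cor(x, outcome$y))
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
    2 * stats::pt(-abs(tstat), n - 2)
  } else {
    g1 <- outcome$y == 1
    n1 <- sum(g1); n0 <- n - n1
    m1 <- colMeans(x[g1, , drop = FALSE])
    m0 <- colMeans(x[!g1, , drop = FALSE])
    v1 <- apply(x[g1, , drop = FALSE], 2, var)
    v0 <- apply(x[!g1, , drop = FALSE], 2, var)
    sp <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n - 2)
    tstat <- (m1 - m0) / sqrt(pmax(sp, 1e-20) * (1 / n1 + 1 / n0))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  keep_voxel <- vi[which(p_val < alpha)]
  if (length(keep_voxel) == 0) {
    vx_note("no voxel passed screening at alpha = ", alpha,
            "; keeping all voxels")
    keep_voxel <- vi
  }
  sort(c(keep_voxel, which(!is_voxel)))
}
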