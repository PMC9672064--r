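# The central model: voxelsurv() fits the full risk-estimation pipeline on
# a (training) cohort -- harmonization, residualization, clinical scaling,
# optional screening, and an L1-penalized regression ensemble -- and
# freezes every estimated parameter into a self-sufficient bundle that can
# score new subjects.

# Per-subject deterministic preprocessing (no cross-subject estimation, so
# it can run once, outside any train/test split): smooth, subsample,
# assemble voxel/global/midline features, extract clinical regressors.
prepare_features <- function(cohort, config) {
  proc <- cohort
  if (config$use_mri) {
    if (!is.null(config$sigma_mm))
      proc <- smooth_volumes(proc, config$sigma_mm)
    if (!is.null(config$subsample_mm))
      proc <- subsample_volumes(proc, config$subsample_mm)
    feats <- assemble_features(proc, channels = config$channels,
                               include_globals = config$include_globals,
                               include_midline = config$include_midline)
  } else feats <- NULL
  clin <- NULL
  if (config$use_clinical) {
    miss <- setdiff(config$clinical_vars, names(cohort$clinical))
    if (length(miss))
      stop("clinical variable(s) missing: ", paste(miss, collapse = ", "))
    clin <- as.matrix(cohort$clinical[, config$clinical_vars, drop = FALSE])
  }
  list(features = feats, clinical = clin,
       site = factor(cohort$clinical$site),
       age = cohort$clinical$age, sex = cohort$clinical$sex,
       subject_ids = cohort$clinical$subject_id,
       outcome = cohort$outcome, mask = proc$mask,
       voxel_size_mm = proc$voxel_size_mm,
       affine = proc$affine)
}

subset_prep <- function(prep, idx) {
  p <- prep
  if (!is.null(p$features)) {
    p$features$values <- p$features$values[idx, , drop = FALSE]
    p$features$subject_ids <- p$features$subject_ids[idx]
    p$features$site <- p$features$site[idx]
  }
  if (!is.null(p$clinical)) p$clinical <- p$clinical[idx, , drop = FALSE]
  p$site <- p$site[idx]
  p$age <- p$age[idx]
  p$sex <- p$sex[idx]
  p$subject_ids <- p$subject_ids[idx]
  p$outcome <- subset_outcome(as_vx_outcome(p$outcome), idx)
  p
}

identity_combat <- function(p) {
  structure(list(identity = TRUE, sites = NULL, n_features = p),
            class = "vx_combat_params")
}

# Fit transforms and the member models on (already prepared) training data.
fit_prepared <- function(prep, config, seed_base) {
  outcome <- as_vx_outcome(prep$outcome, config$family)
  n <- vx_outcome_n(outcome)
  site <- droplevels(prep$site)

  meta_mri <- NULL; mri_block <- NULL
  combat <- resid_params <- NULL
  if (!is.null(prep$features)) {
    vals <- prep$features$values
    meta_mri <- prep$features$meta
    lm_cols <- meta_mri$kind %in% c("voxel", "global")
    combat <- if (nlevels(site) >= 2)
      combat_fit(vals[, lm_cols, drop = FALSE], site)
    else identity_combat(sum(lm_cols))
    harm <- combat_apply(vals[, lm_cols, drop = FALSE], as.character(site),
                         combat)
    resid_params <- residualize_fit(harm, prep$age, prep$sex)
    resid_block <- residualize_apply(harm, prep$age, prep$sex, resid_params)
    mri_block <- cbind(resid_block,
                       vals[, !lm_cols, drop = FALSE])  # midline unchanged
    colnames(mri_block) <- c(meta_mri$name[lm_cols], meta_mri$name[!lm_cols])
    meta_mri <- rbind(meta_mri[lm_cols, , drop = FALSE],
                      meta_mri[!lm_cols, , drop = FALSE])
    keep_idx <- seq_len(ncol(mri_block))
    if (!is.null(config$screen_alpha)) {
      sf <- structure(list(values = mri_block, meta = meta_mri),
                      class = "vx_features")
      keep_idx <- screen_significant_voxels(sf, outcome,
                                            alpha = config$screen_alpha)
    }
    mri_block <- mri_block[, keep_idx, drop = FALSE]
    meta_mri <- meta_mri[keep_idx, , drop = FALSE]
  } else keep_idx <- integer(0)

  scale_params <- NULL; clin_block <- NULL
  if (!is.null(prep$clinical)) {
    scale_params <- scale_clinical_fit(prep$clinical)
    clin_block <- scale_clinical_apply(prep$clinical, scale_params)
  }

  X <- cbind(mri_block, clin_block)
  meta_X <- rbind(
    meta_mri,
    if (!is.null(clin_block))
      data.frame(kind = "clinical", channel = NA, ix = NA, iy = NA,
                 iz = NA, name = colnames(clin_block)))
  stopifnot(ncol(X) == nrow(meta_X))

  # ensemble member designs
  voxel_pos <- which(meta_X$kind == "voxel")
  plan <- NULL
  members <- vector("list", if (config$ensemble_method == "none") 1L
                            else config$n_members)
  if (config$ensemble_method == "voxels" && length(voxel_pos)) {
    plan <- make_half_brain_plan(prep$mask, prep$voxel_size_mm,
                                 n_members = length(members),
                                 seed = seed_base)
    mask_order <- which(prep$mask)
    d <- dim(prep$mask)
    vox_lin <- meta_X$ix[voxel_pos] +
      d[1] * (meta_X$iy[voxel_pos] - 1) +
      d[1] * d[2] * (meta_X$iz[voxel_pos] - 1)
    vox_slot <- match(vox_lin, mask_order)
  }
  for (k in seq_along(members)) {
    rows <- seq_len(n)
    cols <- seq_len(ncol(X))
    mseed <- seed_base + k
    if (config$ensemble_method == "subjects") {
      rows <- with_seed(mseed, resample_rows(outcome, n))
    } else if (config$ensemble_method == "voxels" && length(voxel_pos)) {
      inside <- plan$subsets[[k]][vox_slot]
      cols <- sort(c(voxel_pos[inside], setdiff(cols, voxel_pos)))
    }
    ok <- subset_outcome(outcome, rows)
    cvfit <- lasso_select_lambda(
      X[rows, cols, drop = FALSE], ok,
      nfolds = config$inner_folds, seed = mseed,
      lambda_rule = config$lambda_rule,
      tol = config$lasso_tol %||% 1e-4,
      nlambda = config$lasso_nlambda %||% 30,
      lambda_min_ratio = config$lasso_lambda_min_ratio %||% 0.05)
    idx <- which.min(abs(cvfit$path$lambda - cvfit$lambda_sel))
    beta_full <- numeric(ncol(X))
    beta_full[cols] <- cvfit$path$beta[, idx]
    members[[k]] <- list(beta = setNames(beta_full, meta_X$name),
                         a0 = cvfit$path$a0[idx],
                         lambda = cvfit$lambda_sel, seed = mseed,
                         cols = cols)
  }

  structure(list(config = config, family = outcome$family,
                 combat = combat, resid_params = resid_params,
                 scale_params = scale_params, keep_idx = keep_idx,
                 meta_X = meta_X, members = members, plan = plan,
                 n = n,
                 n_events = if (outcome$family == "survival")
                   sum(outcome$event) else NA,
                 seed_base = seed_base,
                 mask = prep$mask, voxel_size_mm = prep$voxel_size_mm,
                 affine = prep$affine),
            class = "voxelsurv")
}

# Bootstrap row resample keeping at least 2 events (redrawn, max 100
# attempts).  Runs inside with_seed().
resample_rows <- function(outcome, n) {
  for (a in seq_len(100)) {
    rows <- sample.int(n, n, replace = TRUE)
    if (outcome$family != "survival" || sum(outcome$event[rows]) >= 2)
      return(rows)
  }
  stop("could not draw a bootstrap replicate with >= 2 events")
}

# Frozen-transform scoring of prepared subjects: returns the member linear
# predictor matrix (subjects x members).
score_prepared <- function(model, prep) {
  blocks <- NULL
  if (!is.null(prep$features)) {
    vals <- prep$features$values
    meta <- prep$features$meta
    lm_cols <- meta$kind %in% c("voxel", "global")
    harm <- combat_apply(vals[, lm_cols, drop = FALSE],
                         as.character(prep$site), model$combat)
    resid_block <- residualize_apply(harm, prep$age, prep$sex,
                                     model$resid_params)
    mri_block <- cbind(resid_block, vals[, !lm_cols, drop = FALSE])
    colnames(mri_block) <- c(meta$name[lm_cols], meta$name[!lm_cols])
    blocks <- mri_block[, model$keep_idx, drop = FALSE]
  }
  if (!is.null(prep$clinical))
    blocks <- cbind(blocks,
                    scale_clinical_apply(prep$clinical, model$scale_params))
  stopifnot(identical(colnames(blocks), model$meta_X$name))
  matrix(vapply(model$members,
                function(m) drop(blocks %*% m$beta) + m$a0,
                numeric(nrow(blocks))),
         nrow = nrow(blocks))
}

#' Fit the full voxel-based risk-estimation model
#'
#' Runs the complete training pipeline on a cohort: smoothing and
#' subsampling per the configuration, feature assembly, site harmonization
#' (fit on these subjects only), age/sex residualization of the MRI
#' features, [0,1] scaling of the clinical variables, optional univariate
#' screening, and an ensemble of L1-penalized regressions with internally
#' cross-validated penalties.  The returned object freezes every estimated
#' parameter and can score new subjects with [predict.voxelsurv()].
#'
#' @param cohort a `"vx_cohort"` (see [generate_cohort()]) used as the
#'   training set.
#' @param config a [voxelsurv_config()].
#' @return an object of class `"voxelsurv"`.
#' @export
voxelsurv <- function(cohort, config = voxelsurv_config()) {
  prep <- prepare_features(cohort, config)
  fit_prepared(prep, config, seed_base = config$seed)
}

#' Score new subjects with a fitted model
#'
#' Applies the frozen preprocessing (smoothing, subsampling, harmonization
#' with the training site parameters, residualization, clinical scaling)
#' and computes each member's linear predictor `sum_j beta_j x_j`; the
#' per-subject risk estimate is the member mean, and the risk group is HRR
#' iff it is strictly positive.
#'
#' @param object a fitted `"voxelsurv"` model.
#' @param cohort a `"vx_cohort"` of new subjects (every site must be known
#'   to the harmonization parameters).
#' @param ... unused.
#' @return a `"vx_risk_estimate"` (see [aggregate_members()]) with an
#'   added `subject_id` element.
#' @export
predict.voxelsurv <- function(object, cohort, ...) {
  prep <- prepare_features(cohort, object$config)
  est <- aggregate_members(score_prepared(object, prep))
  est$subject_id <- prep$subject_ids
  est
}

#' @export
print.voxelsurv <- function(x, ...) {
  cat("voxelsurv model (", x$family, "): ", length(x$members),
      " member(s), ", nrow(x$meta_X), " candidate features, trained on ",
      x$n, " subjects", sep = "")
  if (!is.na(x$n_events)) cat(" (", x$n_events, " events)", sep = "")
  cat("\n  ensemble:", x$config$ensemble_method,
      "| mean nonzero coefficients per member:",
      round(mean(vapply(x$members, function(m) sum(m$beta != 0),
                        numeric(1))), 1), "\n")
  invisible(x)
}

#' Coefficient table of a fitted model
#'
#' Averages the members' coefficients per feature and reports the nonzero
#' ones with their provenance (kind, channel, voxel mm coordinates via the
#' affine).
#'
#' @param object a `"voxelsurv"` model.
#' @param min_abs report only coefficients with mean absolute value at
#'   least this (default 0: all nonzero).
#' @param ... unused.
#' @return data frame: name, kind, channel, x/y/z (mm), mean beta, and the
#'   number of members selecting the feature.
#' @export
coef.voxelsurv <- function(object, min_abs = 0, ...) {
  B <- vapply(object$members, function(m) m$beta,
              numeric(nrow(object$meta_X)))
  B <- matrix(B, nrow = nrow(object$meta_X))
  mb <- rowMeans(B)
  nsel <- rowSums(B != 0)
  keep <- nsel > 0 & abs(mb) >= min_abs
  m <- object$meta_X[keep, , drop = FALSE]
  vs <- object$voxel_size_mm
  data.frame(name = m$name, kind = m$kind, channel = m$channel,
             x_mm = m$ix * vs[1], y_mm = m$iy * vs[2], z_mm = m$iz * vs[3],
             beta = mb[keep], members = nsel[keep],
             row.names = NULL)[order(-abs(mb[keep])), ]
}

#' @export
summary.voxelsurv <- function(object, ...) {
  tab <- coef(object)
  cat("voxelsurv model summary\n")
  print(object)
  cat("  features selected by >= 1 member:", nrow(tab), "\n")
  if (nrow(tab)) {
    cat("  top coefficients:\n")
    print(head(tab, 10), digits = 3)
  }
  invisible(tab)
}
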