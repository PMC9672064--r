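# Pipeline configuration: fully determines a run given a cohort; hashable.

#' Pipeline configuration
#'
#' Defaults are the package's reference settings for risk modelling: all
#' four tissue channels, sigma = 4 mm smoothing, triple subsampling (12 mm
#' target voxels), a voxel half-brain ensemble of 18 members, 10 outer
#' folds, and the deviance-minimizing penalty rule.
#'
#' @param channels tissue channels to use.
#' @param sigma_mm smoothing kernel sigma (mm); `NULL` disables smoothing.
#' @param subsample_mm target voxel size (mm); `NULL` disables subsampling.
#' @param include_globals,include_midline add global volumes / midline
#'   flags to the feature block.
#' @param screen_alpha univariate screening threshold; `NULL` (default)
#'   disables screening.
#' @param ensemble_method `"none"`, `"subjects"` (bootstrap) or `"voxels"`
#'   (half brains).
#' @param n_members ensemble size (default 18).
#' @param family outcome family.
#' @param lambda_rule `"min"` or `"1se"` penalty selection.
#' @param n_folds outer cross-validation folds.
#' @param inner_folds folds of the internal penalty selection (default 5:
#'   with the small per-fold event counts typical of relapse cohorts,
#'   5-fold inner CV keeps several events per inner fold and halves the
#'   compute of the ensemble fit).
#' @param lasso_tol coordinate-descent convergence tolerance used for the
#'   ensemble member fits (1e-4: member risk scores are identical to three
#'   decimals below this; [lasso_fit()] called directly keeps its stricter
#'   1e-7 default).
#' @param lasso_nlambda,lasso_lambda_min_ratio penalty grid used for the
#'   member fits: 30 log-spaced values down to `0.05 * lambda_max`.  The
#'   cross-validated optimum sits around `0.4-0.6 * lambda_max` on
#'   realistic cohorts, far above the grid floor; the shallower grid skips
#'   only the deeply overfit tail.  ([lasso_fit()] called directly keeps
#'   its denser 100-point, 0.01-ratio default.)
#' @param use_clinical,use_mri include the clinical / MRI feature blocks
#'   (at least one must be on).
#' @param clinical_vars clinical columns used as regressors; the default
#'   takes the symptom-scale items, diagnosis indicator, long-acting
#'   injectable flag, and age (sex is excluded by default).
#' @param seed integer seed controlling folds and ensemble randomness.
#' @return an object of class `"vx_config"`.
#' @export
voxelsurv_config <- function(channels = VX_CHANNELS, sigma_mm = 4,
                             subsample_mm = 12, include_globals = FALSE,
                             include_midline = FALSE, screen_alpha = NULL,
                             ensemble_method = c("voxels", "none",
                                                 "subjects"),
                             n_members = 18,
                             family = c("survival", "gaussian", "binomial"),
                             lambda_rule = c("min", "1se"), n_folds = 10,
                             inner_folds = 5, lasso_tol = 1e-4,
                             lasso_nlambda = 30,
                             lasso_lambda_min_ratio = 0.05,
                             use_clinical = TRUE,
                             use_mri = TRUE,
                             clinical_vars = c("panss_pos", "panss_neg",
                                               "panss_gen", "gaf", "madrs",
                                               "ymrs", "dx_schizoaffective",
                                               "lai", "age"),
                             seed = 1) {
  ensemble_method <- match.arg(ensemble_method)
  family <- match.arg(family)
  lambda_rule <- match.arg(lambda_rule)
  if (!use_clinical && !use_mri)
    stop("at least one of use_clinical / use_mri must be TRUE")
  if (n_members < 1) stop("n_members must be >= 1")
  cfg <- list(channels = channels, sigma_mm = sigma_mm,
              subsample_mm = subsample_mm,
              include_globals = include_globals,
              include_midline = include_midline,
              screen_alpha = screen_alpha,
              ensemble_method = ensemble_method,
              n_members = as.integer(n_members), family = family,
              lambda_rule = lambda_rule, n_folds = as.integer(n_folds),
              inner_folds = as.integer(inner_folds),
              lasso_tol = lasso_tol,
              lasso_nlambda = as.integer(lasso_nlambda),
              lasso_lambda_min_ratio = lasso_lambda_min_ratio,
              use_clinical = use_clinical, use_mri = use_mri,
              clinical_vars = clinical_vars, seed = as.integer(seed))
  class(cfg) <- "vx_config"
  cfg
}

#' @export
print.vx_config <- function(x, ...) {
  cat("voxelsurv config:", x$family, "| channels:",
      paste(x$channels, collapse = ","), "| sigma:",
      x$sigma_mm %||% "none", "mm | subsample:",
      x$subsample_mm %||% "none", "mm | ensemble:", x$ensemble_method,
      "x", x$n_members, "| folds:", x$n_folds, "| seed:", x$seed, "\n")
  invisible(x)
}

#' Hash of a configuration (or any pipeline object)
#'
#' @param x object to hash.
#' @return md5 string.
#' @export
config_hash <- function(x) hash_of(x)
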