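# Event-stratified k-fold construction and the leakage-free train/apply
# orchestration of the full pipeline.

#' Build event-stratified cross-validation folds
#'
#' Subjects with an event are shuffled (seeded) and dealt round-robin to the
#' folds, then censored subjects likewise (continuing around the folds so
#' sizes stay balanced), so per-fold event counts differ by at most one.
#' For gaussian outcomes, subjects are dealt round-robin after a seeded
#' shuffle; for binomial, each class is dealt separately.
#'
#' @param outcome anything accepted by [as_vx_outcome()].
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return class `"vx_fold_plan"`: list with `k`, integer vector `fold`
#'   (one entry per subject), and `seed`.
#' @export
make_folds <- function(outcome, k = 10, seed = 1) {
  outcome <- as_vx_outcome(outcome)
  n <- vx_outcome_n(outcome)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("more folds than subjects")
  strata <- switch(outcome$family,
    survival = outcome$event,
    binomial = outcome$y,
    gaussian = rep(0, n))
  fold <- integer(n)
  with_seed(seed, {
    pos <- 0L  # running position around the folds, across strata
    for (s in sort(unique(strata), decreasing = TRUE)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- (pos + seq_along(idx) - 1L) %% k + 1L
      pos <- (pos + length(idx)) %% k
    }
  })
  structure(list(k = as.integer(k), fold = fold, seed = as.integer(seed)),
            class = "vx_fold_plan")
}

#' @export
print.vx_fold_plan <- function(x, ...) {
  cat("Fold plan: k =", x$k, ", sizes:",
      paste(tabulate(x$fold, x$k), collapse = " "), "\n")
  invisible(x)
}

#' Cross-validated fit and out-of-fold risk estimation
#'
#' For each fold, fits the complete pipeline (harmonization,
#' residualization, scaling, optional screening, penalized-regression
#' ensemble) on the complement and scores the held-out fold with the frozen
#' transforms, so every subject receives exactly one out-of-fold risk
#' estimate and no training-derived parameter ever sees a test subject.
#' Test subjects whose site is absent from their training split cannot be
#' harmonized and are excluded from evaluation (recorded in `excluded`).
#'
#' @param cohort a `"vx_cohort"`.
#' @param config a [voxelsurv_config()].
#' @return class `"voxelsurv_cv"`: per-subject `lp`, `risk_group`, `fold`
#'   (NA lp for excluded subjects), per-fold fitted `models` and their
#'   hashes, the fold plan, and a family-specific `evaluation` element
#'   (site-aware risk-group Cox for survival; MAE and null-model MAE for
#'   gaussian; accuracy for binomial).
#' @export
run_cv <- function(cohort, config = voxelsurv_config()) {
  prep <- prepare_features(cohort, config)
  outcome <- as_vx_outcome(prep$outcome, config$family)
  n <- vx_outcome_n(outcome)
  plan <- make_folds(outcome, k = config$n_folds, seed = config$seed)
  lp <- rep(NA_real_, n)
  excluded <- integer(0)
  models <- vector("list", plan$k)
  null_pred <- rep(NA_real_, n)   # training-mean prediction (gaussian)
  for (f in seq_len(plan$k)) {
    te <- which(plan$fold == f)
    tr <- setdiff(seq_len(n), te)
    prep_tr <- subset_prep(prep, tr)
    fit <- fit_prepared(prep_tr, config,
                        seed_base = config$seed + 1000L * f)
    models[[f]] <- fit
    known <- if (isTRUE(fit$combat$identity)) unique(as.character(prep$site))
             else fit$combat$sites
    ok <- as.character(prep$site[te]) %in% known
    if (any(!ok)) {
      vx_note(sum(!ok), " test subject(s) in fold ", f,
              " from sites absent in training; excluded")
      excluded <- c(excluded, te[!ok])
    }
    if (any(ok)) {
      prep_te <- subset_prep(prep, te[ok])
      lp[te[ok]] <- rowMeans(score_prepared(fit, prep_te))
    }
    if (outcome$family == "gaussian")
      null_pred[te] <- mean(outcome$y[tr])
  }
  risk_group <- factor(lp > 0, c(FALSE, TRUE), c("low", "HRR"))
  used <- which(!is.na(lp))
  evaluation <- switch(outcome$family,
    survival = tryCatch(
      risk_group_cox(outcome$time[used], outcome$event[used],
                     risk_group[used], prep$site[used]),
      error = function(e) {
        vx_note("risk-group Cox unavailable: ", conditionMessage(e))
        NULL
      }),
    gaussian = {
      abs_err <- abs(outcome$y[used] - lp[used])
      null_err <- abs(outcome$y[used] - null_pred[used])
      list(mae = mean(abs_err), null_mae = mean(null_err),
           abs_err = abs_err, null_abs_err = null_err)
    },
    binomial = {
      pred <- as.numeric(lp[used] > 0)
      err <- as.numeric(pred != outcome$y[used])
      list(accuracy = 1 - mean(err), err = err)
    })
  structure(list(lp = lp, risk_group = risk_group, fold = plan$fold,
                 plan = plan, models = models,
                 model_hashes = vapply(models, hash_of, character(1)),
                 excluded = excluded, used = used,
                 subject_ids = prep$subject_ids, outcome = outcome,
                 site = prep$site, config = config,
                 evaluation = evaluation),
            class = "voxelsurv_cv")
}

#' @export
print.voxelsurv_cv <- function(x, ...) {
  cat("Cross-validated voxelsurv (", x$config$family, "), k = ", x$plan$k,
      ", n = ", length(x$lp), sep = "")
  if (length(x$excluded)) cat(" (", length(x$excluded), " excluded)",
                              sep = "")
  cat("\n")
  if (x$config$family == "survival") {
    cat("Out-of-fold risk groups:",
        sum(x$risk_group == "HRR", na.rm = TRUE), "HRR /",
        sum(x$risk_group == "low", na.rm = TRUE), "low\n")
    if (!is.null(x$evaluation)) print(x$evaluation)
  } else if (x$config$family == "gaussian") {
    cat(sprintf("Out-of-fold MAE = %.3f (null model %.3f)\n",
                x$evaluation$mae, x$evaluation$null_mae))
  } else {
    cat(sprintf("Out-of-fold accuracy = %.1f%%\n",
                100 * x$evaluation$accuracy))
  }
  invisible(x)
}

#' @export
plot.voxelsurv_cv <- function(x, ...) {
  if (x$config$family != "survival")
    stop("plot is defined for survival cross-validation results")
  u <- x$used
  km <- kaplan_meier(x$outcome$time[u], x$outcome$event[u],
                     x$risk_group[u])
  plot(km, ...)
}

# Paired absolute errors of a cross-validated run (gaussian: |y - pred|;
# binomial: 0/1 misclassification indicator).
cv_abs_errors <- function(cv) {
  o <- cv$outcome
  if (o$family == "gaussian") abs(o$y - cv$lp)
  else if (o$family == "binomial") as.numeric((cv$lp > 0) != o$y)
  else stop("absolute errors are defined for gaussian/binomial runs")
}

safe_paired_wilcox <- function(a, b) {
  d <- a - b
  d <- d[!is.na(d)]
  if (length(d) == 0 || all(d == 0)) return(1)
  suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value)
}

#' Compare pipeline settings with a paired design
#'
#' Runs the cross-validated pipeline once per configuration (all configs
#' must share the family, fold count and seed, so folds -- and hence the
#' per-subject pairing -- are identical), and reports each configuration's
#' accuracy (MAE for gaussian, proportion correct for binomial) together
#' with paired Wilcoxon tests of the absolute errors against a null model
#' (gaussian: predicting every subject at the training-fold mean;
#' binomial: seeded coin flips) and against the reference configuration.
#'
#' @param cohort a `"vx_cohort"` with a gaussian or binomial outcome.
#' @param configs named list of [voxelsurv_config()]s.
#' @param reference index or name of the reference configuration.
#' @return class `"vx_comparison"`: a data frame with one row per
#'   configuration (metric, `p_vs_null`, `p_vs_reference`), plus the
#'   underlying `"voxelsurv_cv"` objects.
#' @export
run_setting_comparison <- function(cohort, configs, reference = 1) {
  stopifnot(length(configs) >= 1)
  fam <- configs[[1]]$family
  if (!fam %in% c("gaussian", "binomial"))
    stop("setting comparison is defined for gaussian/binomial outcomes")
  same <- vapply(configs, function(cf)
    cf$family == fam && cf$n_folds == configs[[1]]$n_folds &&
      cf$seed == configs[[1]]$seed, logical(1))
  if (!all(same)) stop("configs must share family, n_folds and seed")
  cvs <- lapply(configs, function(cf) run_cv(cohort, cf))
  ref <- if (is.character(reference)) match(reference, names(configs))
         else reference
  ids <- lapply(cvs, function(cv) cv$subject_ids[cv$used])
  if (length(unique(vapply(ids, hash_of, character(1)))) != 1)
    stop("evaluated subjects differ across configs; pairing broken")
  errs <- lapply(cvs, cv_abs_errors)
  o <- cvs[[1]]$outcome
  null_err <- if (fam == "gaussian") {
    np <- rep(NA_real_, length(o$y))
    for (f in seq_len(cvs[[1]]$plan$k)) {
      te <- which(cvs[[1]]$fold == f)
      np[te] <- mean(o$y[-te])
    }
    abs(o$y - np)
  } else {
    flips <- with_seed(configs[[1]]$seed, rbinom(length(o$y), 1, 0.5))
    as.numeric(flips != o$y)
  }
  metric <- vapply(cvs, function(cv)
    if (fam == "gaussian") cv$evaluation$mae else cv$evaluation$accuracy,
    numeric(1))
  tab <- data.frame(
    config = names(configs) %||% paste0("config", seq_along(configs)),
    metric = metric,
    p_vs_null = vapply(seq_along(cvs), function(i)
      safe_paired_wilcox(errs[[i]], null_err), numeric(1)),
    p_vs_reference = vapply(seq_along(cvs), function(i)
      if (i == ref) NA_real_
      else safe_paired_wilcox(errs[[i]], errs[[ref]]), numeric(1)),
    row.names = NULL)
  names(tab)[2] <- if (fam == "gaussian") "mae" else "accuracy"
  structure(list(table = tab, reference = ref, family = fam, cvs = cvs),
            class = "vx_comparison")
}

#' @export
print.vx_comparison <- function(x, ...) {
  cat("Paired setting comparison (", x$family, "), reference = ",
      x$table$config[x$reference], "\n", sep = "")
  print(x$table, digits = 3)
  invisible(x)
}
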