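# L1-penalized regression (lasso) for gaussian, binomial and right-censored
# Cox families, solved by cyclic coordinate descent on the IRLS quadratic
# approximation with soft-thresholding and warm starts (compiled core in
# src/lasso.cpp).  Features are standardized internally (mean 0, SD 1 with
# the 1/n variance convention); coefficients are reported on the original
# scale.  The Cox objective is -(2/n) * Breslow log partial likelihood +
# lambda * ||beta||_1; gaussian and binomial use (1/(2n)) RSS and -(1/n)
# log-likelihood respectively, each with an unpenalized intercept (no
# intercept for Cox).

# Precompute sorted order and Breslow tie groups for a survival outcome.
cox_layout <- function(time, event) {
  ord <- order(time, -event)
  t_s <- time[ord]
  d_s <- event[ord]
  ut <- unique(t_s)
  grp <- match(t_s, ut) - 1L                       # 0-based tie group
  gstart <- match(ut, t_s) - 1L                    # first position per group
  gd <- as.numeric(tapply(d_s, factor(t_s, levels = ut), sum))
  list(ord = ord, d = d_s, grp = grp, gstart = gstart, gd = gd)
}

# Breslow log partial likelihood at linear predictor eta.
breslow_pll <- function(eta, time, event) {
  lay <- cox_layout(time, event)
  .cox_pll(eta[lay$ord], lay$d, lay$grp, lay$gstart, lay$gd)
}

# Gradient of the smooth part of the objective w.r.t. original-scale beta,
# evaluated on standardized X.  Used for lambda_max and KKT checks.
lasso_gradient <- function(xs, outcome, eta, b0 = 0) {
  n <- nrow(xs)
  if (outcome$family == "gaussian") {
    drop(crossprod(xs, (eta + b0) - outcome$y)) / n
  } else if (outcome$family == "binomial") {
    p <- 1 / (1 + exp(-(eta + b0)))
    drop(crossprod(xs, p - outcome$y)) / n
  } else {
    lay <- cox_layout(outcome$time, outcome$event)
    es <- exp(eta[lay$ord] - max(eta))
    S0 <- rev(cumsum(rev(es)))[lay$gstart + 1L]
    inc <- ifelse(lay$gd > 0, lay$gd / S0, 0)
    A <- cumsum(inc)[lay$grp + 1L]
    mu <- es * A
    g_eta <- -(2 / n) * (lay$d - mu)
    drop(crossprod(xs[lay$ord, , drop = FALSE], g_eta))
  }
}

#' Fit an L1-penalized regression path
#'
#' Computes the lasso coefficient path over a decreasing, log-spaced grid of
#' regularization parameters, from `lambda_max` (the smallest value at which
#' all coefficients are zero) down to a fraction of it, with warm starts.
#'
#' @param x numeric matrix, subjects in rows.  Standardized internally;
#'   coefficients are returned on the original scale.
#' @param y outcome accepted by [as_vx_outcome()].
#' @param family `"gaussian"`, `"binomial"` or `"survival"`/`"cox"`;
#'   inferred from `y` when omitted.
#' @param lambda optional user grid (decreasing).  Defaults to 100 log-spaced
#'   values from `lambda_max` down to `0.01 * lambda_max` (`0.05` when
#'   `n < p`).
#' @param nlambda,lambda_min_ratio grid controls when `lambda` is `NULL`.
#' @param tol convergence tolerance: maximum absolute coefficient change on
#'   the standardized scale.
#' @param max_cycles per-lambda budget of coordinate-descent cycles.
#' @return an object of class `"vx_lasso_path"` with elements `lambda`,
#'   `beta` (p x nlambda, original scale), `a0` (intercepts; zero for Cox),
#'   `df` (nonzero counts), `family`, and standardization info.
#' @export
lasso_fit <- function(x, y, family = NULL, lambda = NULL, nlambda = 100,
                      lambda_min_ratio = NULL, tol = 1e-7,
                      max_cycles = 5000) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("x contains non-finite values")
  outcome <- as_vx_outcome(y, family)
  n <- nrow(x); p <- ncol(x)
  if (n < 10) stop("need at least 10 observations")
  if (vx_outcome_n(outcome) != n) stop("x and outcome size mismatch")
  if (outcome$family == "survival" && sum(outcome$event) < 2)
    stop("Cox fit needs at least 2 events")

  xm <- colMeans(x)
  xs_sd <- sqrt(colMeans(x^2) - xm^2)
  active_cols <- which(xs_sd > 1e-12)
  if (length(active_cols) == 0) stop("all columns are constant")
  xs <- sweep(sweep(x[, active_cols, drop = FALSE], 2, xm[active_cols]),
              2, xs_sd[active_cols], "/")

  # lambda_max: max abs gradient of the smooth loss at beta = 0
  g0 <- abs(lasso_gradient(xs, outcome, rep(0, n),
                           b0 = null_intercept(outcome)))
  lambda_max <- max(g0)
  if (is.null(lambda)) {
    if (is.null(lambda_min_ratio))
      lambda_min_ratio <- if (n < length(active_cols)) 0.05 else 0.01
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  } else {
    lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  }

  fit <- switch(outcome$family,
    gaussian = .cd_gaussian(xs, outcome$y - mean(outcome$y), lambda,
                            tol, max_cycles),
    binomial = .cd_binomial(xs, outcome$y, lambda, tol, max_cycles),
    survival = {
      lay <- cox_layout(outcome$time, outcome$event)
      .cd_cox(xs[lay$ord, , drop = FALSE], lay$d, lay$grp, lay$gstart,
              lay$gd, lambda, tol, max_cycles)
    })

  # early path termination in the solver may have truncated the grid
  nused <- fit$nused %||% length(lambda)
  if (nused < length(lambda)) {
    lambda <- lambda[seq_len(nused)]
    fit$beta <- fit$beta[, seq_len(nused), drop = FALSE]
    if (!is.null(fit$b0)) fit$b0 <- fit$b0[seq_len(nused)]
    fit$cycles <- fit$cycles[seq_len(nused)]
  }
  nl <- length(lambda)
  beta <- matrix(0, p, nl,
                 dimnames = list(colnames(x) %||% paste0("x", seq_len(p)),
                                 NULL))
  beta[active_cols, ] <- fit$beta / xs_sd[active_cols]
  a0 <- switch(outcome$family,
    gaussian = mean(outcome$y) - drop(crossprod(xm, beta)),
    binomial = drop(fit$b0) - drop(crossprod(xm[active_cols],
                      fit$beta / xs_sd[active_cols])),
    survival = rep(0, nl))
  structure(list(lambda = lambda, lambda_max = lambda_max, beta = beta,
                 a0 = a0, df = colSums(beta != 0), family = outcome$family,
                 center = xm, scale = xs_sd, dropped = setdiff(seq_len(p),
                 active_cols), cycles = fit$cycles, n = n),
            class = "vx_lasso_path")
}

null_intercept <- function(outcome) {
  switch(outcome$family,
         gaussian = 0,                       # y is centered internally
         binomial = stats::qlogis(mean(outcome$y)),
         survival = 0)
}

#' @export
print.vx_lasso_path <- function(x, ...) {
  cat("L1-penalized", x$family, "path:", length(x$lambda), "lambdas,",
      nrow(x$beta), "features, df range", min(x$df), "-", max(x$df), "\n")
  invisible(x)
}

#' Linear predictors along a lasso path
#'
#' @param object a `"vx_lasso_path"`.
#' @param newx feature matrix on the original scale.
#' @param lambda optional single lambda; defaults to the full grid.  Must be
#'   one of the fitted grid values.
#' @param ... unused.
#' @return matrix of linear predictors (including the intercept for
#'   gaussian/binomial), columns indexed by lambda.
#' @export
predict.vx_lasso_path <- function(object, newx, lambda = NULL, ...) {
  newx <- as.matrix(newx)
  idx <- if (is.null(lambda)) seq_along(object$lambda) else {
    i <- which.min(abs(object$lambda - lambda))
    if (abs(object$lambda[i] - lambda) > 1e-8 * max(1, lambda))
      stop("lambda not on the fitted grid")
    i
  }
  eta <- newx %*% object$beta[, idx, drop = FALSE]
  sweep(eta, 2, object$a0[idx], "+")
}

# Held-out deviance of a fitted path; for Cox uses the Verweij-van
# Houwelingen partial-likelihood deviance (full-data pll minus training pll).
path_cv_deviance <- function(path, x, outcome, test_idx) {
  nl <- length(path$lambda)
  if (outcome$family == "gaussian") {
    eta <- predict(path, x[test_idx, , drop = FALSE])
    colSums((outcome$y[test_idx] - eta)^2)
  } else if (outcome$family == "binomial") {
    eta <- predict(path, x[test_idx, , drop = FALSE])
    yk <- outcome$y[test_idx]
    p <- 1 / (1 + exp(-eta))
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -2 * colSums(yk * log(p) + (1 - yk) * log(1 - p))
  } else {
    eta_all <- as.matrix(x) %*% path$beta
    train_idx <- setdiff(seq_len(nrow(x)), test_idx)
    lay_full <- cox_layout(outcome$time, outcome$event)
    lay_tr <- cox_layout(outcome$time[train_idx], outcome$event[train_idx])
    vapply(seq_len(nl), function(l) {
      ll_full <- .cox_pll(eta_all[lay_full$ord, l], lay_full$d,
                          lay_full$grp, lay_full$gstart, lay_full$gd)
      eta_tr <- eta_all[train_idx, l]
      ll_train <- .cox_pll(eta_tr[lay_tr$ord], lay_tr$d, lay_tr$grp,
                           lay_tr$gstart, lay_tr$gd)
      -2 * (ll_full - ll_train)
    }, numeric(1))
  }
}

#' Select the penalty by internal cross-validation
#'
#' Chooses the regularization parameter minimizing the mean cross-validated
#' deviance: mean squared error (gaussian), binomial deviance, or the
#' Verweij-van Houwelingen partial-likelihood deviance (Cox).  Inner folds
#' are event-stratified for survival outcomes.  Deterministic given `seed`.
#'
#' @inheritParams lasso_fit
#' @param nfolds number of inner folds (default 10); reduced automatically
#'   (with a note) when there are fewer events than folds.
#' @param seed integer seed for the fold assignment.
#' @param lambda_rule `"min"` (deviance-minimizing, default) or `"1se"`.
#' @return class `"vx_lasso_cv"`: the full-data `path`, `lambda` grid, `cvm`
#'   (mean deviance), `cvsd`, `lambda_min`, `lambda_1se`, and `lambda_sel`.
#' @export
lasso_select_lambda <- function(x, y, family = NULL, nfolds = 10, seed = 1,
                                lambda_rule = c("min", "1se"), ...) {
  lambda_rule <- match.arg(lambda_rule)
  x <- as.matrix(x)
  outcome <- as_vx_outcome(y, family)
  n <- nrow(x)
  path <- lasso_fit(x, outcome, ...)
  if (outcome$family == "survival") {
    ne <- sum(outcome$event)
    if (ne < 4) stop("too few events for internal cross-validation")
    if (ne < 2 * nfolds) {
      # keep >= ~2 events per training split so every inner fit is defined
      nfolds <- max(2L, as.integer(floor(ne / 2)))
      vx_note("reduced inner folds to ", nfolds, " (", ne, " events)")
    }
  }
  nfolds <- min(nfolds, n)
  plan <- make_folds(outcome, k = nfolds, seed = seed)
  dev <- matrix(NA_real_, nfolds, length(path$lambda))
  for (k in seq_len(nfolds)) {
    test_idx <- which(plan$fold == k)
    train_idx <- setdiff(seq_len(n), test_idx)
    otr <- subset_outcome(outcome, train_idx)
    fit_k <- lasso_fit(x[train_idx, , drop = FALSE], otr,
                       lambda = path$lambda, ...)
    nk <- length(fit_k$lambda)  # fold path may terminate earlier
    dev[k, seq_len(nk)] <- path_cv_deviance(fit_k, x, outcome, test_idx) /
      length(test_idx)
  }
  # restrict selection to the grid prefix every fold evaluated
  nl_common <- min(apply(dev, 1, function(r) sum(!is.na(r))))
  dev <- dev[, seq_len(nl_common), drop = FALSE]
  cvm <- colMeans(dev)
  cvsd <- apply(dev, 2, sd) / sqrt(nfolds)
  i_min <- which.min(cvm)
  i_1se <- min(which(cvm <= cvm[i_min] + cvsd[i_min]))
  sel <- if (lambda_rule == "min") path$lambda[i_min] else path$lambda[i_1se]
  structure(list(path = path, lambda = path$lambda, cvm = cvm, cvsd = cvsd,
                 lambda_min = path$lambda[i_min],
                 lambda_1se = path$lambda[i_1se], lambda_sel = sel,
                 nfolds = nfolds, family = outcome$family),
            class = "vx_lasso_cv")
}

#' @export
print.vx_lasso_cv <- function(x, ...) {
  cat("Cross-validated lasso (", x$family, "): lambda_min = ",
      signif(x$lambda_min, 4), ", lambda_1se = ", signif(x$lambda_1se, 4),
      ", selected = ", signif(x$lambda_sel, 4), "\n", sep = "")
  invisible(x)
}

subset_outcome <- function(outcome, idx) {
  o <- outcome
  if (o$family == "survival") {
    o$time <- o$time[idx]; o$event <- o$event[idx]
  } else o$y <- o$y[idx]
  o
}

# Maximum KKT violation at a path solution for a given lambda index:
# |grad_j| <= lambda for zero coefficients, grad_j = -lambda * sign(beta_j)
# for nonzero ones (standardized scale).
lasso_kkt_violation <- function(path, x, y, index) {
  outcome <- as_vx_outcome(y, path$family)
  x <- as.matrix(x)
  keep <- setdiff(seq_len(ncol(x)), path$dropped)
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, path$center[keep]),
              2, path$scale[keep], "/")
  b_std <- path$beta[keep, index] * path$scale[keep]
  eta <- drop(xs %*% b_std)
  b0 <- if (path$family == "binomial") {
    path$a0[index] + sum(path$beta[keep, index] * path$center[keep])
  } else if (path$family == "gaussian") {
    # internal parametrization: y centered, xs standardized
    0
  } else 0
  out_int <- outcome
  if (path$family == "gaussian") out_int$y <- outcome$y - mean(outcome$y)
  g <- lasso_gradient(xs, out_int, eta, b0 = b0)
  lam <- path$lambda[index]
  viol_zero <- max(c(0, abs(g[b_std == 0]) - lam))
  viol_nz <- if (any(b_std != 0)) {
    max(abs(g[b_std != 0] + lam * sign(b_std[b_std != 0])))
  } else 0
  max(viol_zero, viol_nz)
}
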