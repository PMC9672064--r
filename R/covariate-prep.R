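# Train-frozen removal of age/sex effects from voxel features (per-feature
# OLS) and [0,1] min-max scaling of clinical variables.  Both transforms
# are estimated on training subjects only and applied as pure functions to
# held-out subjects.

#' Fit per-feature age/sex residualization on training subjects
#'
#' Ordinary least squares of each feature on `1 + age + sex`.  A collinear
#' column (all subjects the same sex, or a single distinct age) is dropped
#' from the design with a note; its slope is recorded as zero.
#'
#' @param train_features numeric matrix, training subjects in rows.
#' @param age numeric; `sex` binary-coded (0/1).
#' @param sex see above.
#' @return class `"vx_resid_params"`: per-feature `intercept`, `b_age`,
#'   `b_sex`.
#' @export
residualize_fit <- function(train_features, age, sex) {
  x <- as.matrix(train_features)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 training subjects")
  stopifnot(length(age) == n, length(sex) == n, all(sex %in% c(0, 1)))
  D <- cbind(intercept = 1, age = age, sex = sex)
  keep <- c(TRUE, var(age) > 0, var(sex) > 0)
  if (!all(keep))
    vx_note("collinear residualization column(s) dropped: ",
            paste(colnames(D)[!keep], collapse = ", "))
  fit <- lm.fit(D[, keep, drop = FALSE], x)
  coefs <- matrix(0, 3, ncol(x), dimnames = list(colnames(D), NULL))
  coefs[keep, ] <- fit$coefficients
  if (!all(is.finite(coefs))) stop("non-finite residualization coefficients")
  structure(list(intercept = coefs["intercept", ], b_age = coefs["age", ],
                 b_sex = coefs["sex", ], n_features = ncol(x)),
            class = "vx_resid_params")
}

#' Apply frozen residualization parameters
#'
#' Subtracts `intercept + b_age * age + b_sex * sex` per feature using the
#' training-fitted coefficients; defined (by linear extrapolation) for any
#' age.  Pure function.
#'
#' @param features numeric matrix.
#' @param age,sex covariates of the subjects being transformed.
#' @param params a `"vx_resid_params"`.
#' @return residualized matrix.
#' @export
residualize_apply <- function(features, age, sex, params) {
  stopifnot(inherits(params, "vx_resid_params"))
  x <- as.matrix(features)
  if (ncol(x) != params$n_features) stop("feature count mismatch")
  pred <- outer(rep(1, nrow(x)), params$intercept) +
    outer(age, params$b_age) + outer(sex, params$b_sex)
  x - pred
}

#' Fit min-max scaling of clinical variables to the unit interval
#'
#' Records the per-variable training minimum and maximum.  Constant columns
#' are flagged and dropped (with a note).  Categorical variables must be
#' pre-expanded to one-hot indicators; binary flags pass through unchanged
#' (min 0, max 1).
#'
#' @param train_clinical numeric data frame or matrix of clinical
#'   variables.
#' @return class `"vx_scale_params"`: `min`, `max`, kept variable names,
#'   dropped constant names.
#' @export
scale_clinical_fit <- function(train_clinical) {
  x <- as.matrix(train_clinical)
  if (!is.numeric(x)) stop("clinical variables must be numeric")
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  const <- maxs - mins <= 0
  if (any(const))
    vx_note("constant clinical column(s) dropped: ",
            paste(colnames(x)[const], collapse = ", "))
  structure(list(min = mins[!const], max = maxs[!const],
                 vars = colnames(x)[!const],
                 dropped = colnames(x)[const]),
            class = "vx_scale_params")
}

#' Apply frozen clinical scaling
#'
#' `(x - min_train) / (max_train - min_train)`.  Held-out values outside
#' the training range map outside [0,1] (an honest out-of-range signal,
#' noted); only values beyond the [-0.5, 1.5] guard range are clipped to
#' it.
#'
#' @param clinical numeric data frame or matrix containing (at least) the
#'   fitted variables.
#' @param params a `"vx_scale_params"`.
#' @return scaled matrix restricted to the fitted variables, in fit order.
#' @export
scale_clinical_apply <- function(clinical, params) {
  stopifnot(inherits(params, "vx_scale_params"))
  x <- as.matrix(clinical)
  miss <- setdiff(params$vars, colnames(x))
  if (length(miss))
    stop("clinical variable(s) missing: ", paste(miss, collapse = ", "))
  x <- x[, params$vars, drop = FALSE]
  sc <- sweep(sweep(x, 2, params$min), 2, params$max - params$min, "/")
  out_of_range <- sc < 0 | sc > 1
  if (any(out_of_range))
    vx_note(sum(out_of_range), " clinical value(s) outside the training ",
            "[0,1] range")
  guard <- sc < -0.5 | sc > 1.5
  if (any(guard)) {
    vx_note(sum(guard), " clinical value(s) clipped to the [-0.5, 1.5] ",
            "guard range")
    sc <- pmin(pmax(sc, -0.5), 1.5)
  }
  sc
}
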