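# Empirical-Bayes location/scale batch-effect harmonization (ComBat,
# parametric priors), split into a fit step that sees only training
# subjects and a pure apply step that transforms any subject of a known
# site with the frozen parameters.
#
# Model per feature g and site s:  x = alpha_g + C beta_g + gamma_sg +
# delta_sg * eps.  Features are standardized by the fitted grand mean,
# covariate effects and pooled SD; per-site location/scale estimates are
# shrunk by parametric empirical Bayes (normal prior on location,
# inverse-gamma on scale) with the standard iterative conditional solution.

#' Estimate harmonization parameters on training subjects
#'
#' @param train_features numeric matrix, training subjects in rows.
#' @param site_labels per-subject site labels (>= 2 sites with >= 2
#'   subjects each; a single site yields identity parameters with a
#'   warning).
#' @param covariates optional numeric matrix of covariates whose effects
#'   are preserved by the harmonization (none by default; age/sex are
#'   handled by the separate residualization step).
#' @param tol relative-change convergence threshold of the EB iteration.
#' @param max_iter iteration cap.
#' @param delta_floor lower bound for the multiplicative effect, guarding
#'   degenerate sites with zero within-site variance.
#' @return class `"vx_combat_params"`: grand intercept and covariate slopes
#'   per feature, pooled variance, per-site EB-shrunken additive
#'   (`gamma_star`) and multiplicative (`delta_star`, SD scale) effects,
#'   and the site roster.
#' @export
combat_fit <- function(train_features, site_labels, covariates = NULL,
                       tol = 1e-6, max_iter = 500, delta_floor = 1e-8) {
  x <- as.matrix(train_features)
  n <- nrow(x); p <- ncol(x)
  site <- droplevels(factor(site_labels))
  if (length(site) != n) stop("site_labels length mismatch")
  if (nlevels(site) < 2) {
    warning("single site: harmonization parameters are the identity")
    return(structure(list(identity = TRUE, sites = levels(site),
                          n_features = p),
                     class = "vx_combat_params"))
  }
  if (any(table(site) < 2)) stop("every training site needs >= 2 subjects")
  D_site <- stats::model.matrix(~ site - 1)
  D <- if (is.null(covariates)) D_site else cbind(D_site,
                                                  as.matrix(covariates))
  ncov <- ncol(D) - nlevels(site)
  B <- solve(crossprod(D), crossprod(D, x))       # (sites+cov) x p
  n_s <- as.numeric(table(site))
  alpha <- drop(crossprod(n_s / n, B[seq_len(nlevels(site)), , drop = FALSE]))
  beta_cov <- if (ncov > 0) B[-seq_len(nlevels(site)), , drop = FALSE]
              else NULL
  fitted_full <- D %*% B
  var_pooled <- colMeans((x - fitted_full)^2)
  var_pooled <- pmax(var_pooled, 1e-20)
  stand_mean <- matrix(alpha, n, p, byrow = TRUE)
  if (ncov > 0)
    stand_mean <- stand_mean + as.matrix(covariates) %*% beta_cov
  z <- (x - stand_mean) / matrix(sqrt(var_pooled), n, p, byrow = TRUE)

  gamma_star <- delta2_star <- matrix(NA_real_, nlevels(site), p,
                                      dimnames = list(levels(site), NULL))
  for (si in seq_len(nlevels(site))) {
    rows <- which(site == levels(site)[si])
    zs <- z[rows, , drop = FALSE]
    ns <- length(rows)
    g_hat <- colMeans(zs)
    d_hat <- apply(zs, 2, var)
    # parametric prior hyper-estimates (method of moments)
    g_bar <- mean(g_hat); t2 <- var(g_hat)
    m_d <- mean(d_hat); s2_d <- var(d_hat)
    a_prior <- (2 * s2_d + m_d^2) / s2_d
    b_prior <- (m_d * s2_d + m_d^3) / s2_d
    g_old <- g_hat; d_old <- d_hat
    for (it in seq_len(max_iter)) {
      g_new <- (t2 * ns * g_hat + d_old * g_bar) / (t2 * ns + d_old)
      sum2 <- colSums(sweep(zs, 2, g_new)^2)
      d_new <- (0.5 * sum2 + b_prior) / (ns / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
      g_old <- g_new; d_old <- d_new
      if (change < tol) break
    }
    if (any(d_old < delta_floor^2)) {
      vx_note("delta floored at site ", levels(site)[si])
      d_old <- pmax(d_old, delta_floor^2)
    }
    gamma_star[si, ] <- g_old
    delta2_star[si, ] <- d_old
  }
  structure(list(identity = FALSE, sites = levels(site),
                 alpha = alpha, beta_cov = beta_cov,
                 var_pooled = var_pooled, gamma_star = gamma_star,
                 delta_star = sqrt(delta2_star), n_features = p,
                 has_covariates = ncov > 0),
            class = "vx_combat_params")
}

#' Apply frozen harmonization parameters
#'
#' Standardizes with the training grand mean, covariate effects and pooled
#' SD, removes the site's shrunken location/scale effect
#' (`(z - gamma*) / delta*`), and de-standardizes.  A pure function of its
#' inputs: nothing is re-estimated.
#'
#' @param features numeric matrix (any subjects, training or held-out).
#' @param site_labels per-subject sites; every label must be in the
#'   training roster (unseen sites are an error, never passed through).
#' @param params a `"vx_combat_params"`.
#' @param covariates required iff the fit used covariates.
#' @return harmonized matrix of the same shape.
#' @export
combat_apply <- function(features, site_labels, params, covariates = NULL) {
  stopifnot(inherits(params, "vx_combat_params"))
  x <- as.matrix(features)
  if (isTRUE(params$identity)) return(x)
  if (ncol(x) != params$n_features) stop("feature count mismatch")
  site <- as.character(site_labels)
  unseen <- setdiff(unique(site), params$sites)
  if (length(unseen))
    stop("site(s) not in the harmonization roster: ",
         paste(unseen, collapse = ", "))
  if (params$has_covariates && is.null(covariates))
    stop("fit used covariates; supply them")
  n <- nrow(x); p <- ncol(x)
  stand_mean <- matrix(params$alpha, n, p, byrow = TRUE)
  if (params$has_covariates)
    stand_mean <- stand_mean + as.matrix(covariates) %*% params$beta_cov
  sdm <- matrix(sqrt(params$var_pooled), n, p, byrow = TRUE)
  z <- (x - stand_mean) / sdm
  si <- match(site, params$sites)
  z_adj <- (z - params$gamma_star[si, , drop = FALSE]) /
    params$delta_star[si, , drop = FALSE]
  z_adj * sdm + stand_mean
}

#' Serialize harmonization parameters to JSON
#'
#' @param params a `"vx_combat_params"`.
#' @param path optional file path; when omitted the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
combat_params_to_json <- function(params, path = NULL) {
  obj <- unclass(params)
  obj$schema <- "vx_combat_params/1"
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname combat_params_to_json
#' @param json JSON string or file path to read back.
#' @export
combat_params_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  if (!identical(obj$schema, "vx_combat_params/1"))
    stop("unrecognized harmonization parameter schema")
  obj$schema <- NULL
  for (f in c("gamma_star", "delta_star"))
    if (!is.null(obj[[f]])) obj[[f]] <- as.matrix(obj[[f]])
  structure(obj, class = "vx_combat_params")
}
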