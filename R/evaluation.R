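# Validation of risk estimates: site-aware Cox comparison of risk groups,
# Kaplan-Meier curves, univariate voxelwise survival maps, and
# Schoenfeld-approximation power calculations.

# Vectorized per-column Cox score test at beta = 0 (Breslow ties):
# U_j = sum over events of (x_ij - riskset mean), V_j = sum over event times
# of D * (riskset mean of x^2 - squared riskset mean); z = U / sqrt(V).
# Columns with zero variance get NA.
cox_score_z <- function(x, time, event) {
  x <- as.matrix(x)
  n <- nrow(x)
  ord <- order(time, -event)
  xs <- x[ord, , drop = FALSE]
  t_s <- time[ord]; d_s <- event[ord]
  ut <- unique(t_s)
  gstart <- match(ut, t_s)
  # reverse cumulative sums -> risk-set sums at each group start
  rc1 <- apply(xs[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
  rc2 <- apply(xs[n:1, , drop = FALSE]^2, 2, cumsum)[n:1, , drop = FALSE]
  atrisk <- n - gstart + 1
  D <- as.numeric(tapply(d_s, factor(t_s, levels = ut), sum))
  ev_groups <- which(D > 0)
  m1 <- rc1[gstart[ev_groups], , drop = FALSE] / atrisk[ev_groups]
  m2 <- rc2[gstart[ev_groups], , drop = FALSE] / atrisk[ev_groups]
  # per-group sum of x over events
  gx <- rowsum(xs * d_s, group = match(t_s, ut))[ev_groups, , drop = FALSE]
  U <- colSums(gx - D[ev_groups] * m1)
  V <- colSums(D[ev_groups] * (m2 - m1^2))
  z <- ifelse(V > 1e-12, U / sqrt(V), NA_real_)
  unname(z)
}

#' Univariate voxelwise survival map
#'
#' Per-voxel Cox score test (score statistic over root information at
#' beta = 0, Breslow ties), signed by the direction of association; a
#' threshold mask marks voxels with two-sided P below `p_threshold`.
#' This routine also backs the univariate screening step.
#'
#' @param features a `"vx_features"` or plain matrix of voxel values.
#' @param time,event right-censored outcome.
#' @param p_threshold uncorrected two-sided threshold (default 0.005).
#' @return class `"vx_voxel_map"`: `z`, `p`, logical `selected`, and the
#'   feature `meta` when available.
#' @export
voxelwise_survival_map <- function(features, time, event,
                                   p_threshold = 0.005) {
  if (sum(event) < 2) stop("need at least 2 events")
  meta <- NULL
  if (inherits(features, "vx_features")) {
    vi <- features$meta$kind == "voxel"
    meta <- features$meta[vi, , drop = FALSE]
    x <- features$values[, vi, drop = FALSE]
  } else x <- as.matrix(features)
  z <- cox_score_z(x, time, event)
  p <- 2 * pnorm(-abs(z))
  excl <- is.na(z)
  if (any(excl)) vx_note(sum(excl), " zero-variance voxels excluded from map")
  structure(list(z = z, p = p, selected = !is.na(p) & p < p_threshold,
                 p_threshold = p_threshold, meta = meta),
            class = "vx_voxel_map")
}

#' @export
print.vx_voxel_map <- function(x, ...) {
  cat("Voxelwise survival map:", length(x$z), "voxels,",
      sum(x$selected), "with P <", x$p_threshold, "\n")
  invisible(x)
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimator with right censoring, one curve per group level,
#' evaluable at any time point.
#'
#' @param time,event right-censored outcome (times > 0).
#' @param group optional grouping factor (single group when omitted).
#' @return class `"vx_km"`: per-group step curves (`time`, `surv`,
#'   `n.risk`, `n.event`) and the underlying [survival::survfit] object.
#' @export
kaplan_meier <- function(time, event, group = NULL) {
  stopifnot(all(time > 0))
  if (is.null(group)) group <- rep("all", length(time))
  group <- factor(group)
  df <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  s <- summary(fit, censored = TRUE)
  gs <- if (is.null(s$strata)) factor(rep(levels(group)[1], length(s$time)))
        else factor(sub("^group=", "", as.character(s$strata)),
                    levels = levels(group))
  curves <- lapply(levels(group), function(g) {
    i <- gs == g
    list(time = s$time[i], surv = s$surv[i], n_risk = s$n.risk[i],
         n_event = s$n.event[i])
  })
  names(curves) <- levels(group)
  structure(list(curves = curves, fit = fit), class = "vx_km")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param km a `"vx_km"`.
#' @param t times at which to evaluate.
#' @param group group label (defaults to the first).
#' @return survival probabilities (right-continuous step function; 1 before
#'   the first event).
#' @export
km_at <- function(km, t, group = names(km$curves)[1]) {
  cv <- km$curves[[group]]
  if (length(cv$time) == 0) return(rep(1, length(t)))
  sf <- stats::stepfun(cv$time, c(1, cv$surv), right = FALSE)
  sf(t)
}

#' @export
plot.vx_km <- function(x, ...) {
  plot(x$fit, mark.time = TRUE, xlab = "Time", ylab = "Survival",
       col = seq_along(x$curves), ...)
  graphics::legend("bottomleft", legend = names(x$curves),
                   col = seq_along(x$curves), lty = 1, bty = "n")
  invisible(x)
}

#' Site-aware Cox comparison of risk groups
#'
#' Cox proportional-hazards regression of the outcome on the estimated risk
#' group with the site as a Gaussian random intercept (penalized partial
#' likelihood).  Falls back to a site-stratified Cox model when there are
#' two or fewer sites or the variance estimate hits the zero boundary, and
#' to a plain Cox model for a single site.
#'
#' @param time,event right-censored outcome.
#' @param risk_group logical or two-level factor (`TRUE`/second level =
#'   high-risk).
#' @param site_labels per-subject site factor.
#' @return class `"vx_risk_group_result"`: `hr`, `ci` (95%), `z`, `p`,
#'   `beta`, `se`, `site_var`, `method` used, per-group event counts, the
#'   Kaplan-Meier curves, and an `unstable` flag.
#' @export
risk_group_cox <- function(time, event, risk_group, site_labels = NULL) {
  if (sum(event) < 2) stop("need at least 2 events")
  grp <- if (is.logical(risk_group)) factor(risk_group, c(FALSE, TRUE),
                                            c("low", "HRR"))
         else factor(risk_group)
  if (nlevels(grp) != 2 || any(table(grp) == 0))
    stop("both risk groups must be non-empty")
  if (is.null(site_labels)) site_labels <- rep("site1", length(time))
  site <- factor(droplevels(factor(site_labels)))
  df <- data.frame(time = time, event = event, grp = grp, site = site)
  method <- NULL; site_var <- 0
  fit <- NULL
  if (nlevels(site) > 2) {
    fit <- tryCatch(
      suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ grp +
                          survival::frailty.gaussian(site), data = df,
                        ties = "breslow")),
      error = function(e) NULL)
    if (!is.null(fit)) {
      hist <- fit$history[[1]]
      site_var <- tail_theta(hist)
      if (is.na(site_var) || site_var < 1e-8) {
        vx_note("site variance at zero boundary; using stratified Cox")
        fit <- NULL
      } else method <- "random_intercept"
    }
  }
  # degenerate groupings (all events on one side) make the Newton steps
  # diverge; the warning is absorbed and surfaced via the `unstable` flag
  if (is.null(fit) && nlevels(site) >= 2) {
    fit <- suppressWarnings(
      survival::coxph(survival::Surv(time, event) ~ grp +
                        survival::strata(site), data = df,
                      ties = "breslow"))
    method <- "stratified"
  }
  if (is.null(fit)) {
    fit <- suppressWarnings(
      survival::coxph(survival::Surv(time, event) ~ grp, data = df,
                      ties = "breslow"))
    method <- "plain"
  }
  beta <- unname(fit$coefficients["grpHRR"])
  se <- sqrt(fit$var[1, 1])
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  ev <- tapply(event, grp, sum)
  unstable <- !is.finite(beta) || abs(beta) > 10 || se > 10 ||
    any(ev == 0)
  structure(list(hr = exp(beta), ci = exp(beta + c(-1, 1) * qnorm(0.975) *
                                            se),
                 z = z, p = p, beta = beta, se = se, site_var = site_var,
                 method = method, events_by_group = ev,
                 km = kaplan_meier(time, event, grp), unstable = unstable),
            class = "vx_risk_group_result")
}

tail_theta <- function(hist) {
  th <- hist$theta
  if (is.null(th)) return(NA_real_)
  as.numeric(th[length(th)])
}

#' @export
print.vx_risk_group_result <- function(x, ...) {
  cat(sprintf(
    "Risk-group Cox (%s): HR = %.2f (95%% CI %.2f-%.2f), Z = %.2f, P = %.3g\n",
    x$method, x$hr, x$ci[1], x$ci[2], x$z, x$p))
  cat("Events: low =", x$events_by_group[["low"]],
      ", HRR =", x$events_by_group[["HRR"]],
      "; site variance =", signif(x$site_var, 3), "\n")
  if (x$unstable) cat("Note: estimate flagged unstable\n")
  invisible(x)
}

#' Survival power and required events (Schoenfeld approximation)
#'
#' `power_events()` gives the power to detect a hazard ratio `hr` with
#' `n_events` observed events when a fraction `prop_exposed` of subjects is
#' in the exposed group:
#' `power = Phi(sqrt(E p (1-p)) |log hr| - z_{1-alpha/2})`.
#' `events_required()` inverts it.  This is the standard approximation; it
#' need not coincide with other software's variants.
#'
#' @param hr hazard ratio (> 0; != 1 for `events_required`).
#' @param n_events number of observed events.
#' @param prop_exposed exposed-group fraction in (0, 1).
#' @param alpha two-sided type-I error.
#' @return `power_events`: power in (0, 1); `events_required`: integer
#'   event count.
#' @export
power_events <- function(hr, n_events, prop_exposed = 0.5, alpha = 0.05) {
  stopifnot(hr > 0, prop_exposed > 0, prop_exposed < 1)
  pnorm(sqrt(n_events * prop_exposed * (1 - prop_exposed)) * abs(log(hr)) -
          qnorm(1 - alpha / 2))
}

#' @rdname power_events
#' @param power target power in (0, 1).
#' @export
events_required <- function(hr, power = 0.8, prop_exposed = 0.5,
                            alpha = 0.05) {
  stopifnot(hr > 0, prop_exposed > 0, prop_exposed < 1)
  if (hr == 1) stop("events_required is infinite at hr = 1")
  ceiling((qnorm(1 - alpha / 2) + qnorm(power))^2 /
            (prop_exposed * (1 - prop_exposed) * log(hr)^2))
}
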