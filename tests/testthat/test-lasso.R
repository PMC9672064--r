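# Penalized regression: analytic and reference-implementation oracles,
# KKT optimality, and penalty selection behavior.

test_that("orthonormal-design gaussian lasso equals closed-form soft-thresholding", {
  n <- 64; p <- 6
  X <- ortho_design(n, p)
  set.seed(3)
  y <- drop(X %*% c(2, -1, 0.5, 0, 0, 0)) + rnorm(n)
  rho <- drop(crossprod(X, y - mean(y))) / n     # OLS coefs under X'X = nI
  for (lam in c(0.05, 0.3, 0.8)) {
    fit <- lasso_fit(X, y, family = "gaussian", lambda = lam, tol = 1e-10)
    expected <- sign(rho) * pmax(abs(rho) - lam, 0)
    expect_equal(unname(fit$beta[, 1]), expected, tolerance = 1e-7)
  }
})

test_that("lambda = 0 fits match unpenalized Newton/IRLS oracles", {
  d <- sim_surv(n = 50, p = 3, beta = c(0.8, -0.5, 0), seed = 11)
  # gaussian vs lm
  set.seed(4)
  yg <- drop(d$X %*% c(1, -1, 0.5)) + rnorm(50)
  fg <- lasso_fit(d$X, yg, family = "gaussian", lambda = c(1, 0),
                  tol = 1e-10)
  ols <- coef(lm(yg ~ d$X))
  expect_lt(max(abs(fg$beta[, 2] - ols[-1])), 1e-4)
  expect_lt(abs(fg$a0[2] - ols[1]), 1e-4)
  # binomial vs glm
  set.seed(5)
  yb <- rbinom(50, 1, stats::plogis(drop(d$X %*% c(1, -1, 0))))
  fb <- lasso_fit(d$X, yb, family = "binomial", lambda = c(1, 0),
                  tol = 1e-10)
  irls <- coef(glm(yb ~ d$X, family = binomial))
  expect_lt(max(abs(fb$beta[, 2] - irls[-1])), 1e-4)
  # Cox vs coxph (Breslow ties, Newton-Raphson)
  fc <- lasso_fit(d$X, survival::Surv(d$time, d$event), lambda = c(1, 0),
                  tol = 1e-10)
  cph <- survival::coxph(survival::Surv(d$time, d$event) ~ d$X,
                         ties = "breslow")
  expect_lt(max(abs(fc$beta[, 2] - coef(cph))), 1e-4)
})

test_that("paths agree with glmnet (Cox at half lambda for its 1/n scale)", {
  skip_if_not_installed("glmnet")
  set.seed(42)
  n <- 100; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  b <- c(2, -1.5, 1, rep(0, p - 3))
  y <- drop(X %*% b) + rnorm(n)
  fit <- lasso_fit(X, y, family = "gaussian")
  g <- glmnet::glmnet(X, y, lambda = fit$lambda, thresh = 1e-12)
  expect_lt(max(abs(as.matrix(g$beta) - fit$beta)), 1e-5)
  d <- sim_surv(100, 12, b / 4, seed = 9)
  fc <- lasso_fit(d$X, survival::Surv(d$time, d$event), lambda = 0.1,
                  tol = 1e-9)
  gc <- glmnet::glmnet(d$X, survival::Surv(d$time, d$event),
                       family = "cox", lambda = 0.05, thresh = 1e-14)
  expect_lt(max(abs(as.matrix(gc$beta) - fc$beta)), 1e-6)
})

test_that("coefficients are exactly zero at and above lambda_max", {
  set.seed(6)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y <- rnorm(60)
  f <- lasso_fit(X, y, family = "gaussian")
  expect_true(all(f$beta[, 1] == 0))
  f2 <- lasso_fit(X, y, family = "gaussian",
                  lambda = c(2 * f$lambda_max, f$lambda_max))
  expect_true(all(f2$beta == 0))
})

test_that("KKT conditions hold at returned solutions for all families", {
  for (fam in c("gaussian", "binomial", "survival")) {
    d <- sim_surv(n = 80, p = 15, beta = c(1, -1, rep(0, 13)), seed = 21)
    y <- switch(fam,
                gaussian = d$lp + rnorm(80),
                binomial = rbinom(80, 1, stats::plogis(d$lp)),
                survival = survival::Surv(d$time, d$event))
    path <- lasso_fit(d$X, y, family = fam)
    for (i in round(seq(2, length(path$lambda), length.out = 5))) {
      viol <- voxelsurv:::lasso_kkt_violation(path, d$X, y, i)
      expect_lt(viol, 1e-5)
    }
  }
})

test_that("training loss is non-increasing along the path", {
  d <- sim_surv(n = 90, p = 10, seed = 31)
  path <- lasso_fit(d$X, survival::Surv(d$time, d$event))
  eta <- d$X %*% path$beta
  pll <- apply(eta, 2, voxelsurv:::breslow_pll, time = d$time,
               event = d$event)
  loss <- -(2 / 90) * pll
  expect_true(all(diff(loss) < 1e-8))
})

test_that("column rescaling divides the original-scale coefficients", {
  set.seed(8)
  X <- matrix(rnorm(70 * 5), 70, 5)
  y <- drop(X %*% c(1, 1, 0, 0, 0)) + rnorm(70)
  f1 <- lasso_fit(X, y, family = "gaussian", tol = 1e-9)
  X2 <- X; X2[, 2] <- X2[, 2] * 10
  f2 <- lasso_fit(X2, y, family = "gaussian", lambda = f1$lambda,
                  tol = 1e-9)
  expect_equal(f2$beta[2, ], f1$beta[2, ] / 10, tolerance = 1e-8)
  expect_equal(f2$beta[1, ], f1$beta[1, ], tolerance = 1e-8)
})

test_that("penalty selection: pure noise mostly empty, strong signal always kept", {
  empty <- 0
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(rnorm(100 * 50), 100, 50)
    y <- rnorm(100)
    cv <- lasso_select_lambda(X, y, family = "gaussian", nfolds = 5,
                              seed = s)
    i <- which.min(abs(cv$path$lambda - cv$lambda_sel))
    if (sum(cv$path$beta[, i] != 0) == 0) empty <- empty + 1
  }
  expect_gte(empty, 16)   # >= 80% of seeds select the empty model

  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    X <- matrix(rnorm(100 * 10), 100, 10)
    y <- 3 * X[, 1] + rnorm(100)                 # R^2 ~ 0.9
    cv <- lasso_select_lambda(X, y, family = "gaussian", nfolds = 5,
                              seed = s)
    i <- which.min(abs(cv$path$lambda - cv$lambda_sel))
    if (cv$path$beta[1, i] != 0) hits <- hits + 1
  }
  expect_equal(hits, 20)
})

test_that("penalty selection is deterministic given the seed", {
  d <- sim_surv(n = 60, p = 8, seed = 41)
  y <- survival::Surv(d$time, d$event)
  cv1 <- lasso_select_lambda(d$X, y, nfolds = 5, seed = 7)
  cv2 <- lasso_select_lambda(d$X, y, nfolds = 5, seed = 7)
  expect_identical(cv1$lambda_sel, cv2$lambda_sel)
  expect_identical(cv1$cvm, cv2$cvm)
})

test_that("degenerate inputs are rejected", {
  set.seed(9)
  X <- matrix(rnorm(40 * 3), 40, 3)
  expect_error(lasso_fit(X, rexp(40), family = "survival"))  # no events
  Xbad <- X; Xbad[1, 1] <- NA
  expect_error(lasso_fit(Xbad, rnorm(40), family = "gaussian"),
               "non-finite")
  expect_error(lasso_fit(X[1:5, ], rnorm(5), family = "gaussian"),
               "at least 10")
})
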