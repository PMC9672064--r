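# Train-only ComBat harmonization: identity cases, moments oracle,
# reference-implementation equivalence, purity of the apply step.

test_that("single site yields identity harmonization", {
  set.seed(1)
  x <- matrix(rnorm(30 * 5), 30, 5)
  expect_warning(pr <- combat_fit(x, rep("a", 30)), "single site")
  expect_equal(combat_apply(x, rep("a", 30), pr), x)
})

test_that("constant two-site shift: EB locations approach +/- c/2 (moments oracle)", {
  set.seed(2)
  ns <- 400; p <- 50; cshift <- 1.5
  site <- rep(c("a", "b"), each = ns)
  x <- matrix(rnorm(2 * ns * p), 2 * ns, p)
  x[site == "a", ] <- x[site == "a", ] + cshift
  pr <- combat_fit(x, site)
  # moments oracle: per-site mean of standardized data, no shrinkage.
  # EB shrinkage pulls each feature toward the site average, so agreement
  # is within the cross-feature spread of the moment estimates.
  sd_pool <- sqrt(pr$var_pooled)
  zm_a <- colMeans((x[site == "a", ] -
                      matrix(pr$alpha, ns, p, TRUE)) /
                     matrix(sd_pool, ns, p, TRUE))
  expect_lt(max(abs(pr$gamma_star["a", ] - zm_a)), 4 * sd(zm_a))
  expect_equal(mean(pr$gamma_star["a", ]), (cshift / 2) / mean(sd_pool),
               tolerance = 0.05)
  expect_equal(mean(pr$gamma_star["b", ]), -(cshift / 2) / mean(sd_pool),
               tolerance = 0.05)
})

test_that("planted site effects are removed (means and variances)", {
  # per-feature location/scale site effects (the regime empirical Bayes is
  # built for: feature-specific batch effects shrunk across features);
  # shift scale 1 SD, log-scale SD 0.3.  500 subjects per site: at this
  # size the EB scale shrinkage residual falls below the 10% band for
  # >= 95% of features (smaller sites leave a visibly larger residual)
  set.seed(31)
  n <- 1000; p <- 150
  site <- rep(c("site1", "site2"), each = n / 2)
  gamma_true <- matrix(rnorm(2 * p, 0, 1), 2, p)
  delta_true <- matrix(exp(rnorm(2 * p, 0, 0.3)), 2, p)
  x <- matrix(rnorm(n * p), n, p)
  for (s in 1:2) {
    rows <- which(site == paste0("site", s))
    x[rows, ] <- sweep(sweep(x[rows, ], 2, delta_true[s, ], "*"),
                       2, gamma_true[s, ], "+")
  }
  pr <- combat_fit(x, site)
  adj <- combat_apply(x, site, pr)
  m_a <- colMeans(adj[site == "site1", ]); m_b <- colMeans(adj[site == "site2", ])
  sdp <- sqrt(pr$var_pooled)
  expect_lt(unname(stats::quantile(abs(m_a - m_b) / sdp, 0.95)), 0.05)
  v_ratio <- apply(adj[site == "site1", ], 2, var) /
    apply(adj[site == "site2", ], 2, var)
  expect_gte(mean(v_ratio > 0.9 & v_ratio < 1.1), 0.95)
  # sanity: the raw data really carried site effects before correction
  raw_diff <- abs(colMeans(x[site == "site1", ]) -
                    colMeans(x[site == "site2", ]))
  expect_gt(unname(stats::quantile(raw_diff / sdp, 0.95)), 0.5)
})

test_that("fit+apply on training data matches the reference implementation", {
  skip_if_not_installed("sva")
  set.seed(7)
  ns <- 200; p <- 60
  site <- factor(rep(c("a", "b", "c"), each = ns))
  x <- matrix(rnorm(3 * ns * p), 3 * ns, p) +
    outer(as.numeric(site), rep(1, p)) * 0.5
  x <- x * rep(exp(0.3 * as.numeric(site) - 0.6), p)
  pr <- combat_fit(x, site)
  mine <- combat_apply(x, as.character(site), pr)
  ref <- t(suppressMessages(sva::ComBat(dat = t(x), batch = site,
                                        par.prior = TRUE)))
  expect_lt(max(abs(mine - ref)), 1e-6)
})

test_that("apply is linear and rejects unseen sites", {
  set.seed(9)
  site <- rep(c("a", "b"), each = 25)
  x <- matrix(rnorm(50 * 8), 50, 8)
  pr <- combat_fit(x, site)
  xnew <- matrix(rnorm(8), 1, 8)
  base <- combat_apply(xnew, "a", pr)
  pert <- xnew; pert[1, 3] <- pert[1, 3] + 0.1
  out <- combat_apply(pert, "a", pr)
  delta <- out - base
  expect_equal(delta[1, 3], 0.1 / pr$delta_star["a", 3], tolerance = 1e-10)
  expect_true(all(abs(delta[1, -3]) < 1e-12))
  expect_error(combat_apply(xnew, "zz", pr), "roster")
})

test_that("fit output is invariant to held-out subjects (leakage sentinel)", {
  set.seed(10)
  site <- rep(c("a", "b"), each = 30)
  x <- matrix(rnorm(60 * 10), 60, 10)
  train <- 1:40
  pr1 <- combat_fit(x[train, ], site[train])
  x2 <- x; x2[41:60, ] <- 999
  pr2 <- combat_fit(x2[train, ], site[train])
  expect_identical(voxelsurv:::hash_of(pr1), voxelsurv:::hash_of(pr2))
})

test_that("a planted age effect survives fit+apply within 5%", {
  set.seed(12)
  n <- 400; p <- 30; slope <- 0.05
  site <- rep(c("a", "b"), each = n / 2)
  age <- sample(18:60, n, TRUE)
  x <- matrix(rnorm(n * p, sd = 0.5), n, p) + outer(age - 40, rep(slope, p)) +
    outer(as.numeric(site == "b"), rep(0.8, p))
  pr <- combat_fit(x, site)
  adj <- combat_apply(x, site, pr)
  slopes <- apply(adj, 2, function(col) coef(lm(col ~ age))[2])
  expect_lt(abs(mean(slopes) - slope) / slope, 0.05)
})

test_that("harmonization parameters survive a JSON round-trip", {
  set.seed(13)
  site <- rep(c("a", "b"), each = 20)
  x <- matrix(rnorm(40 * 6), 40, 6)
  pr <- combat_fit(x, site)
  js <- combat_params_to_json(pr)
  pr2 <- combat_params_from_json(js)
  expect_equal(combat_apply(x, site, pr2), combat_apply(x, site, pr),
               tolerance = 1e-12, ignore_attr = TRUE)
})
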