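test_that("truncated Poisson cluster sizes respect their bounds with the
          untruncated mean as parameter", {
  set.seed(31)
  s <- sample_cluster_sizes(2e4, scenario_config(cluster_size = "small"))
  expect_true(all(s >= 1 & s <= 10))
  expect_equal(mean(s), 5, tolerance = 0.05)
  sL <- sample_cluster_sizes(2e4, scenario_config(cluster_size = "large"))
  expect_true(all(sL >= 1 & sL <= 40))
  expect_true(any(sL > 20))
  expect_equal(sample_cluster_sizes(5, c(mean = 1, min = 1, max = 1)),
               rep(1L, 5))
})

test_that("covariates: between-cluster variables are cluster-constant,
          prevalences and winsorization follow the spec", {
  set.seed(33)
  sizes <- sample_cluster_sizes(3000, scenario_config())
  sp <- covariate_spec()
  X <- generate_covariates(sizes, sp)
  cl <- rep.int(seq_along(sizes), sizes)
  multi <- sizes >= 2
  for (j in 1:2) {
    expect_equal(max(tapply(X[, j], cl, var)[multi]), 0)
  }
  expect_gt(max(tapply(X[, 3], cl, var)[sizes > 3]), 0)
  expect_equal(mean(X[, 1]), 0.5, tolerance = 0.03)
  expect_equal(mean(X[, 2]), 0.3, tolerance = 0.03)
  expect_equal(mean(X[, 3]), 0.2, tolerance = 0.03)
  expect_setequal(unique(X[, 4]), 0:3)
  expect_lte(max(X[, 5]), sp$x5_bounds[2])
  expect_true(any(X[, 5] == sp$x5_bounds[2]))      # winsorization active

  # zero latent correlation: covariate correlations vanish
  X0 <- generate_covariates(rep(1L, 3e4), covariate_spec(latent_rho = 0))
  off <- cor(X0)[upper.tri(diag(5))]
  expect_lt(max(abs(off)), 0.03)
})

test_that("intercept calibration: closed form with zero slopes,
          monotonicity, and achieved rate", {
  set.seed(35)
  b0 <- calibrate_intercept(rep(0, 5), target = 0.3)
  expect_equal(b0, qlogis(0.3), tolerance = 1e-8)
  sl <- c(0.69, -0.5, 0.5, 0.25, 0.25)
  set.seed(35); b01 <- calibrate_intercept(sl, target = 0.1)
  set.seed(35); b03 <- calibrate_intercept(sl, target = 0.3)
  expect_lt(b01, b03)
  # achieved marginal rate on a fresh large draw
  cfg <- scenario_config(N = 4000, cluster_size = "small",
                         latent_corr = 0.7, event_rate = 0.1)
  set.seed(36)
  d <- generate_dataset(cfg, b01)
  expect_equal(mean(d$y), 0.1, tolerance = 0.01)
  expect_equal(mean(attr(d, "mu_true")), 0.1, tolerance = 0.005)
})

test_that("latent-threshold outcomes: independence at rho = 0, comonotone
          clusters at rho = 1, exact marginal model", {
  set.seed(37)
  sizes <- rep(4L, 3000)
  X <- generate_covariates(sizes)
  beta <- c(-2, 0.69, -0.5, 0.5, 0.25, 0.25)
  y0 <- generate_outcomes(X, beta, sizes, 0)
  mu <- plogis(drop(cbind(1, X) %*% beta))
  cd0 <- clustered_data(y0, X, rep.int(seq_along(sizes), sizes))
  attr(cd0, "mu_true") <- mu
  expect_lt(abs(achieved_correlation(cd0)), 0.03)

  # rho = 1 with cluster-constant covariates: all outcomes identical
  Xc <- X[rep(seq(1, nrow(X), by = 4), each = 4), ]
  y1 <- generate_outcomes(Xc, beta, sizes, 1)
  g <- rep.int(seq_along(sizes), sizes)
  expect_true(all(tapply(y1, g, function(v) length(unique(v))) == 1))

  expect_equal(mean(y0), mean(mu), tolerance = 0.01)
})

test_that("achieved binary correlation increases with latent correlation and
          with the event rate", {
  vals <- sapply(list(c(0.7, 0.1), c(0.9, 0.1), c(0.9, 0.3)), function(cc) {
    cfg <- scenario_config(N = 4000, cluster_size = "small",
                           latent_corr = cc[1], event_rate = cc[2])
    set.seed(40); b0 <- calibrate_intercept(cfg$beta_slopes, target = cc[2],
                                            n_mc = 5e4)
    set.seed(41); achieved_correlation(generate_dataset(cfg, b0))
  })
  expect_lt(vals[1], vals[2])
  expect_lt(vals[2], vals[3])
})

test_that("separation detection: toy cases and certificate validity", {
  expect_true(detect_separation(cbind(1, c(0, 0, 1, 1)), c(0, 0, 1, 1)))
  # balanced 2x2 with both outcomes in every cell
  X <- cbind(1, rep(0:1, each = 4))
  y <- rep(c(0, 1), 4)
  expect_false(detect_separation(X, y))
  # all-equal outcomes are separated (by the intercept)
  expect_true(detect_separation(cbind(1, rnorm(6)), rep(1, 6)))

  cd <- separated_clustered()
  s <- detect_separation(cd)
  expect_true(s)
  g <- attr(s, "direction")
  v <- drop(((2 * cd$y - 1) * cd$X) %*% g)
  expect_true(all(v >= -1e-8))
  expect_gt(sum(v), 1e-6)
})

test_that("the dental-like fixture has the advertised structure and
          estimator behavior", {
  d <- make_dental_fixture()
  expect_equal(d$N, 134)
  expect_equal(length(d$y), 533)
  expect_equal(sum(d$y), 28)
  expect_equal(sum(d$X[, "therapy"]), 24)
  expect_true(all(d$y[d$X[, "therapy"] == 1] == 0))
  expect_true(detect_separation(d))
  # deterministic
  d2 <- make_dental_fixture()
  expect_identical(d$y, d2$y)
  expect_identical(d$X, d2$X)

  expect_false(fit_gee(d, "exchangeable")$converged)
  a1 <- fit_auggee1(d, "exchangeable")
  expect_true(all(is.finite(a1$beta)))
  expect_lt(abs(a1$beta["therapy"]), 5)
})

test_that("same seed reproduces the same dataset bit for bit", {
  cfg <- scenario_config(N = 10, cluster_size = "small")
  set.seed(77); b0 <- calibrate_intercept(cfg$beta_slopes, target = 0.1,
                                          n_mc = 2e4)
  set.seed(123); d1 <- generate_dataset(cfg, b0)
  set.seed(123); d2 <- generate_dataset(cfg, b0)
  expect_identical(d1$y, d2$y)
  expect_identical(d1$X, d2$X)
})
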