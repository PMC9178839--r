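test_that("estimating function and information match brute-force per-cluster
          assembly for every structure", {
  cd <- random_clustered(13, n_clusters = 5, p = 2, weights = TRUE)
  beta <- c(-0.3, 0.4, -0.2)
  U4 <- matrix(0.25, 12, 12); diag(U4) <- 1
  cases <- list(list("independent", NULL), list("exchangeable", 0.45),
                list("exchangeable", -0.1), list("ar1", 0.35),
                list("unstructured", U4))
  for (cs in cases) {
    got <- gee_score(beta, cs[[2]], cd, cs[[1]])
    want <- brute_gee(beta, cs[[2]], cd, cs[[1]])
    expect_equal(unname(got$U), unname(want$U), tolerance = 1e-10,
                 label = cs[[1]])
    expect_equal(unname(got$I), unname(want$I0), tolerance = 1e-10)
  }
})

test_that("under independence the estimating function is the weighted
          logistic score", {
  cd <- random_clustered(17, weights = TRUE)
  beta <- c(0.2, -0.5, 0.3)
  pi <- plogis(drop(cd$X %*% beta))
  sc <- gee_score(beta, NULL, cd, "independent")
  expect_equal(unname(sc$U),
               unname(drop(crossprod(cd$X, cd$weights * (cd$y - pi)))),
               tolerance = 1e-12)
})

test_that("a two-observation cluster with exchangeable alpha = 0.5 matches
          the explicit 2x2 inversion", {
  cd <- clustered_data(c(1, 0), cbind(x = c(0.5, -1)), c(1, 1))
  beta <- c(0.1, 0.6)
  pi <- plogis(drop(cd$X %*% beta))
  v <- pi * (1 - pi)
  V <- diag(sqrt(v)) %*% matrix(c(1, .5, .5, 1), 2) %*% diag(sqrt(v))
  Vinv <- solve(V)                                # hand-checkable 2x2
  D <- diag(v) %*% cd$X
  sc <- gee_score(beta, 0.5, cd, "exchangeable")
  expect_equal(unname(sc$U), unname(drop(t(D) %*% Vinv %*% (cd$y - pi))),
               tolerance = 1e-12)
  expect_equal(unname(sc$I), unname(t(D) %*% Vinv %*% D), tolerance = 1e-12)
})

test_that("estimating function vanishes at the fitted solution", {
  cd <- random_clustered(23, n_clusters = 15)
  fit <- fit_gee(cd, "exchangeable", tol = 1e-10, max_iter = 100)
  expect_true(fit$converged)
  sc <- gee_score(unname(fit$beta), fit$alpha, cd, "exchangeable")
  expect_lt(max(abs(sc$U)), 1e-6)
})

test_that("moment estimator of alpha follows the printed exchangeable
          formula, including its boundary cases", {
  # residuals exactly (1, 1): y = (1,1), pi = 0.5 -> alpha-hat = 1
  cd <- clustered_data(c(1, 1), matrix(0, 2, 1), c(1, 1))
  expect_equal(estimate_alpha(cd, c(0.5, 0.5), "exchangeable"), 1)
  # anti-correlated residuals (1, -1) -> -1
  cd2 <- clustered_data(c(1, 0), matrix(0, 2, 1), c(1, 1))
  expect_equal(estimate_alpha(cd2, c(0.5, 0.5), "exchangeable"), -1)
  # zero residuals impossible with binary y; equal-probability mix averages
  # the per-cluster ratios: clusters (1,1) and (1,0) give (1 + -1)/2 = 0
  cd3 <- clustered_data(c(1, 1, 1, 0), matrix(0, 4, 1), c(1, 1, 2, 2))
  expect_equal(estimate_alpha(cd3, rep(0.5, 4), "exchangeable"), 0)
  # singleton clusters contribute nothing
  cd4 <- clustered_data(c(1, 1, 0), matrix(0, 3, 1), c(1, 1, 2))
  expect_equal(estimate_alpha(cd4, rep(0.5, 3), "exchangeable"), 1)
  # no pairable cluster at all
  cd5 <- clustered_data(c(1, 0), matrix(0, 2, 1), c(1, 2))
  expect_error(estimate_alpha(cd5, c(0.5, 0.5), "exchangeable"),
               "independent")
})

test_that("independent-structure GEE equals ML logistic regression", {
  for (s in c(2, 9)) {
    cd <- random_clustered(s, weights = TRUE)
    fit <- fit_gee(cd, "independent", tol = 1e-8, max_iter = 100)
    ml <- suppressWarnings(glm.fit(cd$X, cd$y, weights = cd$weights,
                                   family = binomial()))
    expect_equal(unname(fit$beta), unname(ml$coefficients), tolerance = 1e-6)
  }
})

test_that("GEE flags non-convergence on separated data instead of erroring", {
  cd <- separated_clustered()
  fit <- expect_no_error(fit_gee(cd, "exchangeable"))
  expect_false(fit$converged)
  expect_true(is.character(fit$reason))
})

test_that("cluster order permutation leaves estimates unchanged", {
  cd <- random_clustered(41, n_clusters = 9)
  perm <- c(5, 1, 9, 3, 7, 2, 8, 4, 6)
  rows <- unlist(lapply(perm, function(i) which(cd$cluster == i)))
  cd2 <- clustered_data(cd$y[rows], cd$X[rows, -1, drop = FALSE],
                        cd$cluster[rows])
  f1 <- fit_gee(cd, "exchangeable", tol = 1e-9, max_iter = 100)
  f2 <- fit_gee(cd2, "exchangeable", tol = 1e-9, max_iter = 100)
  expect_equal(unname(f1$beta), unname(f2$beta), tolerance = 1e-7)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-7)
})

test_that("exchangeable alpha estimate recovers the within-cluster
          correlation on simulated data", {
  set.seed(77)
  N <- 400; size <- 4
  cl <- rep(1:N, each = size)
  x <- rnorm(N * size)
  # exchangeable binary outcomes via a shared latent effect
  b <- rep(rnorm(N), each = size)
  y <- as.integer(plogis(-0.5 + 0.5 * x + 1.2 * b) > runif(N * size))
  cd <- clustered_data(y, cbind(x = x), cl)
  fit <- fit_gee(cd, "exchangeable")
  expect_true(fit$converged)
  # oracle: empirical pairwise correlation of residuals at the fit
  e <- (cd$y - fit$fitted) / sqrt(fit$fitted * (1 - fit$fitted))
  em <- matrix(e, nrow = size)
  cors <- cor(t(em))
  expect_equal(fit$alpha, mean(cors[upper.tri(cors)]), tolerance = 0.05)
})

test_that("ar1 and unstructured moment estimators follow their pairwise
          definitions", {
  cd <- random_clustered(51, n_clusters = 6, mean_size = 3)
  pi <- plogis(drop(cd$X %*% c(-0.2, 0.3, 0.1)))
  e <- (cd$y - pi) / sqrt(pi * (1 - pi))
  # ar1 oracle: mean over clusters of lag-1 products / (n_i - 1)
  vals <- c()
  for (i in seq_len(cd$N)) {
    r <- which(cd$cluster == i); ni <- length(r)
    if (ni < 2) next
    vals <- c(vals, sum(e[r[-ni]] * e[r[-1]]) / (ni - 1))
  }
  expect_equal(estimate_alpha(cd, pi, "ar1"), mean(vals), tolerance = 1e-12)
  A <- estimate_alpha(cd, pi, "unstructured")
  expect_true(isSymmetric(A))
  expect_equal(diag(A), rep(1, nrow(A)))
  # entry (1,2): mean over clusters with >= 2 observations
  v12 <- sapply(seq_len(cd$N), function(i) {
    r <- which(cd$cluster == i)
    if (length(r) < 2) NA else e[r[1]] * e[r[2]]
  })
  expect_equal(A[1, 2], mean(v12, na.rm = TRUE), tolerance = 1e-12)
})
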