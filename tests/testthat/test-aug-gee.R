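test_that("generalized hat reduces to the ordinary hat under independence
          and keeps trace = p + 1 everywhere", {
  cd <- random_clustered(71, n_clusters = 7, p = 2, weights = TRUE)
  beta <- c(-0.2, 0.4, 0.3)
  pi <- plogis(drop(cd$X %*% beta))
  gh <- generalized_hat(beta, NULL, cd, "independent")
  expect_equal(gh$diag, hat_diagonals(cd$X, pi, cd$weights),
               tolerance = 1e-12)

  U4 <- matrix(0.2, 12, 12); diag(U4) <- 1
  for (cs in list(list("exchangeable", 0.5), list("exchangeable", -0.1),
                  list("ar1", 0.6), list("unstructured", U4))) {
    gh <- generalized_hat(beta, cs[[2]], cd, cs[[1]])
    expect_equal(sum(gh$diag), ncol(cd$X), tolerance = 1e-8,
                 label = cs[[1]])
    expect_true(all(gh$diag >= 0 & gh$diag <= 1))
  }
})

test_that("a single two-observation cluster matches the hand-built block", {
  cd <- clustered_data(c(1, 0), cbind(x = c(1, -0.5)), c(1, 1))
  beta <- c(0.2, 0.4); alpha <- 0.5
  pi <- plogis(drop(cd$X %*% beta))
  W <- diag(pi * (1 - pi))
  R <- matrix(c(1, .5, .5, 1), 2)
  Om <- sqrt(W) %*% solve(R) %*% sqrt(W)
  es <- eigen(Om); B <- es$vectors %*% diag(sqrt(es$values)) %*% t(es$vectors)
  H <- B %*% cd$X %*% solve(t(cd$X) %*% Om %*% cd$X) %*% t(cd$X) %*% B
  gh <- generalized_hat(beta, alpha, cd, "exchangeable", keep_blocks = TRUE)
  expect_equal(gh$blocks[[1]], H, tolerance = 1e-10)
  expect_equal(gh$diag, diag(H), tolerance = 1e-10)
  expect_equal(sum(gh$diag), 2, tolerance = 1e-10)
})

test_that("augmentation builds 3N clusters with pseudo-weight p + 1 and
          flipped third copy", {
  cd <- clustered_data(c(1, 0, 1, 0, 0, 1), matrix(rnorm(6)),
                       rep(1:2, each = 3))
  fl <- fit_firth(cd)
  aug <- build_augmented(cd, fl$hat)
  expect_equal(aug$N, 6)
  expect_equal(length(aug$y), 18)
  n <- 6
  expect_equal(sum(aug$weights[-(1:n)]), ncol(cd$X), tolerance = 1e-10)
  expect_equal(aug$weights[1:n], cd$weights)
  # third copy flips; flipping twice restores
  expect_equal(aug$y[2 * n + 1:n], 1 - cd$y)
  aug2 <- build_augmented(cd, fl$hat)
  expect_equal(1 - aug2$y[2 * n + 1:n], cd$y)
  # alternative N-cluster layout merges the copies
  augN <- build_augmented(cd, fl$hat, pseudo_clusters = "N")
  expect_equal(augN$N, 2)
  expect_equal(sort(augN$sizes), c(9L, 9L))
})

test_that("augmented GEE with independent structure equals Firth's logistic
          regression", {
  for (s in c(8, 19)) {
    cd <- random_clustered(s)
    fl <- fit_firth(cd)
    a1 <- fit_auggee1(cd, "independent")
    aa <- fit_auggee(cd, "independent")
    expect_true(a1$converged && aa$converged)
    expect_lt(max(abs(a1$beta - fl$beta)), 1e-5)
    expect_lt(max(abs(aa$beta - fl$beta)), 1e-5)
  }
})

test_that("single-step fit equals the first outer iterate of the iterated
          algorithm", {
  cd <- random_clustered(26, n_clusters = 10)
  a1 <- fit_auggee1(cd, "exchangeable")
  aa1 <- fit_auggee(cd, "exchangeable", max_outer = 1)
  expect_equal(a1$beta, aa1$beta, tolerance = 1e-12)
  expect_equal(a1$alpha, aa1$alpha, tolerance = 1e-12)
})

test_that("augmented GEE gives finite estimates on separated data", {
  cd <- separated_clustered()
  a1 <- fit_auggee1(cd, "exchangeable")
  aa <- fit_auggee(cd, "exchangeable")
  expect_true(all(is.finite(a1$beta)))
  expect_true(all(is.finite(aa$beta)))
  expect_lt(abs(a1$beta["z"]), 10)
  expect_lt(abs(aa$beta["z"]), 10)
})

test_that("single-step augmented GEE with independent structure never fails
          on hard data (the fallback estimator)", {
  cd <- separated_clustered()
  f <- fit_auggee1(cd, "independent")
  expect_true(f$converged)
  expect_true(all(is.finite(f$beta)))
  # all-events outcome: still finite
  cd2 <- clustered_data(rep(1, 8), matrix(rnorm(8)), rep(1:4, each = 2))
  f2 <- fit_auggee1(cd2, "independent")
  expect_true(all(is.finite(f2$beta)))
})

test_that("estimates shrink toward the truth as the number of clusters
          grows (consistency of the augmented estimator)", {
  bias_at <- function(N, seed) {
    set.seed(seed)
    reps <- sapply(1:30, function(i) {
      cl <- rep(1:N, each = 4)
      x <- rep(rbinom(N, 1, 0.5), each = 4)       # between-cluster binary
      b <- rep(rnorm(N), each = 4)
      y <- as.integer(plogis(-1 + 0.69 * x + b) > runif(4 * N))
      cd <- clustered_data(y, cbind(x = x), cl)
      fit_auggee1(cd, "exchangeable")$beta["x"]
    })
    abs(mean(reps) - 0.69)
  }
  expect_lt(bias_at(150, 5), bias_at(15, 5) + 0.05)
})
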