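# Clustered binary data generator with latent-threshold (Gaussian copula)
# dependence. Outcomes satisfy the marginal logit model exactly:
# Y_ij = 1 iff pnorm(g_ij) < expit(x_ij beta), where the latent Gaussians
# g_ij have exchangeable within-cluster correlation. Covariates are obtained
# by transforming correlated standard normals Z1..Z5: three binaries (Z1,
# Z2 cluster-constant "between-cluster" covariates), one quartile-binned
# ordinal and one log-normal-type continuous covariate, winsorized.

#' Covariate generation settings
#'
#' Defaults reconstruct a realistic epidemiological covariate mix: latent
#' correlation 0.2 between all pairs of Z1..Z5; binary prevalences 0.5
#' (Z1, between-cluster, the main exposure), 0.3 (Z2, between-cluster) and
#' 0.2 (Z3); a 4-level ordinal from quartile binning of Z4 (coded 0..3);
#' and X5 = exp(Z5/2) winsorized at Q1 - 3 IQR and Q3 + 3 IQR, the quartiles
#' taken as the transform of the standard-normal quartiles.
#'
#' @param latent_rho common latent correlation among Z1..Z5.
#' @param prevalences length-3 prevalences of the binary covariates.
#' @return list of class `covariate_spec`.
#' @export
covariate_spec <- function(latent_rho = 0.2,
                           prevalences = c(0.5, 0.3, 0.2)) {
  Sigma <- matrix(latent_rho, 5, 5); diag(Sigma) <- 1
  q <- exp(stats::qnorm(c(0.25, 0.75)) / 2)
  iqr <- diff(q)
  structure(list(
    Sigma = Sigma,
    thresholds = stats::qnorm(1 - prevalences),
    ordinal_breaks = stats::qnorm(c(0.25, 0.5, 0.75)),
    x5_transform = function(z) exp(z / 2),
    x5_bounds = c(q[1] - 3 * iqr, q[2] + 3 * iqr)
  ), class = "covariate_spec")
}

#' Simulation scenario settings
#'
#' One cell of the factorial design: number of clusters (20/50/100), cluster
#' size class (truncated Poisson with mean 5, 10 or 20 and range 1-10, 1-20
#' or 1-40), latent-scale exchangeable correlation (0.7/0.9) and marginal
#' event rate (0.1/0.3). The main binary between-cluster covariate has true
#' coefficient 0.69; the remaining slopes default to (-0.5, 0.5, 0.25,
#' 0.25). The intercept is calibrated to the event rate by [calibrate_intercept()].
#'
#' @param N number of clusters.
#' @param cluster_size `"small"`, `"moderate"` or `"large"`.
#' @param latent_corr exchangeable correlation of the latent responses.
#' @param event_rate target marginal event rate.
#' @param beta1 true coefficient of the main covariate X1.
#' @param beta_rest true slopes of X2..X5.
#' @param n_datasets datasets per scenario.
#' @param seed scenario master seed.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(N = 20,
                            cluster_size = c("small", "moderate", "large"),
                            latent_corr = 0.9, event_rate = 0.1,
                            beta1 = 0.69,
                            beta_rest = c(-0.5, 0.5, 0.25, 0.25),
                            n_datasets = 1000, seed = 1L) {
  cluster_size <- match.arg(cluster_size)
  pois <- switch(cluster_size,
                 small = c(mean = 5, min = 1, max = 10),
                 moderate = c(mean = 10, min = 1, max = 20),
                 large = c(mean = 20, min = 1, max = 40))
  structure(list(N = N, cluster_size = cluster_size, pois = pois,
                 latent_corr = latent_corr, event_rate = event_rate,
                 beta_slopes = c(beta1, beta_rest),
                 n_datasets = n_datasets, seed = seed),
            class = "scenario_config")
}

#' Sample cluster sizes from a truncated Poisson distribution
#'
#' Rejection sampling: Poisson draws (with `mean` read as the untruncated
#' Poisson parameter) are redrawn until they fall inside \[min, max\].
#'
#' @param N number of clusters.
#' @param config a [scenario_config()] (or a named vector `c(mean, min, max)`).
#' @return integer vector of length N.
#' @export
sample_cluster_sizes <- function(N, config) {
  p <- if (inherits(config, "scenario_config")) config$pois else config
  sizes <- stats::rpois(N, p[["mean"]])
  bad <- which(sizes < p[["min"]] | sizes > p[["max"]])
  while (length(bad)) {
    sizes[bad] <- stats::rpois(length(bad), p[["mean"]])
    bad <- bad[sizes[bad] < p[["min"]] | sizes[bad] > p[["max"]]]
  }
  sizes
}

#' Generate the covariate matrix for given cluster sizes
#'
#' Z1 and Z2 are drawn at cluster level (constant within cluster); Z3..Z5
#' are drawn per observation from their conditional normal distribution
#' given (Z1, Z2), so the marginal 5x5 latent correlation equals
#' `spec$Sigma` exactly while within-cluster dependence of X3..X5 is induced
#' only through the shared cluster-level pair.
#'
#' @param sizes integer vector of cluster sizes.
#' @param spec a [covariate_spec()].
#' @return matrix with columns x1..x5 and sum(sizes) rows.
#' @export
generate_covariates <- function(sizes, spec = covariate_spec()) {
  ncl <- length(sizes)
  total <- sum(sizes)
  rep_idx <- rep.int(seq_len(ncl), sizes)
  S <- spec$Sigma
  S11 <- S[1:2, 1:2]; S21 <- S[3:5, 1:2]; S22 <- S[3:5, 3:5]
  A <- S21 %*% solve(S11)                  # regression of (Z3..Z5) on (Z1,Z2)
  Ccond <- S22 - A %*% t(S21)
  Zb <- matrix(stats::rnorm(2 * ncl), ncl, 2) %*% chol(S11)
  mu <- (Zb %*% t(A))[rep_idx, , drop = FALSE]
  Zw <- matrix(stats::rnorm(3 * total), total, 3) %*% chol(Ccond) + mu
  Z <- cbind(Zb[rep_idx, , drop = FALSE], Zw)
  x5 <- spec$x5_transform(Z[, 5])
  cbind(
    x1 = as.numeric(Z[, 1] > spec$thresholds[1]),
    x2 = as.numeric(Z[, 2] > spec$thresholds[2]),
    x3 = as.numeric(Z[, 3] > spec$thresholds[3]),
    x4 = findInterval(Z[, 4], spec$ordinal_breaks),
    x5 = pmin(pmax(x5, spec$x5_bounds[1]), spec$x5_bounds[2])
  )
}

#' Calibrate the intercept to a target marginal event rate
#'
#' Monte-Carlo root finding: a large iid covariate sample is drawn from the
#' latent model (cluster structure does not affect the per-observation
#' marginals) and the intercept solving
#' mean(expit(beta0 + X beta_slopes)) = target is located with
#' [stats::uniroot()] on the fixed sample.
#'
#' @param beta_slopes slopes for x1..x5.
#' @param spec a [covariate_spec()].
#' @param target target event rate in (0, 1).
#' @param n_mc Monte-Carlo sample size.
#' @return calibrated intercept beta0.
#' @export
calibrate_intercept <- function(beta_slopes, spec = covariate_spec(),
                                target = 0.1, n_mc = 2e5) {
  stopifnot(target > 0, target < 1)
  X <- generate_covariates(rep(1L, n_mc), spec)
  lp <- drop(X %*% beta_slopes)
  f <- function(b0) mean(expit(b0 + lp)) - target
  lo <- -30; hi <- 30
  while (f(lo) > 0) lo <- lo * 2
  while (f(hi) < 0) hi <- hi * 2
  if (abs(lo) > 500 || abs(hi) > 500) stop("intercept calibration failed to bracket")
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Generate clustered binary outcomes from the latent-threshold model
#'
#' Latent exchangeable Gaussians g_ij = sqrt(rho) b_i + sqrt(1 - rho) e_ij
#' are thresholded against the linear predictor on the uniform scale:
#' Y_ij = 1 iff pnorm(g_ij) < expit(x_ij beta). The marginal model
#' P(Y = 1 | x) = expit(x beta) holds exactly; within-cluster dependence is
#' controlled by the latent correlation rho.
#'
#' @param X covariate matrix (columns x1..x5, no intercept).
#' @param beta full coefficient vector (intercept first).
#' @param sizes cluster sizes (rows of X grouped by cluster).
#' @param latent_corr exchangeable latent correlation in \[0, 1).
#' @return integer 0/1 outcome vector.
#' @export
generate_outcomes <- function(X, beta, sizes, latent_corr) {
  if (latent_corr < 0 || latent_corr > 1) stop("invalid latent correlation")
  total <- sum(sizes)
  stopifnot(nrow(X) == total)
  rep_idx <- rep.int(seq_along(sizes), sizes)
  lp <- drop(cbind(1, X) %*% beta)
  b <- stats::rnorm(length(sizes))
  g <- sqrt(latent_corr) * b[rep_idx] +
    sqrt(1 - latent_corr) * stats::rnorm(total)
  as.integer(stats::pnorm(g) < expit(lp))
}

#' Generate one simulated dataset for a scenario
#'
#' @param config a [scenario_config()].
#' @param beta0 calibrated intercept (see [calibrate_intercept()]).
#' @param spec a [covariate_spec()].
#' @return A [clustered_data] object with attribute `mu_true`, the true
#'   event probabilities.
#' @export
generate_dataset <- function(config, beta0, spec = covariate_spec()) {
  sizes <- sample_cluster_sizes(config$N, config)
  X <- generate_covariates(sizes, spec)
  beta <- c(beta0, config$beta_slopes)
  y <- generate_outcomes(X, beta, sizes, config$latent_corr)
  out <- clustered_data(y = y, X = X, cluster = rep.int(seq_along(sizes), sizes))
  attr(out, "mu_true") <- expit(drop(cbind(1, X) %*% beta))
  out
}

#' Detect separation by linear programming
#'
#' The data are (quasi-completely or completely) separable iff a nonzero
#' gamma exists with x_i' gamma >= 0 for all events and <= 0 for all
#' non-events, with strict inequality somewhere. Writing z_i = 2 y_i - 1,
#' by Stiemke's duality such a gamma exists iff the linear program
#' \{ sum_i lambda_i z_i x_i = 0, lambda >= 1 \} is INFEASIBLE; the check
#' runs a phase-1 simplex (with Bland's anti-cycling rule) on that system,
#' whose infeasibility certificate is exactly a separating direction
#' maximizing the total slack among the dual-feasible set.
#'
#' @param X design matrix (with or without intercept column) or a
#'   [clustered_data] object.
#' @param y binary outcomes (omit for `clustered_data` input).
#' @param tol relative positivity tolerance on the phase-1 optimum.
#' @return logical with attribute `direction` (a separating gamma, on the
#'   design-column scale) when separable.
#' @export
detect_separation <- function(X, y = NULL, tol = 1e-7) {
  if (inherits(X, "clustered_data")) { y <- X$y; X <- X$X }
  X <- as.matrix(X)
  z <- 2 * y - 1
  Zx <- unique(z * X)
  # lambda = 1 + mu, mu >= 0:  t(Zx) mu = -t(Zx) 1
  d <- -colSums(Zx)
  sol <- phase1_feasibility(t(Zx), d)
  sep <- sol$value > tol * (1 + sum(abs(d)))
  if (sep) {
    gamma <- -sol$y
    names(gamma) <- colnames(X)
    attr(sep, "direction") <- gamma
  }
  sep
}

#' Empirical within-cluster correlation of binary outcomes at the truth
#'
#' The exchangeable moment estimator evaluated at the TRUE event
#' probabilities: the mean over clusters (with at least two observations) of
#' the average pairwise product of Pearson-standardized outcomes. This is
#' the "achieved" binary-outcome correlation induced by the latent-threshold
#' generator, which depends on both the latent correlation and the event
#' rate.
#'
#' @param data a [clustered_data] (or list of them).
#' @param mu_true true probabilities (defaults to the `mu_true` attribute).
#' @return scalar correlation estimate.
#' @export
achieved_correlation <- function(data, mu_true = NULL) {
  if (!inherits(data, "clustered_data") && is.list(data)) {
    vals <- vapply(data, achieved_correlation, numeric(1))
    return(mean(vals))
  }
  if (is.null(mu_true)) mu_true <- attr(data, "mu_true")
  estimate_alpha(data, mu_true, "exchangeable")
}

#' Synthetic dental-study-like fixture with separation
#'
#' A deterministic synthetic dataset emulating the structural features of a
#' multi-implant dentistry study: 134 patients (clusters) contributing 533
#' implantations, a rare event (rate about 0.05) concentrated in 7 patients,
#' a rare binary between-patient covariate (therapy, 24 observations) whose
#' carriers experience no events — which makes the data quasi-completely
#' separable — plus a within-patient 3-level timing factor (two dummies) and
#' a continuous age covariate in decades. This is a synthetic stand-in, not
#' the study data.
#'
#' @param seed integer seed (fixed default: the packaged fixture).
#' @return A [clustered_data] object.
#' @export
make_dental_fixture <- function(seed = 2022L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  ncl <- 134L
  sizes <- sample_cluster_sizes(ncl, c(mean = 4, min = 1, max = 10))
  # adjust to exactly 533 observations
  diffn <- 533L - sum(sizes)
  while (diffn != 0L) {
    i <- sample.int(ncl, 1L)
    step <- sign(diffn)
    if (sizes[i] + step >= 1L && sizes[i] + step <= 10L) {
      sizes[i] <- sizes[i] + step
      diffn <- diffn - step
    }
  }
  rep_idx <- rep.int(seq_len(ncl), sizes)

  diabetes <- stats::rbinom(ncl, 1, 0.15)
  # therapy carriers: patients whose sizes sum to exactly 24 observations
  ord <- sample.int(ncl)
  csum <- cumsum(sizes[ord])
  k <- which(csum == 24L)[1]
  while (is.na(k)) {
    ord <- sample.int(ncl)
    csum <- cumsum(sizes[ord])
    k <- which(csum == 24L)[1]
  }
  therapy <- integer(ncl)
  therapy[ord[seq_len(k)]] <- 1L
  age <- round(stats::rnorm(ncl, 5.5, 1.2), 1)

  timing <- sample(0:2, 533L, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  X <- cbind(timing_early = as.numeric(timing == 1),
             timing_later = as.numeric(timing == 2),
             diabetes = diabetes[rep_idx],
             therapy = therapy[rep_idx],
             age = age[rep_idx])

  # 28 events in 7 therapy-free patients with at least 4 implantations
  y <- integer(533L)
  eligible <- which(therapy == 0L & sizes >= 4L)
  cases <- sample(eligible, 7L)
  for (i in cases) {
    rows <- which(rep_idx == i)
    y[sample(rows, 4L)] <- 1L
  }
  clustered_data(y = y, X = X, cluster = rep_idx)
}
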