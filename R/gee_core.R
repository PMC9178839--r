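# Core GEE machinery. The marginal logit model P(Y_ij = 1 | x_ij) =
# expit(x_ij beta) is estimated from the estimating equations
#   sum_i X_i' W_i (W_i^{1/2} R_i(alpha) W_i^{1/2})^{-1} (y_i - pi_i) = 0,
# with W_i = diag(pi_ij (1 - pi_ij)). Per-observation scale weights enter in
# the PROC GEE / geem2 dialect: with Q_i = diag(w_ij) the working covariance
# is V_i = Delta_i^{1/2} Q_i^{-1/2} R_i Q_i^{-1/2} Delta_i^{1/2}, which is
# algebraically the same as replacing W_i by diag(w_ij pi_ij (1-pi_ij)) and
# the residual by Delta_i^{-1}(y_i - pi_i):
#   U_i = X_i' Omega_i Delta_i^{-1} (y_i - pi_i),
#   I   = sum_i X_i' Omega_i X_i,           Omega_i = W_i^{1/2} R_i^{-1} W_i^{1/2}.
# Under independence this is the weighted logistic score / information; at
# unit weights it is the printed estimating function verbatim.

# admissibility of alpha for building R^{-1} (exchangeable closed form)
check_exch_alpha <- function(alpha, nmax) {
  if (!is.finite(alpha) || alpha >= 1 ||
      (nmax > 1 && alpha <= -1 / (nmax - 1))) {
    stop("singular working correlation: exchangeable alpha = ",
         format(alpha), " inadmissible for cluster size ", nmax)
  }
}

# Estimating-function pieces at (beta, alpha). Returns:
#   U  : (p+1) estimating function
#   I  : (p+1)x(p+1) model-based information sum_i X_i' Omega_i X_i
#   OX : N* x (p+1) matrix with rows of Omega_i X_i (per cluster)
#   g  : N* vector Omega_i Delta_i^{-1} (y_i - pi_i), so d_i = X_i' g_i
#   d  : N x (p+1) per-cluster score contributions
#   pi : fitted probabilities
gee_parts <- function(beta, alpha, data, structure) {
  X <- data$X
  cl <- data$cluster
  pi <- expit(drop(X %*% beta))
  v <- pi * (1 - pi)
  w <- data$weights * v
  tres <- (data$y - pi) / v

  if (structure == "independent" ||
      (is.numeric(alpha) && !is.matrix(alpha) && length(alpha) == 1L &&
       alpha == 0)) {
    g <- w * tres
    OX <- w * X
    I <- crossprod(X, OX)
  } else if (structure == "exchangeable") {
    check_exch_alpha(alpha, max(data$sizes))
    c1 <- 1 / (1 - alpha)
    c2 <- alpha / (1 + (data$sizes - 1) * alpha)   # per cluster
    c2row <- c2[cl]
    s <- sqrt(w)
    st_sum <- rowsum(s * tres, cl, reorder = FALSE)[cl, 1L]
    g <- c1 * (w * tres - c2row * s * st_sum)
    A <- rowsum(s * X, cl, reorder = FALSE)        # N x (p+1), rows X_i' s_i
    OX <- c1 * (w * X - (c2row * s) * A[cl, , drop = FALSE])
    I <- c1 * crossprod(X, w * X) - crossprod(A, (c1 * c2) * A)
  } else {
    # generic per-cluster path (ar1, unstructured, exchangeable fallback)
    g <- numeric(length(pi))
    OX <- matrix(0, nrow(X), ncol(X))
    I <- matrix(0, ncol(X), ncol(X))
    pos <- 0L
    for (i in seq_len(data$N)) {
      ni <- data$sizes[i]
      rows <- pos + seq_len(ni)
      pos <- pos + ni
      R <- working_matrix(structure, alpha, ni)
      si <- sqrt(w[rows])
      Om <- solve(R) * tcrossprod(si)
      Xi <- X[rows, , drop = FALSE]
      OXi <- Om %*% Xi
      g[rows] <- Om %*% tres[rows]
      OX[rows, ] <- OXi
      I <- I + crossprod(Xi, OXi)
    }
  }
  d <- rowsum(X * g, cl, reorder = FALSE)
  U <- colSums(d)
  list(U = U, I = I, OX = OX, g = g, d = d, pi = pi)
}

#' GEE estimating function and model-based information
#'
#' Evaluates the generalized estimating function U(beta, alpha) and the
#' model-based information I(beta, alpha) = sum_i X_i' Omega_i X_i at the
#' supplied parameters, with Omega_i = W_i^(1/2) R_i(alpha)^(-1) W_i^(1/2)
#' and W_i the (scale-weighted) binomial variance diagonal. Under the
#' independent structure U reduces to the weighted logistic score.
#'
#' @param beta coefficient vector (length ncol(X)).
#' @param alpha working correlation parameter (scalar, or matrix for
#'   `unstructured`; ignored for `independent`).
#' @param data a [clustered_data] object.
#' @param structure working correlation structure tag.
#' @return list with `U` and `I`.
#' @export
gee_score <- function(beta, alpha, data, structure = "exchangeable") {
  structure <- match.arg(structure,
                         c("independent", "exchangeable", "ar1", "unstructured"))
  parts <- gee_parts(beta, alpha, data, structure)
  list(U = parts$U, I = parts$I)
}

#' Moment estimator of the working correlation parameter
#'
#' Pearson residuals e_ij = (y_ij - pi_ij) / sqrt(pi_ij (1 - pi_ij)) are
#' combined into the structure-specific moment estimate. For the exchangeable
#' structure each cluster contributes its average pairwise residual product
#' (divided by n_i (n_i - 1)), and the estimate is the mean over clusters
#' with at least two observations; clusters of size one contribute nothing.
#' Scale weights enter as sqrt(w_j) factors on the residuals (the
#' scale-factor dialect), so low-weight pseudo observations are damped; the
#' pair-count denominator stays unweighted, and everything reduces to the
#' unweighted formula at unit weights. The scale parameter is fixed at 1
#' throughout; residuals are not dispersion-rescaled.
#'
#' @param data a [clustered_data] object.
#' @param fitted fitted probabilities at the current coefficients.
#' @param structure `"exchangeable"`, `"ar1"` or `"unstructured"`.
#' @return scalar estimate (matrix for `unstructured`).
#' @export
estimate_alpha <- function(data, fitted, structure = "exchangeable") {
  structure <- match.arg(structure, c("exchangeable", "ar1", "unstructured"))
  if (max(data$sizes) < 2L) {
    stop("no cluster with 2 or more observations: ",
         "use the independent working structure")
  }
  v <- fitted * (1 - fitted)
  e <- (data$y - fitted) / sqrt(v)
  q <- sqrt(data$weights)
  cl <- data$cluster

  if (structure == "exchangeable") {
    qe <- q * e
    S1 <- rowsum(qe, cl, reorder = FALSE)[, 1L]
    S2 <- rowsum(qe^2, cl, reorder = FALSE)[, 1L]
    num <- S1^2 - S2
    den <- data$sizes * (data$sizes - 1)
    keep <- data$sizes >= 2L
    return(mean(num[keep] / den[keep]))
  }
  if (structure == "ar1") {
    vals <- numeric(0)
    pos <- 0L
    for (i in seq_len(data$N)) {
      ni <- data$sizes[i]
      rows <- pos + seq_len(ni)
      pos <- pos + ni
      if (ni < 2L) next
      j <- rows[-ni]; k <- rows[-1L]
      vals <- c(vals, sum(q[j] * q[k] * e[j] * e[k]) / (ni - 1))
    }
    return(mean(vals))
  }
  # unstructured: per-pair mean over clusters providing that pair
  nmax <- max(data$sizes)
  num <- matrix(0, nmax, nmax); cnt <- matrix(0, nmax, nmax)
  pos <- 0L
  for (i in seq_len(data$N)) {
    ni <- data$sizes[i]
    rows <- pos + seq_len(ni)
    pos <- pos + ni
    if (ni < 2L) next
    qe <- q[rows] * e[rows]
    num[1:ni, 1:ni] <- num[1:ni, 1:ni] + tcrossprod(qe)
    cnt[1:ni, 1:ni] <- cnt[1:ni, 1:ni] + 1
  }
  alpha <- ifelse(cnt > 0, num / pmax(cnt, 1), 0)
  diag(alpha) <- 1
  (alpha + t(alpha)) / 2
}

# worst absolute correlation, used for the (-1, 1) admissibility flag
alpha_extreme <- function(alpha, structure) {
  if (structure == "independent") return(0)
  if (is.matrix(alpha)) {
    off <- alpha[upper.tri(alpha)]
    if (!length(off)) 0 else max(abs(off))
  } else abs(alpha)
}

# Fisher-scoring engine shared by ordinary, penalized and inner augmented
# fits. One Newton step per outer iteration, alternating with the moment
# update of alpha. `penalized = TRUE` adds the Firth-type term
# 1/2 trace(I^{-1} dI/dbeta_m) to U and (per the published algorithm) uses
# the alpha from the PREVIOUS iteration in the update step.
gee_engine <- function(data, structure, beta0, alpha0 = 0, tol = 1e-3,
                       max_iter = 30, penalized = FALSE, fixed_alpha = NULL) {
  beta <- as.numeric(beta0)
  alpha_cur <- if (!is.null(fixed_alpha)) fixed_alpha else alpha0
  converged <- FALSE
  reason <- NA_character_
  trace <- matrix(NA_real_, 0, length(beta))
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    pi <- expit(drop(data$X %*% beta))
    alpha_new <- alpha_cur
    if (is.null(fixed_alpha) && structure != "independent") {
      alpha_new <- tryCatch(estimate_alpha(data, pi, structure),
                            error = function(e) e)
      if (inherits(alpha_new, "error")) {
        reason <- conditionMessage(alpha_new); break
      }
    }
    alpha_step <- if (penalized) alpha_cur else alpha_new
    parts <- tryCatch(gee_parts(beta, alpha_step, data, structure),
                      error = function(e) e)
    if (inherits(parts, "error")) { reason <- conditionMessage(parts); break }
    U <- parts$U
    if (penalized) {
      U <- U + firth_penalty_from_parts(parts, data)
    }
    step <- tryCatch(solve(parts$I, U), error = function(e) e)
    if (inherits(step, "error")) {
      reason <- "singular information matrix"; break
    }
    beta_new <- beta + drop(step)
    if (any(!is.finite(beta_new))) { reason <- "divergent update"; break }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    alpha_cur <- alpha_new
    trace <- rbind(trace, beta)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged && is.na(reason)) reason <- "iteration limit reached"
  alpha_ok <- structure == "independent" ||
    (all(is.finite(alpha_extreme(alpha_cur, structure))) &&
     alpha_extreme(alpha_cur, structure) < 1)
  list(beta = beta, alpha = alpha_cur, converged = converged && alpha_ok,
       criterion_met = converged, alpha_ok = alpha_ok,
       reason = if (converged && alpha_ok) NA_character_ else
         if (!alpha_ok) "correlation parameter outside (-1, 1)" else reason,
       n_iter = iter, trace = trace)
}

# default start for ordinary GEE: ML logistic via capped IRLS (the
# GLM-type initialization of standard GEE software)
default_start <- function(data) {
  g <- tryCatch(suppressWarnings(
    stats::glm.fit(data$X, data$y, weights = data$weights,
                   family = stats::binomial(),
                   control = list(maxit = 25))),
    error = function(e) NULL)
  b <- if (is.null(g)) rep(0, ncol(data$X)) else g$coefficients
  b[!is.finite(b)] <- 0
  b
}

# assemble the exported fit object; variance is always evaluated on
# `var_data` (the ORIGINAL data for the augmented estimators)
as_gee_fit <- function(eng, var_data, structure, method,
                       n_outer = NA_integer_, extra_reason = NULL) {
  p1 <- ncol(var_data$X)
  fitted <- expit(drop(var_data$X %*% eng$beta))
  cov_s <- cov_m <- matrix(NA_real_, p1, p1)
  if (all(is.finite(eng$beta))) {
    vc <- tryCatch({
      parts <- sandwich_parts(eng$beta, eng$alpha, var_data, structure)
      list(s = sandwich_from_parts(parts),
           m = morel_from_parts(parts, var_data, eng$alpha, structure))
    }, error = function(e) NULL)
    if (!is.null(vc)) { cov_s <- vc$s; cov_m <- vc$m }
  }
  dimnames(cov_s) <- dimnames(cov_m) <- list(colnames(var_data$X),
                                             colnames(var_data$X))
  structure(list(
    beta = stats::setNames(eng$beta, colnames(var_data$X)),
    alpha = eng$alpha,
    converged = eng$converged,
    reason = if (!is.null(extra_reason) && !eng$converged) extra_reason
             else eng$reason,
    n_outer = n_outer,
    n_inner = eng$n_iter,
    trace = eng$trace,
    cov_sandwich = cov_s,
    cov_morel = cov_m,
    fitted = fitted,
    N = var_data$N,
    structure = structure,
    method = method
  ), class = "gee_fit")
}

#' Ordinary GEE for marginal logistic regression
#'
#' Fisher-scoring solution of the generalized estimating equations with a
#' moment update of the working correlation parameter at every iteration
#' (one Newton step per outer iteration). The scale parameter is fixed at 1.
#' A fit is flagged non-convergent if the maximum absolute coefficient change
#' fails to drop below `tol` within `max_iter` iterations, if the estimated
#' correlation parameter leaves (-1, 1), or on any numerical failure; no
#' exception is thrown on divergence.
#'
#' @param data a [clustered_data] object.
#' @param structure working correlation structure.
#' @param beta0 starting coefficients; default is the (possibly
#'   non-converged) ML logistic fit.
#' @param alpha0 starting correlation parameter (identity working structure).
#' @param tol convergence tolerance on max |change in beta|.
#' @param max_iter iteration cap.
#' @param fixed_alpha if non-NULL, the correlation parameter is held fixed at
#'   this value and never re-estimated.
#' @return A `gee_fit` object; see [fit_pengee()] for the shared fields.
#' @export
fit_gee <- function(data, structure = "exchangeable", beta0 = NULL,
                    alpha0 = 0, tol = 1e-3, max_iter = 30,
                    fixed_alpha = NULL) {
  structure <- match.arg(structure,
                         c("independent", "exchangeable", "ar1", "unstructured"))
  if (is.null(beta0)) beta0 <- default_start(data)
  eng <- gee_engine(data, structure, beta0, alpha0, tol, max_iter,
                    penalized = FALSE, fixed_alpha = fixed_alpha)
  as_gee_fit(eng, data, structure, "gee")
}

#' @export
print.gee_fit <- function(x, ...) {
  lab <- c(gee = "GEE", pengee = "Penalized GEE",
           auggee = "Iterated augmented GEE",
           auggee1 = "Single-step augmented GEE")[x$method]
  cat(lab, "(", x$structure, "working correlation )\n")
  if (!x$converged) cat("NOT converged:", x$reason, "\n")
  ci <- tryCatch(confint(x), error = function(e) NULL)
  out <- data.frame(estimate = x$beta,
                    se = sqrt(pmax(diag(x$cov_morel), 0)))
  if (!is.null(ci)) { out$ci_low <- ci[, 1L]; out$ci_high <- ci[, 2L] }
  print(out)
  if (x$structure != "independent") {
    a <- if (is.matrix(x$alpha)) "unstructured" else signif(x$alpha, 4)
    cat("alpha:", a, " clusters:", x$N, "\n")
  }
  invisible(x)
}

#' @export
coef.gee_fit <- function(object, ...) object$beta

#' @export
vcov.gee_fit <- function(object, type = c("morel", "sandwich"), ...) {
  type <- match.arg(type)
  if (type == "morel") object$cov_morel else object$cov_sandwich
}
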