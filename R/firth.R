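#' Firth's logistic regression
#'
#' Bias-reduced logistic regression for independent observations: the
#' likelihood is penalized by the Jeffreys invariant prior |I(beta)|^(1/2),
#' which on the score scale adds 1/2 trace(I^-1 dI/dbeta_m) to each score
#' component and guarantees finite coefficient estimates even for separable
#' data. Solved by Newton-Raphson on the modified score with step-halving
#' (up to 5 halvings whenever the penalized log-likelihood would decrease).
#' Supplies starting values and hat diagonals to all GEE-type estimators in
#' the package, which ignore the clustering at this stage.
#'
#' @param X design matrix with leading intercept column (or a
#'   [clustered_data] object, whose clustering is ignored).
#' @param y binary outcomes (omit when `X` is a [clustered_data]).
#' @param weights non-negative scale weights, default 1.
#' @param tol convergence tolerance on max |change in beta|.
#' @param max_iter maximum Newton iterations.
#' @return Object of class `firth_fit`: list with `beta`, `se` (approximate
#'   standard errors, square roots of diag (X'WX)^-1 at the final estimate),
#'   `hat` (leverage h_i, 0 <= h_i <= 1, sum = ncol(X)), `fitted`,
#'   `penalized_loglik`, `converged`, `n_iter`.
#' @export
fit_firth <- function(X, y = NULL, weights = NULL, tol = 1e-6, max_iter = 50) {
  if (inherits(X, "clustered_data")) {
    if (is.null(weights)) weights <- X$weights
    y <- X$y
    X <- X$X
  }
  X <- as.matrix(X)
  n <- nrow(X)
  p1 <- ncol(X)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p1) - 1L)

  qrX <- qr(sqrt(weights + (weights == 0) * 1e-8) * X)
  if (qrX$rank < p1) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p1]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }

  beta <- rep(0, p1)
  pll <- function(beta) {
    pi <- expit(drop(X %*% beta))
    info <- crossprod(X, weights * pi * (1 - pi) * X)
    sum(weights * (y * log(pi) + (1 - y) * log(1 - pi))) +
      0.5 * determinant(info, logarithm = TRUE)$modulus
  }
  ll_old <- pll(beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    pi <- expit(drop(X %*% beta))
    w <- weights * pi * (1 - pi)
    info <- crossprod(X, w * X)
    h <- hat_from_parts(X, w, info)
    # modified score: X'[Q(y - pi) + h(1/2 - pi)]
    U <- crossprod(X, weights * (y - pi) + h * (0.5 - pi))
    step <- solve(info, U)
    fac <- 1
    for (half in 0:5) {
      cand <- beta + fac * step
      ll_new <- pll(cand)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-10) break
      fac <- fac / 2
    }
    delta <- max(abs(cand - beta))
    beta <- cand
    ll_old <- ll_new
    if (delta < tol) { converged <- TRUE; break }
  }

  pi <- expit(drop(X %*% beta))
  w <- weights * pi * (1 - pi)
  info <- crossprod(X, w * X)
  structure(list(
    beta = stats::setNames(drop(beta), colnames(X)),
    se = stats::setNames(sqrt(diag(solve(info))), colnames(X)),
    hat = hat_from_parts(X, w, info),
    fitted = pi,
    penalized_loglik = as.numeric(ll_old),
    converged = converged,
    n_iter = iter
  ), class = "firth_fit")
}

# leverage diagonals given precomputed weights and information matrix
hat_from_parts <- function(X, w, info) {
  B <- sqrt(w) * X
  h <- rowSums((B %*% solve(info)) * B)
  pmin(pmax(h, 0), 1)
}

#' Hat-matrix diagonals for weighted logistic regression
#'
#' Diagonal elements of H = W^(1/2) X (X'WX)^-1 X' W^(1/2) with
#' W = diag(weights * pi * (1 - pi)). Each h_i lies in \[0, 1\] and the
#' diagonals sum to the number of columns of X.
#'
#' @param X design matrix.
#' @param pi fitted probabilities, strictly inside (0, 1).
#' @param weights scale weights, default 1.
#' @return numeric vector of leverages.
#' @export
hat_diagonals <- function(X, pi, weights = NULL) {
  X <- as.matrix(X)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  if (any(pi <= 0 | pi >= 1)) stop("fitted probabilities must be in (0,1)")
  w <- weights * pi * (1 - pi)
  info <- crossprod(X, w * X)
  hat_from_parts(X, w, info)
}

#' @export
print.firth_fit <- function(x, ...) {
  cat("Firth's logistic regression",
      if (x$converged) "(converged" else "(NOT converged",
      paste0("in ", x$n_iter, " iterations)\n"))
  print(data.frame(estimate = x$beta, se = x$se))
  invisible(x)
}

#' @export
coef.firth_fit <- function(object, ...) object$beta

#' Augmented, weighted representation of Firth's logistic regression
#'
#' Builds the 3 N* row pseudo-dataset on which ordinary (weighted) maximum
#' likelihood, iterated together with leverage updates, reproduces the Firth
#' estimate: the original rows with weight 1, a copy with weight h_i/2, and a
#' copy with the outcome flipped and weight h_i/2. The total pseudo-row weight
#' equals sum(h_i) = ncol(X).
#'
#' @param data a [clustered_data] object.
#' @param fit a `firth_fit` carrying hat diagonals for every row.
#' @return list with `y`, `X`, `weights`, and `source_index` mapping each
#'   augmented row to its original row.
#' @export
augment_independent <- function(data, fit) {
  stopifnot(inherits(data, "clustered_data"), inherits(fit, "firth_fit"))
  n <- length(data$y)
  if (length(fit$hat) != n) stop("fit does not carry hat diagonals for every row")
  idx <- rep(seq_len(n), 3L)
  list(
    y = c(data$y, data$y, 1 - data$y),
    X = data$X[idx, , drop = FALSE],
    weights = c(data$weights, fit$hat / 2, fit$hat / 2),
    source_index = idx
  )
}
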