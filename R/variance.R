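# Sandwich covariance S = I0^{-1} I1 I0^{-1} with
#   I0 = sum_i X_i' W_i V_i^{-1} W_i X_i,  I1 = sum_i d_i d_i',
#   d_i = X_i' W_i V_i^{-1} (y_i - pi_i),
# and the Morel small-sample correction
#   S* = I0^{-1} I1* I0^{-1} + delta phi I0^{-1},
#   I1* = (N*-1)/(N*-p-1) * N/(N-1) * sum_i (d_i - dbar)(d_i - dbar)',
#   delta = min(0.5, (p+1)/(N-p-1)),
#   phi = max(1, trace(alpha I0^{-1} I1*)/(p+1)).
# For the augmented estimators these are evaluated on the ORIGINAL data at
# the final (beta, alpha) - not on the augmented pseudo-data.

sandwich_parts <- function(beta, alpha, data, structure) {
  parts <- gee_parts(beta, alpha, data, structure)
  I1 <- crossprod(parts$d)
  list(I0 = parts$I, d = parts$d, I1 = I1)
}

sandwich_from_parts <- function(parts) {
  I0inv <- solve(parts$I0)
  I0inv %*% parts$I1 %*% I0inv
}

# scalar correlation entering phi: the estimate itself for scalar
# structures, 0 for independence, the mean off-diagonal for unstructured
phi_alpha_scalar <- function(alpha, structure) {
  if (structure == "independent") return(0)
  if (is.matrix(alpha)) {
    off <- alpha[upper.tri(alpha)]
    if (!length(off)) 0 else mean(off)
  } else alpha
}

morel_from_parts <- function(parts, data, alpha, structure) {
  N <- data$N
  Nstar <- length(data$y)
  p1 <- ncol(parts$I0)
  if (Nstar <= p1) stop("fewer observations than parameters")
  if (N < 2) stop("Morel correction needs at least 2 clusters")
  if (N <= p1) {
    warning("number of clusters <= number of parameters; delta capped at 0.5")
    delta <- 0.5
  } else {
    delta <- min(0.5, p1 / (N - p1))
  }
  dbar <- colMeans(parts$d)
  Dc <- sweep(parts$d, 2L, dbar)
  I1star <- (Nstar - 1) / (Nstar - p1) * N / (N - 1) * crossprod(Dc)
  I0inv <- solve(parts$I0)
  a <- phi_alpha_scalar(alpha, structure)
  phi <- max(1, a * sum(diag(I0inv %*% I1star)) / p1)
  I0inv %*% I1star %*% I0inv + delta * phi * I0inv
}

#' Sandwich covariance of GEE coefficient estimates
#'
#' The robust variance estimate I0^-1 I1 I0^-1 evaluated at the supplied
#' parameters. For the augmented estimators this should be (and, in the fit
#' objects returned by this package, is) evaluated on the original data, not
#' the augmented pseudo-data.
#'
#' @inheritParams gee_score
#' @return (p+1) x (p+1) covariance matrix.
#' @export
sandwich_cov <- function(beta, alpha, data, structure = "exchangeable") {
  structure <- match.arg(structure,
                         c("independent", "exchangeable", "ar1", "unstructured"))
  sandwich_from_parts(sandwich_parts(beta, alpha, data, structure))
}

#' Morel small-sample corrected sandwich covariance
#'
#' Adds the Morel, Bokossa and Neerchal correction to the sandwich estimate:
#' the meat is mean-centred and inflated by (N*-1)/(N*-p-1) * N/(N-1), and a
#' bread term delta * phi * I0^-1 is added with
#' delta = min(0.5, (p+1)/(N-p-1)) and
#' phi = max(1, trace(alpha I0^-1 I1*) / (p+1)). For the unstructured
#' working correlation the scalar alpha in phi is replaced by the mean
#' off-diagonal estimate.
#'
#' @inheritParams gee_score
#' @return (p+1) x (p+1) covariance matrix.
#' @export
morel_cov <- function(beta, alpha, data, structure = "exchangeable") {
  structure <- match.arg(structure,
                         c("independent", "exchangeable", "ar1", "unstructured"))
  parts <- sandwich_parts(beta, alpha, data, structure)
  morel_from_parts(parts, data, alpha, structure)
}

#' Confidence intervals for GEE fits
#'
#' Symmetric t-based intervals: estimate +/- t-quantile times the Morel
#' corrected standard error, with the number of clusters as degrees of
#' freedom (exactly N, not N - p).
#'
#' @param object a `gee_fit`.
#' @param parm coefficients to include (names or indices); default all.
#' @param level confidence level.
#' @param ... unused.
#' @return matrix with columns `lower` and `upper`.
#' @export
confint.gee_fit <- function(object, parm = NULL, level = 0.95, ...) {
  se <- sqrt(pmax(diag(object$cov_morel), 0))
  q <- stats::qt(1 - (1 - level) / 2, df = object$N)
  ci <- cbind(lower = object$beta - q * se, upper = object$beta + q * se)
  rownames(ci) <- names(object$beta)
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}
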