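# Augmented GEE: Firth-type bias reduction via data augmentation. At the
# current (beta, alpha) each cluster's leverage block
#   H_i = Omega_i^{1/2} X_i (sum_j X_j' Omega_j X_j)^{-1} X_i' Omega_i^{1/2},
#   Omega_i = W_i^{1/2} R_i(alpha)^{-1} W_i^{1/2},
# generalizes the logistic hat matrix (the sum inside the inverse runs over
# ALL clusters; only then does trace(H) = p + 1). Two pseudo clusters per
# original cluster carry the covariates with weights h/2, once with the
# observed outcome and once flipped, and weighted GEE is re-solved on the
# 3N-cluster pseudo-data.

#' Generalized hat matrix for clustered data
#'
#' Per-cluster leverage blocks and their diagonals at the supplied
#' parameters. The symmetric positive-semidefinite square root of Omega_i is
#' used; under the independent structure the diagonals coincide with the
#' ordinary weighted-logistic leverages. The diagonals lie in \[0, 1\] and
#' sum to ncol(X) exactly.
#'
#' @inheritParams gee_score
#' @param keep_blocks also return the n_i x n_i blocks.
#' @return list with `diag` (per-observation leverage) and, optionally,
#'   `blocks`.
#' @export
generalized_hat <- function(beta, alpha, data, structure = "exchangeable",
                            keep_blocks = FALSE) {
  structure <- match.arg(structure,
                         c("independent", "exchangeable", "ar1", "unstructured"))
  X <- data$X
  pi <- expit(drop(X %*% beta))
  w <- data$weights * pi * (1 - pi)

  if (structure == "independent") {
    info <- crossprod(X, w * X)
    h <- hat_from_parts(X, w, info)
    blocks <- NULL
    if (keep_blocks) {
      Minv <- solve(info)
      blocks <- vector("list", data$N)
      pos <- 0L
      for (i in seq_len(data$N)) {
        rows <- pos + seq_len(data$sizes[i]); pos <- pos + data$sizes[i]
        B <- sqrt(w[rows]) * X[rows, , drop = FALSE]
        blocks[[i]] <- B %*% Minv %*% t(B)
      }
    }
    return(list(diag = h, blocks = blocks))
  }

  if (structure == "exchangeable") check_exch_alpha(alpha, max(data$sizes))
  omega <- vector("list", data$N)
  M <- matrix(0, ncol(X), ncol(X))
  pos <- 0L
  for (i in seq_len(data$N)) {
    ni <- data$sizes[i]
    rows <- pos + seq_len(ni); pos <- pos + ni
    si <- sqrt(w[rows])
    Rinv <- if (structure == "exchangeable") {
      c1 <- 1 / (1 - alpha)
      c2 <- alpha / (1 + (ni - 1) * alpha)
      c1 * (diag(ni) - matrix(c2, ni, ni))
    } else {
      solve(working_matrix(structure, alpha, ni))
    }
    Om <- Rinv * tcrossprod(si)
    omega[[i]] <- Om
    M <- M + crossprod(X[rows, , drop = FALSE], Om %*% X[rows, , drop = FALSE])
  }
  Minv <- solve(M)
  h <- numeric(length(pi))
  blocks <- if (keep_blocks) vector("list", data$N) else NULL
  pos <- 0L
  for (i in seq_len(data$N)) {
    ni <- data$sizes[i]
    rows <- pos + seq_len(ni); pos <- pos + ni
    B <- sym_sqrt(omega[[i]]) %*% X[rows, , drop = FALSE]
    K <- B %*% Minv
    h[rows] <- pmin(pmax(rowSums(K * B), 0), 1)
    if (keep_blocks) blocks[[i]] <- K %*% t(B)
  }
  list(diag = h, blocks = blocks)
}

#' Build the augmented pseudo-dataset
#'
#' Stacks three copies of the data: the original clusters with their
#' weights, one pseudo cluster per original cluster with weights h/2 and the
#' observed outcomes, and one with weights h/2 and flipped outcomes. By
#' default the copies form 3N separate clusters (two fresh pseudo clusters
#' per original cluster); `pseudo_clusters = "N"` merges each original
#' cluster with its two pseudo copies instead. The total pseudo-row weight
#' is sum(h) = ncol(X).
#'
#' @param data a [clustered_data] object.
#' @param hat per-observation leverage (a numeric vector or the result of
#'   [generalized_hat()] / a `firth_fit`).
#' @param pseudo_clusters `"3N"` (default) or `"N"`.
#' @return A [clustered_data] object with the augmented rows and a
#'   `source_index` attribute mapping each row to its original row.
#' @export
build_augmented <- function(data, hat, pseudo_clusters = c("3N", "N")) {
  pseudo_clusters <- match.arg(pseudo_clusters)
  if (is.list(hat)) hat <- if (!is.null(hat$diag)) hat$diag else hat$hat
  if (inherits(hat, "firth_fit")) hat <- hat$hat
  n <- length(data$y)
  if (length(hat) != n) stop("need one hat diagonal per observation")
  labs <- data$cluster_labels[data$cluster]
  cl <- if (pseudo_clusters == "3N") {
    c(labs, paste0(labs, " +copy"), paste0(labs, " -copy"))
  } else {
    c(labs, labs, labs)
  }
  idx <- rep(seq_len(n), 3L)
  out <- clustered_data(
    y = c(data$y, data$y, 1 - data$y),
    X = data$X[idx, , drop = FALSE],
    cluster = cl,
    weights = c(data$weights, hat / 2, hat / 2)
  )
  attr(out, "source_index") <- idx
  out
}

#' Iterated augmented GEE
#'
#' Starting from the Firth logistic estimate (clustering ignored) and an
#' identity working correlation, each outer iteration recomputes the
#' generalized hat matrix at the current (beta, alpha), rebuilds the
#' augmented 3N-cluster dataset, and re-solves weighted GEE on it
#' (warm-started at the current beta, at most `inner_max` iterations).
#' Outer convergence requires max |change in beta| < `tol` within
#' `max_outer` iterations; the fit is flagged non-convergent if that fails,
#' if the final inner solve fails, or if the correlation estimate leaves
#' (-1, 1). The reported covariance matrices are the sandwich and Morel
#' estimates on the ORIGINAL data at the final (beta, alpha). With an
#' independent working structure the estimate equals Firth's logistic
#' regression.
#'
#' @inheritParams fit_gee
#' @param max_outer outer iteration cap.
#' @param inner_max iteration cap for each inner weighted GEE solve.
#' @param pseudo_clusters cluster layout of the augmented data, see
#'   [build_augmented()].
#' @return A `gee_fit` object (`n_outer` outer iterations; `n_inner` from
#'   the last inner solve).
#' @export
fit_auggee <- function(data, structure = "exchangeable", tol = 1e-3,
                       max_outer = 20, inner_max = 30,
                       pseudo_clusters = "3N", fixed_alpha = NULL) {
  structure <- match.arg(structure,
                         c("independent", "exchangeable", "ar1", "unstructured"))
  fl <- tryCatch(fit_firth(data), error = function(e) e)
  if (inherits(fl, "error")) {
    return(failed_fit(data, structure, "auggee", conditionMessage(fl)))
  }
  beta <- unname(fl$beta)
  alpha_cur <- if (!is.null(fixed_alpha)) fixed_alpha else 0
  outer_ok <- FALSE
  inner_ok <- TRUE          # every inner solve must itself converge
  inner <- NULL
  reason <- NA_character_
  k <- 0L
  for (k in seq_len(max_outer)) {
    hat <- tryCatch(generalized_hat(beta, alpha_cur, data, structure),
                    error = function(e) e)
    if (inherits(hat, "error")) { reason <- conditionMessage(hat); break }
    aug <- build_augmented(data, hat$diag, pseudo_clusters)
    inner <- gee_engine(aug, structure, beta0 = beta, alpha0 = alpha_cur,
                        tol = tol, max_iter = inner_max,
                        fixed_alpha = fixed_alpha)
    if (!inner$converged) {
      inner_ok <- FALSE
      if (is.na(reason)) reason <- inner$reason
    }
    delta <- max(abs(inner$beta - beta))
    beta <- inner$beta
    alpha_cur <- inner$alpha
    if (any(!is.finite(beta))) { reason <- "divergent update"; break }
    if (delta < tol) { outer_ok <- TRUE; break }
  }
  conv <- outer_ok && inner_ok
  if (is.na(reason) && !outer_ok) reason <- "outer iteration limit reached"
  eng <- list(beta = beta, alpha = alpha_cur, converged = conv,
              criterion_met = outer_ok,
              alpha_ok = is.null(inner) || inner$alpha_ok,
              reason = if (conv) NA_character_ else reason,
              n_iter = if (is.null(inner)) 0L else inner$n_iter,
              trace = if (is.null(inner)) NULL else inner$trace)
  as_gee_fit(eng, data, structure, "auggee", n_outer = k)
}

#' Single-step augmented GEE
#'
#' Firth's logistic regression is fitted ignoring the clustering, the data
#' are augmented once using the ORDINARY hat diagonals from that fit
#' (weights h/2, outcome kept / flipped, 3N clusters), and a single weighted
#' GEE solve on the augmented data — warm-started at the Firth estimate —
#' gives the final coefficients and correlation parameter. Equivalent to
#' stopping the iterated algorithm after one outer iteration with the
#' ordinary hat matrix. With an independent working structure the result is
#' Firth's logistic regression itself, so this variant always returns finite
#' estimates and serves as the fallback estimator in the simulation harness.
#' Covariances are evaluated on the original data.
#'
#' @inheritParams fit_auggee
#' @param max_iter iteration cap for the single weighted GEE solve.
#' @return A `gee_fit` object.
#' @export
fit_auggee1 <- function(data, structure = "exchangeable", tol = 1e-3,
                        max_iter = 30, pseudo_clusters = "3N",
                        fixed_alpha = NULL) {
  structure <- match.arg(structure,
                         c("independent", "exchangeable", "ar1", "unstructured"))
  fl <- tryCatch(fit_firth(data), error = function(e) e)
  if (inherits(fl, "error")) {
    return(failed_fit(data, structure, "auggee1", conditionMessage(fl)))
  }
  aug <- build_augmented(data, fl$hat, pseudo_clusters)
  eng <- gee_engine(aug, structure, beta0 = unname(fl$beta), alpha0 = 0,
                    tol = tol, max_iter = max_iter, fixed_alpha = fixed_alpha)
  as_gee_fit(eng, data, structure, "auggee1", n_outer = 1L)
}

# placeholder fit when even the Firth initializer fails
failed_fit <- function(data, structure, method, reason) {
  eng <- list(beta = rep(NA_real_, ncol(data$X)), alpha = NA_real_,
              converged = FALSE, criterion_met = FALSE, alpha_ok = FALSE,
              reason = reason, n_iter = 0L, trace = NULL)
  as_gee_fit(eng, data, structure, method)
}
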