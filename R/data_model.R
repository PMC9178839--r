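#' Clustered binary-outcome data
#'
#' Container for long-format clustered data used by all estimators in the
#' package: a binary outcome, a design matrix with a leading intercept column,
#' a cluster identifier and optional non-negative per-observation scale
#' weights. Rows are canonicalized to be contiguous by cluster, preserving
#' the first-appearance order of cluster identifiers and the within-cluster
#' row order from the input (the latter matters for the AR(1) working
#' structure).
#'
#' @param y binary outcome vector, values in \{0, 1\}.
#' @param X covariate matrix (without intercept) or design matrix whose first
#'   column is an intercept column of ones; column names are kept.
#' @param cluster vector of cluster identifiers, one per observation.
#' @param weights optional non-negative scale weights, default 1. Weights act
#'   as per-observation scale factors multiplying each observation's
#'   contribution to the estimating equations (the PROC GEE / geem2 dialect).
#'
#' @return An object of class `clustered_data`: a list with elements
#'   `y`, `X` (design matrix including intercept), `cluster` (integer index
#'   1..N), `cluster_labels`, `weights`, `N` (number of clusters) and
#'   `sizes` (observations per cluster; clusters of size 1 are allowed).
#' @export
clustered_data <- function(y, X, cluster, weights = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  storage.mode(X) <- "double"
  n <- length(y)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (length(cluster) != n) stop("length(cluster) must equal length(y)")
  if (any(is.na(cluster)) || any(!nzchar(as.character(cluster)))) {
    stop("empty or missing cluster identifiers")
  }
  bad <- which(!(y %in% c(0, 1)))
  if (length(bad)) {
    stop("outcome must be coded 0/1; offending rows: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) ", ..." else "")
  }
  y <- as.numeric(y)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(is.na(weights)) || any(weights < 0)) {
    stop("weights must be non-negative and one per observation")
  }

  has_icpt <- ncol(X) >= 1L && all(X[, 1L] == 1)
  if (!has_icpt) {
    X <- cbind("(Intercept)" = 1, X)
  } else if (is.null(colnames(X)) || colnames(X)[1L] == "") {
    cn <- colnames(X)
    if (is.null(cn)) cn <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1L)))
    cn[1L] <- "(Intercept)"
    colnames(X) <- cn
  }
  if (is.null(colnames(X))) {
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1L)))
  }

  # canonical order: clusters in first-appearance order, contiguous
  f <- factor(cluster, levels = unique(cluster))
  ord <- order(as.integer(f))  # stable: keeps within-cluster order
  idx <- as.integer(f)[ord]
  out <- structure(list(
    y = y[ord],
    X = X[ord, , drop = FALSE],
    cluster = idx,
    cluster_labels = levels(f),
    weights = as.numeric(weights)[ord],
    N = nlevels(f),
    sizes = as.integer(tabulate(idx, nlevels(f)))
  ), class = "clustered_data")
  out
}

#' @export
print.clustered_data <- function(x, ...) {
  cat("Clustered binary dataset:", length(x$y), "observations in", x$N,
      "clusters\n")
  cat("  cluster sizes: min", min(x$sizes), "/ median", stats::median(x$sizes),
      "/ max", max(x$sizes), "\n")
  cat("  event rate:", signif(mean(x$y), 3), "\n")
  cat("  covariates:", paste(colnames(x$X)[-1L], collapse = ", "), "\n")
  invisible(x)
}

#' Read long-format clustered data from a delimited file
#'
#' Reads a CSV (or TSV, chosen by file extension) with a header row and
#' builds a validated [clustered_data] object with an intercept column
#' prepended to the requested covariates.
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated.
#' @param cluster_col,outcome_col names of the cluster-id and outcome columns.
#' @param covariate_cols character vector of covariate column names.
#' @param weight_col optional name of a scale-weight column.
#' @return A [clustered_data] object.
#' @export
read_clustered <- function(path, cluster_col, outcome_col, covariate_cols,
                           weight_col = NULL) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(cluster_col, outcome_col, covariate_cols, weight_col)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("columns not found: ", paste(miss, collapse = ", "))
  yraw <- df[[outcome_col]]
  bad <- which(!(yraw %in% c(0, 1)))
  if (length(bad)) {
    stop("non-binary outcome in column '", outcome_col, "'; rows: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  w <- if (is.null(weight_col)) NULL else df[[weight_col]]
  clustered_data(y = yraw,
                 X = as.matrix(df[covariate_cols]),
                 cluster = df[[cluster_col]],
                 weights = w)
}

#' Write clustered data back to CSV
#'
#' Inverse of [read_clustered()]: writes one row per observation with the
#' cluster label, outcome, covariates (intercept dropped) and weights.
#'
#' @param data a [clustered_data] object.
#' @param path output file path (CSV).
#' @export
write_clustered <- function(data, path) {
  df <- data.frame(cluster = data$cluster_labels[data$cluster],
                   y = data$y,
                   data$X[, -1L, drop = FALSE],
                   weights = data$weights,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Working correlation matrix
#'
#' Builds the n-by-n working correlation matrix R(alpha) for one cluster.
#' Supported structures: `independent` (identity), `exchangeable` (constant
#' off-diagonal alpha), `ar1` (alpha^|j-k|) and `unstructured` (alpha is the
#' full correlation matrix, recycled to the leading n-by-n block).
#'
#' @param structure one of `"independent"`, `"exchangeable"`, `"ar1"`,
#'   `"unstructured"`.
#' @param alpha correlation parameter: scalar for exchangeable/ar1, a
#'   correlation matrix for unstructured, ignored for independent.
#' @param n cluster size (>= 1).
#' @param check if `TRUE`, error when the requested matrix is not positive
#'   definite (a working correlation approaching singularity).
#' @return n-by-n symmetric unit-diagonal matrix.
#' @export
working_matrix <- function(structure, alpha = NULL, n, check = TRUE) {
  structure <- match.arg(structure,
                         c("independent", "exchangeable", "ar1", "unstructured"))
  if (n < 1) stop("n must be >= 1")
  R <- switch(structure,
    independent = diag(n),
    exchangeable = {
      R <- matrix(alpha, n, n); diag(R) <- 1; R
    },
    ar1 = {
      d <- abs(outer(seq_len(n), seq_len(n), "-"))
      alpha^d
    },
    unstructured = {
      if (!is_square(alpha) || nrow(alpha) < n) {
        stop("unstructured alpha must be a correlation matrix of size >= n")
      }
      R <- alpha[seq_len(n), seq_len(n), drop = FALSE]
      diag(R) <- 1
      (R + t(R)) / 2
    })
  if (check && n > 1L) {
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10) {
      stop("working correlation matrix is singular or not positive definite",
           " (structure '", structure, "', n = ", n, ")")
    }
  }
  R
}

#' Export fit results as a tidy table
#'
#' One row per coefficient with estimate, sandwich and Morel standard errors,
#' t-based 95% confidence limits and the method tag.
#'
#' @param fit a `gee_fit` or `firth_fit` object.
#' @param path optional CSV path; when supplied the table is also written.
#' @param level confidence level.
#' @return Invisibly (when writing) or visibly, a `data.frame`.
#' @export
tidy_results <- function(fit, path = NULL, level = 0.95) {
  est <- coef(fit)
  if (inherits(fit, "gee_fit")) {
    ses <- sqrt(pmax(diag(fit$cov_sandwich), 0))
    sem <- sqrt(pmax(diag(fit$cov_morel), 0))
    ci <- confint(fit, level = level)
    df <- data.frame(term = names(est), estimate = unname(est),
                     se_sandwich = unname(ses), se_morel = unname(sem),
                     ci_low = unname(ci[, 1L]), ci_high = unname(ci[, 2L]),
                     method = fit$method)
  } else {
    q <- stats::qnorm(1 - (1 - level) / 2)
    df <- data.frame(term = names(est), estimate = unname(est),
                     se_sandwich = NA_real_, se_morel = NA_real_,
                     ci_low = unname(est - q * fit$se),
                     ci_high = unname(est + q * fit$se),
                     method = "firth")
  }
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
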