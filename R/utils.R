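# Internal numerical helpers shared by the estimators.

# Linear predictors are clamped so fitted probabilities stay strictly inside
# (0,1); beyond |eta| = 30 the probability is within 1e-13 of the boundary and
# the working variance would underflow to exact zero.
.ETA_CLAMP <- 30

expit <- function(eta) stats::plogis(pmin(pmax(eta, -.ETA_CLAMP), .ETA_CLAMP))

# symmetric PSD matrix square root via eigendecomposition
sym_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  val <- pmax(e$values, 0)
  e$vectors %*% (sqrt(val) * t(e$vectors))
}

# sum of `x` (vector or matrix columns) within groups, returned per group
# in first-appearance order of `g` (an integer index 1..N)
group_rowsum <- function(x, g, N) {
  rowsum(x, group = g, reorder = FALSE)
}

is_square <- function(M) is.matrix(M) && nrow(M) == ncol(M)

# Phase-1 (feasibility) simplex for { D mu = d, mu >= 0 } with Bland's
# anti-cycling rule: rows with negative d are flipped, one artificial
# variable per row forms the starting basis, and the sum of artificials is
# minimized. Returns the phase-1 optimum (zero iff feasible) and the final
# simplex multipliers `y` (in the ORIGINAL row space), which certify
# infeasibility when the optimum is positive: D'y <= 0 and d'y > 0.
phase1_feasibility <- function(D, d, eps = 1e-9, max_pivots = 1e5) {
  m <- nrow(D); n <- ncol(D)
  flip <- d < 0
  if (any(flip)) {
    D[flip, ] <- -D[flip, , drop = FALSE]
    d[flip] <- -d[flip]
  }
  Tb <- cbind(D, diag(m), d)
  basis <- n + seq_len(m)
  red <- c(rep(0, n), rep(1, m), 0) - colSums(Tb)
  it <- 0L
  repeat {
    j <- which(red[seq_len(n + m)] < -eps)
    if (!length(j)) break
    j <- j[1L]                                 # Bland: lowest eligible index
    col <- Tb[, j]
    pos <- which(col > eps)
    if (!length(pos)) stop("LP failure: unbounded phase-1 problem")
    ratio <- Tb[pos, n + m + 1L] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + eps]
    i <- cand[which.min(basis[cand])]          # Bland: lowest leaving index
    Ti <- Tb[i, ] / Tb[i, j]
    Tb <- Tb - tcrossprod(col, Ti)
    Tb[i, ] <- Ti
    red <- red - red[j] * Ti
    basis[i] <- j
    it <- it + 1L
    if (it >= max_pivots) stop("LP failure: pivot limit reached")
  }
  y <- unname(1 - red[n + seq_len(m)])
  y[flip] <- -y[flip]
  list(value = unname(-red[n + m + 1L]), y = y)
}
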