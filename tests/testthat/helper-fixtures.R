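# Fixture builders shared across the suite. All randomness is seeded at the
# call site so every test is reproducible in isolation.

# small random clustered dataset with mild dependence through a shared
# cluster effect; guaranteed to contain both outcome levels
random_clustered <- function(seed, n_clusters = 8, mean_size = 4, p = 2,
                             beta = NULL, weights = FALSE) {
  set.seed(seed)
  repeat {
    sizes <- pmax(1L, rpois(n_clusters, mean_size))
    n <- sum(sizes)
    cl <- rep.int(seq_len(n_clusters), sizes)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    X[, 1] <- rbinom(n, 1, 0.4)
    if (is.null(beta)) beta <- c(-0.4, rep(0.6, p))
    eta <- drop(cbind(1, X) %*% beta) + rep(rnorm(n_clusters, 0, 0.7), sizes)
    y <- rbinom(n, 1, plogis(eta))
    if (any(y == 0) && any(y == 1)) break
  }
  w <- if (weights) runif(n, 0.5, 2) else NULL
  clustered_data(y, X, cl, weights = w)
}

# deterministic quasi-completely separated dataset: the rare binary
# covariate z carries no events
separated_clustered <- function(n_clusters = 10, size = 4) {
  n <- n_clusters * size
  cl <- rep.int(seq_len(n_clusters), rep(size, n_clusters))
  set.seed(99)
  z <- as.numeric(cl <= 2)                       # rare, cluster-constant
  x <- round(rnorm(n), 2)
  y <- ifelse(z == 1, 0, rbinom(n, 1, 0.45))
  while (all(y[z == 0] == 0)) y[z == 0] <- rbinom(sum(z == 0), 1, 0.45)
  clustered_data(y, cbind(z = z, x = x), cl)
}

# brute-force evaluation of the estimating function, information, cluster
# scores and the sandwich/Morel formulas by explicit per-cluster matrix
# algebra (independent of the package's vectorized path)
brute_gee <- function(beta, alpha, data, structure) {
  X <- data$X; y <- data$y; wts <- data$weights
  p1 <- ncol(X)
  pi <- plogis(drop(X %*% beta))
  I0 <- matrix(0, p1, p1)
  U <- numeric(p1)
  d <- matrix(0, data$N, p1)
  pos <- 0L
  for (i in seq_len(data$N)) {
    ni <- data$sizes[i]
    rows <- pos + seq_len(ni); pos <- pos + ni
    Xi <- X[rows, , drop = FALSE]
    Delta <- diag(pi[rows] * (1 - pi[rows]), ni)
    Q <- diag(wts[rows], ni)
    R <- working_matrix(structure, alpha, ni)
    Vi <- sqrt(Delta) %*% solve(sqrt(Q)) %*% R %*% solve(sqrt(Q)) %*% sqrt(Delta)
    Di <- Delta %*% Xi
    di <- drop(t(Di) %*% solve(Vi, y[rows] - pi[rows]))
    d[i, ] <- di
    U <- U + di
    I0 <- I0 + t(Di) %*% solve(Vi) %*% Di
  }
  I1 <- t(d) %*% d
  S <- solve(I0) %*% I1 %*% solve(I0)
  N <- data$N; Nstar <- length(y)
  dbar <- colMeans(d)
  Dc <- sweep(d, 2, dbar)
  I1s <- (Nstar - 1) / (Nstar - p1) * N / (N - 1) * (t(Dc) %*% Dc)
  delta <- min(0.5, p1 / (N - p1))
  a <- if (structure == "independent") 0 else alpha
  phi <- max(1, a * sum(diag(solve(I0) %*% I1s)) / p1)
  Sstar <- solve(I0) %*% I1s %*% solve(I0) + delta * phi * solve(I0)
  list(U = U, I0 = I0, I1 = I1, d = d, S = S, Sstar = Sstar,
       delta = delta, phi = phi)
}
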