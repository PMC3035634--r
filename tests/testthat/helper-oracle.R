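# Independent oracles. These deliberately avoid the package's likelihood
# machinery: the mixed-model oracle builds the full N x N marginal
# covariance from explicit design matrices and maximizes the dense
# multivariate-normal likelihood by direct optimization; the BH oracle is a
# literal transcription of the step-up definition.

# Dense-likelihood oracle for the set-level model (ML). Observations are
# stacked gene-fastest within sample, matching as.vector(Y).
oracle_dense_ml <- function(Y, group, batch, subject, E = NULL) {
  G <- nrow(Y); n <- ncol(Y); N <- G * n
  y <- as.vector(Y)
  X <- cbind(1, rep(as.numeric(group == "case"), each = G))
  Zs <- stats::model.matrix(~ 0 + f, data.frame(f = factor(rep(subject, each = G))))
  use_batch <- length(unique(batch)) > 1L
  Zb <- if (use_batch) {
    stats::model.matrix(~ 0 + f, data.frame(f = factor(rep(batch, each = G))))
  } else NULL
  K <- if (is.null(E)) 0L else ncol(E)
  Zk <- lapply(seq_len(K), function(k) {
    m <- matrix(0, N, n)
    for (s in seq_len(n)) m[(s - 1L) * G + seq_len(G), s] <- E[, k]
    m
  })
  nll <- function(th) {
    v <- exp(th)
    V <- diag(rep(v[1L], N)) + v[2L] * tcrossprod(Zs)
    i <- 3L
    if (use_batch) { V <- V + v[i] * tcrossprod(Zb); i <- i + 1L }
    for (k in seq_len(K)) { V <- V + v[i] * tcrossprod(Zk[[k]]); i <- i + 1L }
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    ViY <- backsolve(R, backsolve(R, cbind(y, X), transpose = TRUE))
    A <- crossprod(X, ViY[, -1L, drop = FALSE])
    b <- crossprod(X, ViY[, 1L])
    beta <- solve(A, b)
    quad <- sum(y * ViY[, 1L]) - sum(b * beta)
    0.5 * (N * log(2 * pi) + 2 * sum(log(diag(R))) + quad)
  }
  npar <- 2L + as.integer(use_batch) + K
  vt <- stats::var(y)
  starts <- list(log(rep(0.5 * vt, npar)),
                 log(c(0.9 * vt, rep(0.05 * vt, npar - 1L))),
                 log(rep(0.1 * vt, npar)))
  best <- NULL
  for (st in starts) {
    o <- stats::optim(st, nll, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-13))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best <- stats::optim(best$par, nll, method = "Nelder-Mead",
                       control = list(maxit = 4000, reltol = 1e-13))
  v <- exp(best$par)
  V <- diag(rep(v[1L], N)) + v[2L] * tcrossprod(Zs)
  i <- 3L
  if (use_batch) { V <- V + v[i] * tcrossprod(Zb); i <- i + 1L }
  for (k in seq_len(K)) { V <- V + v[i] * tcrossprod(Zk[[k]]); i <- i + 1L }
  Vi <- solve(V)
  beta <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y))
  list(loglik = -best$value, beta = drop(beta), theta = v)
}

# Literal step-up BH: adjusted_(i) = min_{j >= i} min(1, m p_(j) / j)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(m * sp[i:m] / seq(i, m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Closed-form pooled two-sample t-test
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(t), df = n1 + n2 - 2)
}

# Closed-form Welch t-test
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(t), df = df)
}

# Rebuild the eigenvector basis exactly as the fitter selects it, so the
# oracle sees the same loadings.
fitted_basis <- function(Y, meta, K_fit) {
  if (K_fit == 0L) return(NULL)
  eb <- gene_correlation_eigen(center_by_group(Y, meta),
                               K_max = min(dim(Y)))
  eb$loadings[, seq_len(K_fit), drop = FALSE]
}
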