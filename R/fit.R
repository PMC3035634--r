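#' Model specification for the set-level mixed model
#'
#' @param K_max Maximum number of eigenvector random-effect components
#'   (default 5). The fitted number is `min(K_max, K_signal, rank)`, where
#'   `K_signal` counts the correlation eigenvalues above the
#'   Marchenko-Pastur noise edge `(1 + sqrt(G/df))^2` for a sample
#'   correlation matrix with `df = n - 2` residual degrees of freedom;
#'   weaker components are indistinguishable from sampling noise and
#'   conditioning on them anti-conserves the group test. `K_max = 0` drops
#'   the eigenvector terms entirely.
#' @param variance_floor Lower bound for every variance component
#'   (default 1e-8); boundary fits are valid and mean the component is
#'   effectively absent.
#' @param test `"LRT"` (default): likelihood-ratio test of the group effect
#'   with both nested models refit by full maximum likelihood, referred to
#'   chi-square with 1 df. `"Wald"`: the REML-based Wald statistic referred
#'   to a t distribution with between-within denominator degrees of freedom
#'   (number of subjects minus 2), which reduces exactly to the pooled
#'   two-sample t-test in the single-gene, single-batch case.
#' @param include_batch Include the batch random intercept when the design
#'   has more than one batch (default TRUE).
#' @param factor_variance `"per_component"` (default): each retained
#'   eigenvector gets its own variance. `"shared"`: component variances are
#'   tied to the eigenvalue profile, `sigma_c^2 * lambda_k`, with a single
#'   free scale (factor covariance proportional to the estimated
#'   correlation structure).
#' @param max_iter Iteration budget for each variance-component
#'   optimization (default 500).
#' @param n_starts Number of optimizer starting points (default 2).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(K_max = 5L, variance_floor = 1e-8,
                       test = c("LRT", "Wald"), include_batch = TRUE,
                       factor_variance = c("per_component", "shared"),
                       max_iter = 500L, n_starts = 2L) {
  test <- match.arg(test)
  factor_variance <- match.arg(factor_variance)
  if (K_max < 0L) stop("K_max must be >= 0", call. = FALSE)
  if (variance_floor < 0) stop("variance_floor must be >= 0", call. = FALSE)
  structure(list(K_max = as.integer(K_max), variance_floor = variance_floor,
                 test = test, include_batch = isTRUE(include_batch),
                 factor_variance = factor_variance,
                 max_iter = as.integer(max_iter),
                 n_starts = as.integer(n_starts)),
            class = "model_spec")
}

# ---------------------------------------------------------------------------
# Marginal likelihood machinery.
#
# Model, in long form over observations (gene g, sample s):
#   y_gs = mu + beta * I[case(s)] + b_batch(s) + u_subject(s)
#          + sum_k a_{s,k} E_{g,k} + eps_gs
# The marginal covariance of the stacked data is
#   V = I_n (x) Sigma0  +  sum_w d_w m_w m_w',
# where Sigma0 = sigma^2 I_G + E diag(sigma_k^2) E' is the per-sample
# gene-gene block, and each w is one batch or subject level with a scalar
# effect shared by all genes of its samples (m_w = indicator (x) 1_G).
# Because E has orthonormal columns, Sigma0 inverts in closed form, and the
# batch/subject part is a low-rank update handled by Woodbury identities, so
# each likelihood evaluation costs O(GnK + n_w^3) with n_w = #batches +
# #subjects. Fixed-effect columns are constant within a sample, which
# collapses all X-quadratics onto per-sample scalars.
# ---------------------------------------------------------------------------

# E: orthonormal loading columns. eigen_scale: when non-NULL (length K),
# the K component variances are tied as sigma_c^2 * eigen_scale_k with a
# single free parameter sigma_c^2 (factor covariance proportional to
# E diag(eigen_scale) E'); when NULL each component has its own variance.
mm_prepare <- function(Y, case, subject, batch = NULL, E = NULL,
                       floor = 1e-8, eigen_scale = NULL) {
  G <- nrow(Y); n <- ncol(Y)
  K <- if (is.null(E)) 0L else ncol(E)
  if (K == 0L) eigen_scale <- NULL
  subject <- factor(subject)
  S <- stats::model.matrix(~ 0 + subject)
  use_batch <- !is.null(batch)
  if (use_batch) {
    batch <- factor(batch)
    if (nlevels(batch) < 2L) use_batch <- FALSE
  }
  Bm <- if (use_batch) stats::model.matrix(~ 0 + batch) else NULL
  M <- if (use_batch) cbind(Bm, S) else S
  wtype <- c(if (use_batch) rep(1L, ncol(Bm)), rep(2L, ncol(S)))
  Xf <- cbind(1, as.numeric(case))
  X0 <- Xf[, 1L, drop = FALSE]
  list(G = G, n = n, N = G * n, K = K, Y = Y, E = E,
       eigen_scale = eigen_scale,
       cs = colSums(Y), yy_tot = sum(Y * Y),
       EtY = if (K) crossprod(E, Y) else NULL,
       e1 = if (K) colSums(E) else NULL,
       M = M, MtM = crossprod(M), wtype = wtype, use_batch = use_batch,
       idx_b = if (use_batch) seq_len(ncol(Bm)) else integer(0),
       idx_s = (if (use_batch) ncol(Bm) else 0L) + seq_len(ncol(S)),
       X = list(full = Xf, null = X0),
       XtX = list(full = crossprod(Xf), null = crossprod(X0)),
       MtX = list(full = crossprod(M, Xf), null = crossprod(M, X0)),
       floor = max(floor, 1e-12),
       vtot = max(stats::var(as.numeric(Y)), 1e-8))
}

# theta = log variances: [resid, subject, (batch), factor_1..K] with
# per-component factor variances, or [resid, subject, (batch), factor]
# when the component variances are tied via eigen_scale
mm_nfac <- function(pre) {
  if (pre$K == 0L) 0L else if (is.null(pre$eigen_scale)) pre$K else 1L
}
mm_npar <- function(pre) 2L + as.integer(pre$use_batch) + mm_nfac(pre)

mm_sk <- function(pre, th) {
  if (pre$K == 0L) return(numeric(0))
  off <- 2L + as.integer(pre$use_batch)
  if (is.null(pre$eigen_scale)) {
    exp(th[off + seq_len(pre$K)])
  } else {
    exp(th[off + 1L]) * pre$eigen_scale
  }
}

mm_eval <- function(pre, th, model = "full", reml = FALSE) {
  G <- pre$G; n <- pre$n; N <- pre$N; K <- pre$K
  s2 <- exp(th[1L]); su <- exp(th[2L])
  sb <- if (pre$use_batch) exp(th[3L]) else NULL
  sk <- mm_sk(pre, th)
  if (K) {
    lam <- sk / (s2 + sk)
    q <- (G - sum(lam * pre$e1^2)) / s2
    ts <- (pre$cs - colSums(pre$EtY * (lam * pre$e1))) / s2
    yy <- (pre$yy_tot - sum(lam * rowSums(pre$EtY^2))) / s2
    ld0 <- (G - K) * log(s2) + sum(log(s2 + sk))
  } else {
    q <- G / s2
    ts <- pre$cs / s2
    yy <- pre$yy_tot / s2
    ld0 <- G * log(s2)
  }
  dw <- numeric(length(pre$wtype))
  dw[pre$wtype == 2L] <- su
  if (pre$use_batch) dw[pre$wtype == 1L] <- sb
  Cw <- q * pre$MtM
  diag(Cw) <- diag(Cw) + 1 / dw
  R <- chol(Cw)
  dR <- diag(R)
  if (!all(is.finite(dR)) || min(dR) <= max(dR) * 1e-10) {
    stop("ill-conditioned covariance", call. = FALSE)
  }
  Xs <- pre$X[[model]]
  A0 <- q * pre$XtX[[model]]
  b0 <- crossprod(Xs, ts)
  wy <- crossprod(pre$M, ts)
  wX <- q * pre$MtX[[model]]
  uy <- backsolve(R, wy, transpose = TRUE)
  uX <- backsolve(R, wX, transpose = TRUE)
  A <- A0 - crossprod(uX)
  b <- b0 - crossprod(uX, uy)
  yVy <- yy - sum(uy^2)
  logdetV <- n * ld0 + sum(log(dw)) + 2 * sum(log(diag(R)))
  Ach <- chol(A)
  beta <- backsolve(Ach, backsolve(Ach, b, transpose = TRUE))
  quad <- yVy - sum(b * beta)
  p <- ncol(Xs)
  ll <- if (reml) {
    -0.5 * ((N - p) * log(2 * pi) + logdetV + 2 * sum(log(diag(Ach))) + quad)
  } else {
    -0.5 * (N * log(2 * pi) + logdetV + quad)
  }
  Ainv <- chol2inv(Ach)
  list(ll = ll, beta = drop(beta), vcov_beta = Ainv, quad = quad,
       logdetV = logdetV,
       state = list(s2 = s2, su = su, sb = sb, sk = sk,
                    lam = if (K) lam else numeric(0), q = q, R = R,
                    model = model, reml = reml))
}

# Analytic gradient of the negative log-likelihood with respect to the log
# variances, sharing the Woodbury/low-rank structure of mm_eval. Uses the
# standard identities d(-ll)/d v_i = (tr(P G_i) - y'P G_i P y)/2 (REML) and
# (tr(V^-1 G_i) - y'P G_i P y)/2 (ML), with G_i = dV/d v_i, specialized so
# that no N x N object is ever formed.
mm_grad <- function(pre, th, ev) {
  st <- ev$state
  G <- pre$G; n <- pre$n; K <- pre$K
  s2 <- st$s2; su <- st$su; sb <- st$sb; sk <- st$sk; lam <- st$lam
  q <- st$q
  E <- pre$E
  u_vec <- if (K) (1 - drop(E %*% (lam * pre$e1))) / s2 else
    rep(1 / s2, G)
  uu <- sum(u_vec^2)
  uE <- if (K) pre$e1 * (1 - lam) / s2 else numeric(0)
  trS0 <- if (K) (G - sum(lam)) / s2 else G / s2
  tk <- if (K) (1 - lam) / s2 else numeric(0)
  Ci <- chol2inv(st$R)
  Xs <- pre$X[[st$model]]
  p <- ncol(Xs)

  # residual field Py, held as a G x n matrix
  fitted_s <- drop(Xs %*% ev$beta)
  Emat <- pre$Y - matrix(fitted_s, G, n, byrow = TRUE)
  if (K) {
    EtE <- pre$EtY - outer(pre$e1, fitted_s)
    Tm <- (Emat - E %*% (lam * EtE)) / s2
  } else {
    Tm <- Emat / s2
  }
  cs_T <- colSums(Tm)
  h <- Ci %*% crossprod(pre$M, cs_T)
  m_vec <- drop(pre$M %*% h)
  Rm <- Tm - outer(u_vec, m_vec)
  colR <- colSums(Rm)
  MtR <- drop(crossprod(pre$M, colR))
  quad_res <- sum(Rm * Rm)
  quad_subj <- sum(MtR[pre$idx_s]^2)
  quad_batch <- if (pre$use_batch) sum(MtR[pre$idx_b]^2) else 0
  quad_k <- if (K) rowSums(crossprod(E, Rm)^2) else numeric(0)

  # tr(V^-1 G_i) = base_i - tr(Ci %*% F_i)
  CiM <- Ci * pre$MtM             # elementwise: used for tr(Ci * (c*MtM))
  tr_ci_mtm <- sum(CiM)
  Ms <- pre$MtM[, pre$idx_s, drop = FALSE]
  tr_subj <- q * n - st$q^2 * sum((Ci %*% Ms) * Ms)
  tr_res <- n * trS0 - uu * tr_ci_mtm
  tr_batch <- if (pre$use_batch) {
    Mb <- pre$MtM[, pre$idx_b, drop = FALSE]
    q * n - q^2 * sum((Ci %*% Mb) * Mb)
  } else 0
  tr_k <- if (K) n * tk - uE^2 * tr_ci_mtm else numeric(0)

  if (st$reml) {
    # subtract tr(A^-1 X'V^-1 G_i V^-1 X); V^-1 x_j = u_vec (x) g_j
    Gm <- Xs - pre$M %*% (Ci %*% (q * pre$MtX[[st$model]]))
    GtG <- crossprod(Gm)
    StG <- crossprod(pre$M[, pre$idx_s, drop = FALSE], Gm)
    Ainv <- ev$vcov_beta
    tr_res <- tr_res - uu * sum(Ainv * GtG)
    tr_subj <- tr_subj - q^2 * sum(Ainv * crossprod(StG))
    if (pre$use_batch) {
      BtG <- crossprod(pre$M[, pre$idx_b, drop = FALSE], Gm)
      tr_batch <- tr_batch - q^2 * sum(Ainv * crossprod(BtG))
    }
    if (K) tr_k <- tr_k - uE^2 * sum(Ainv * GtG)
  }

  g_res <- 0.5 * (tr_res - quad_res) * s2
  g_subj <- 0.5 * (tr_subj - quad_subj) * su
  g <- c(g_res, g_subj)
  if (pre$use_batch) g <- c(g, 0.5 * (tr_batch - quad_batch) * sb)
  if (K) {
    g_fac <- 0.5 * (tr_k - quad_k) * sk
    g <- c(g, if (is.null(pre$eigen_scale)) g_fac else sum(g_fac))
  }
  g
}

mm_starts <- function(pre, n_starts) {
  v <- pre$vtot
  nfac <- mm_nfac(pre)
  fac_scale <- if (!is.null(pre$eigen_scale)) max(pre$eigen_scale) else 1
  mk <- function(resid, subj, batchv, fac) {
    th <- c(resid, subj)
    if (pre$use_batch) th <- c(th, batchv)
    if (nfac) th <- c(th, rep(fac / fac_scale, nfac))
    log(pmax(th * v, pre$floor))
  }
  starts <- list(mk(0.5, 0.25, 0.10, 0.30),
                 mk(0.9, 0.02, 0.02, 0.05),
                 mk(0.1, 0.50, 0.20, 0.50))
  starts[seq_len(max(1L, min(n_starts, length(starts))))]
}

mm_optimize <- function(pre, model = "full", reml = FALSE, starts,
                        maxit = 500L) {
  npar <- mm_npar(pre)
  cache <- new.env(parent = emptyenv())
  compute <- function(th) {
    if (!is.null(cache$th) && identical(th, cache$th)) return(cache$out)
    out <- tryCatch({
      ev <- mm_eval(pre, th, model, reml)
      list(nll = -ev$ll, grad = mm_grad(pre, th, ev))
    }, error = function(e) list(nll = 1e10, grad = rep(0, npar)))
    if (!is.finite(out$nll)) out <- list(nll = 1e10, grad = rep(0, npar))
    cache$th <- th
    cache$out <- out
    out
  }
  lower <- rep(log(pre$floor), npar)
  upper <- rep(log(1e4 * pre$vtot), npar)
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    o <- try(stats::optim(st, fn = function(th) compute(th)$nll,
                          gr = function(th) compute(th)$grad,
                          method = "L-BFGS-B", lower = lower, upper = upper,
                          control = list(maxit = maxit, factr = 1e6)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best) || best$value >= 1e9) {
    stop("variance-component optimization failed for every start",
         call. = FALSE)
  }
  if (best$convergence != 0L) {
    # a line-search hiccup near the boundary is usually cured by restarting
    # from the current best point
    o <- try(stats::optim(best$par, fn = function(th) compute(th)$nll,
                          gr = function(th) compute(th)$grad,
                          method = "L-BFGS-B", lower = lower, upper = upper,
                          control = list(maxit = maxit, factr = 1e6)),
             silent = TRUE)
    if (!inherits(o, "try-error") && o$value <= best$value + 1e-10) best <- o
  }
  ev <- mm_eval(pre, best$par, model, reml)
  list(theta = best$par, ll = ev$ll, beta = ev$beta,
       vcov_beta = ev$vcov_beta, converged = best$convergence == 0L)
}

mm_theta_names <- function(pre) {
  fac <- if (pre$K == 0L) NULL
  else if (is.null(pre$eigen_scale)) paste0("eigen", seq_len(pre$K))
  else "eigen"
  c("residual", "subject", if (pre$use_batch) "batch", fac)
}

#' Fit the set-level mixed model and test the group effect
#'
#' For one gene set, fits the linear mixed model with log2 expression as the
#' outcome, disease group as the fixed effect, and batch, subject, and
#' eigenvector-derived factor terms as random effects. The factor loadings
#' are the leading eigenvectors of the within-set gene-gene correlation
#' matrix, estimated on group-mean-centered residuals; each retained
#' component gets its own variance. Variance components are estimated by
#' REML with a non-negativity floor; the group effect is tested per
#' `spec$test` (see [model_spec()]).
#'
#' Genes absent from the matrix are ignored; genes with zero variance (or
#' zero residual variance when eigenvector terms are requested) are dropped
#' with a warning, mirroring how a screen must survive a pathological set.
#'
#' @param set_genes Character vector of gene symbols (one gene is permitted:
#'   the model then collapses to the classic two-group comparison).
#' @param expression Numeric log2 expression matrix, genes x samples.
#' @param metadata Sample metadata (see [validate_metadata()]).
#' @param spec A [model_spec()].
#' @param set_name Optional label carried into the result.
#' @return A list of class `gene_set_fit` with elements `set_name`, `size`,
#'   `genes`, `raw_p`, `beta_hat` (log2 case-minus-control effect, control
#'   as reference), `se`, `statistic`, `df`, `test`, `K`, `eigenvalues`,
#'   `var_components` (REML estimates), `loglik` (REML and, for the LRT, the
#'   two ML fits), `beta_ml`, and `converged`.
#' @export
fit_gene_set_model <- function(set_genes, expression, metadata,
                               spec = model_spec(), set_name = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  expression <- validate_expression(expression, min_genes = 1L,
                                    min_samples = 4L)
  metadata <- validate_metadata(metadata, samples = colnames(expression))
  present <- intersect(unique(trimws(set_genes)), rownames(expression))
  if (length(present) == 0L) {
    stop("none of the set's genes are measured", call. = FALSE)
  }
  Y <- expression[present, , drop = FALSE]
  if (max(Y) - min(Y) == 0) {
    stop("degenerate input: all expression values identical", call. = FALSE)
  }
  rv <- apply(Y, 1L, stats::var)
  drop <- rv <= 0
  want_eigen <- spec$K_max > 0L && sum(!drop) >= 2L
  if (want_eigen) {
    res_all <- center_by_group(Y, metadata)
    drop <- drop | apply(res_all, 1L, stats::var) <= 0
  }
  if (any(drop)) {
    warning("dropping zero-variance gene(s): ",
            paste(rownames(Y)[drop], collapse = ", "), call. = FALSE)
    Y <- Y[!drop, , drop = FALSE]
    if (nrow(Y) == 0L) {
      stop("degenerate input: no gene with nonzero variance", call. = FALSE)
    }
  }
  G <- nrow(Y)
  n <- ncol(Y)
  case <- as.integer(metadata$group == "case")
  batch <- if (spec$include_batch &&
               length(unique(metadata$batch)) > 1L) metadata$batch else NULL

  E <- NULL
  eigenvalues <- numeric(0)
  if (spec$K_max > 0L && G >= 2L) {
    resid <- center_by_group(Y, metadata)
    eb <- gene_correlation_eigen(resid, K_max = min(G, n))
    # retain only components above the Marchenko-Pastur noise edge of a
    # sample correlation matrix with df = n - #groups residual degrees of
    # freedom: weaker eigenvalues are indistinguishable from sampling noise
    # and conditioning on them deflates the group test's standard error
    df_resid <- n - length(unique(metadata$group))
    mp_edge <- (1 + sqrt(G / df_resid))^2
    k_signal <- sum(eb$all_eigenvalues > mp_edge)
    K <- min(spec$K_max, k_signal, eb$rank, n)
    if (K >= 1L) {
      E <- eb$loadings[, seq_len(K), drop = FALSE]
      eigenvalues <- eb$eigenvalues[seq_len(K)]
    }
  }

  eigen_scale <- if (!is.null(E) && spec$factor_variance == "shared") {
    eigenvalues
  } else NULL
  pre <- mm_prepare(Y, case, metadata$subject, batch, E,
                    floor = spec$variance_floor,
                    eigen_scale = eigen_scale)
  starts <- mm_starts(pre, spec$n_starts)
  reml <- mm_optimize(pre, "full", reml = TRUE, starts = starts,
                      maxit = spec$max_iter)
  beta_hat <- reml$beta[2L]
  se <- sqrt(reml$vcov_beta[2L, 2L])
  converged <- reml$converged
  loglik <- c(reml = reml$ll)
  beta_ml <- NA_real_

  if (spec$test == "LRT") {
    # warm start from the REML solution plus one independent start: starting
    # only at the REML optimum can trip the relative-reduction stopping rule
    # before the ML optimum is reached
    warm <- c(list(reml$theta), starts[1L])
    mlf <- mm_optimize(pre, "full", reml = FALSE, starts = warm,
                       maxit = spec$max_iter)
    ml0 <- mm_optimize(pre, "null", reml = FALSE, starts = warm,
                       maxit = spec$max_iter)
    stat <- max(0, 2 * (mlf$ll - ml0$ll))
    raw_p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
    df <- 1L
    converged <- converged && mlf$converged && ml0$converged
    loglik <- c(loglik, ml = mlf$ll, ml_null = ml0$ll)
    beta_ml <- mlf$beta[2L]
  } else {
    # between-within denominator df: the group contrast lives at the
    # subject level, so the reference is t with (#subjects - 2) df; with
    # one sample per subject and a single gene this is exactly the pooled
    # two-sample t-test
    df <- length(unique(metadata$subject)) - 2L
    stat <- beta_hat / se
    raw_p <- 2 * stats::pt(-abs(stat), df = df)
  }
  if (!converged) {
    warning(sprintf("set '%s': optimizer did not fully converge; p from best fit",
                    if (is.null(set_name)) "<unnamed>" else set_name),
            call. = FALSE)
  }
  vc <- exp(reml$theta)
  names(vc) <- mm_theta_names(pre)
  structure(list(
    set_name = set_name, size = G, genes = rownames(Y),
    raw_p = raw_p, beta_hat = beta_hat, se = se, statistic = stat, df = df,
    test = spec$test, K = pre$K, eigenvalues = eigenvalues,
    var_components = vc, loglik = loglik, beta_ml = beta_ml,
    converged = converged
  ), class = "gene_set_fit")
}

#' @export
print.gene_set_fit <- function(x, ...) {
  cat(sprintf("gene_set_fit%s: %d gene(s), K = %d, test = %s\n",
              if (is.null(x$set_name)) "" else paste0(" [", x$set_name, "]"),
              x$size, x$K, x$test))
  cat(sprintf("  beta_hat (log2, case - control) = %.4g (se %.3g)\n",
              x$beta_hat, x$se))
  cat(sprintf("  raw_p = %.4g   converged = %s\n", x$raw_p, x$converged))
  cat("  variance components:",
      paste(sprintf("%s=%.3g", names(x$var_components), x$var_components),
            collapse = ", "), "\n")
  invisible(x)
}
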