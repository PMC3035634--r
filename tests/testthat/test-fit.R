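test_that("model_spec validates its fields", {
  expect_error(model_spec(K_max = -1), "K_max")
  expect_error(model_spec(variance_floor = -1), "variance_floor")
  expect_error(model_spec(test = "ANOVA"))
  expect_identical(model_spec(test = "Wald")$test, "Wald")
})

test_that("single-gene Wald fit reproduces the pooled t-test", {
  for (seed in c(1, 2, 3)) {
    d <- single_gene_data(n1 = 6, n2 = 5, seed = seed, delta = 0.8)
    fit <- fit_gene_set_model("G1", d$expr, d$meta,
                              model_spec(K_max = 0, test = "Wald"))
    p_oracle <- pooled_t_oracle(d$y[seq_len(d$n1)], d$y[-seq_len(d$n1)])
    expect_equal(fit$raw_p, p_oracle, tolerance = 1e-8)
    expect_equal(fit$beta_hat,
                 mean(d$y[seq_len(d$n1)]) - mean(d$y[-seq_len(d$n1)]),
                 tolerance = 1e-8)
  }
})

test_that("degenerate inputs are rejected, zero-variance genes dropped", {
  n <- 8
  meta <- data.frame(sample = paste0("s", 1:n),
                     group = rep(c("case", "control"), each = 4),
                     batch = "b1", subject = paste0("p", 1:n))
  flat <- matrix(3, 2, n, dimnames = list(c("g1", "g2"), meta$sample))
  expect_error(fit_gene_set_model(c("g1", "g2"), flat, meta),
               "degenerate")

  set.seed(1)
  expr <- rbind(matrix(rnorm(3 * n), 3, n), g_flat = rep(1, n))
  rownames(expr) <- c("g1", "g2", "g3", "g_flat")
  colnames(expr) <- meta$sample
  expect_warning(
    fit <- fit_gene_set_model(rownames(expr), expr, meta,
                              model_spec(K_max = 2)),
    "g_flat")
  expect_identical(fit$size, 3L)
  expect_true(is.finite(fit$raw_p))
})

test_that("raw_p is invariant under sample permutation", {
  d <- tiny_instance(G = 6, n1 = 5, n2 = 4, seed = 31, K_true = 2)
  sp <- model_spec()
  fit <- fit_gene_set_model(d$genes, d$expr, d$meta, sp)
  set.seed(99)
  perm <- sample(ncol(d$expr))
  fit_p <- fit_gene_set_model(d$genes, d$expr[, perm], d$meta[perm, ], sp)
  expect_equal(fit_p$raw_p, fit$raw_p, tolerance = 1e-8)
  expect_equal(fit_p$beta_hat, fit$beta_hat, tolerance = 1e-6)
})

test_that("swapping case/control labels negates beta and preserves raw_p", {
  for (test in c("LRT", "Wald")) {
    d <- tiny_instance(G = 5, n1 = 5, n2 = 5, seed = 37, K_true = 1,
                       delta = 0.3)
    sp <- model_spec(test = test)
    fit <- fit_gene_set_model(d$genes, d$expr, d$meta, sp)
    meta_sw <- d$meta
    meta_sw$group <- ifelse(d$meta$group == "case", "control", "case")
    fit_sw <- fit_gene_set_model(d$genes, d$expr, meta_sw, sp)
    expect_equal(fit_sw$beta_hat, -fit$beta_hat, tolerance = 1e-6)
    expect_equal(fit_sw$raw_p, fit$raw_p, tolerance = 1e-8)
  }
})

test_that("REML fit agrees with lme4 on a factor-structured instance", {
  skip_if_not_installed("lme4")
  d <- tiny_instance(G = 4, n1 = 5, n2 = 4, seed = 41, K_true = 1)
  Y <- d$expr
  meta <- d$meta
  E <- fitted_basis(Y, meta, 1L)
  pre <- mmgsa:::mm_prepare(Y, as.integer(meta$group == "case"),
                            meta$subject, meta$batch, E, 1e-8)
  r <- mmgsa:::mm_optimize(pre, "full", reml = TRUE,
                           starts = mmgsa:::mm_starts(pre, 3))
  G <- nrow(Y); n <- ncol(Y)
  df <- data.frame(y = as.vector(Y),
                   case = rep(as.numeric(meta$group == "case"), each = G),
                   batch = rep(meta$batch, each = G),
                   subject = rep(meta$subject, each = G),
                   sample = rep(colnames(Y), each = G),
                   e1 = rep(E[, 1], n))
  lf <- lme4::lmer(
    y ~ case + (1 | batch) + (1 | subject) + (0 + e1 | sample),
    data = df, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  expect_equal(r$beta[2], unname(lme4::fixef(lf)["case"]),
               tolerance = 1e-4)
  expect_equal(r$ll, as.numeric(stats::logLik(lf)), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(lf))
  lme4_resid <- vc$vcov[vc$grp == "Residual"]
  expect_equal(exp(r$theta[1]), lme4_resid, tolerance = 1e-3)
})

test_that("ML fit matches the dense-likelihood oracle on tiny instances", {
  # the full 20-instance sweep runs in the acceptance suite; spot-check here
  for (seed in c(51, 52, 53)) {
    G <- sample(2:3, 1)
    d <- tiny_instance(G = G, n1 = 4, n2 = 3, seed = seed, K_true = 1)
    fit <- fit_gene_set_model(d$genes, d$expr, d$meta,
                              model_spec(K_max = 1, test = "LRT"))
    E <- fitted_basis(d$expr, d$meta, fit$K)
    orc <- oracle_dense_ml(d$expr, d$meta$group, d$meta$batch,
                           d$meta$subject, E)
    expect_equal(unname(fit$loglik["ml"]), orc$loglik, tolerance = 1e-4)
    expect_equal(fit$beta_ml, orc$beta[2], tolerance = 1e-3)
  }
})

test_that("fit handles K_max = 0, single batch, and constant shifts", {
  d <- tiny_instance(G = 4, n1 = 4, n2 = 4, seed = 61, n_batches = 1)
  sp <- model_spec(K_max = 0)
  fit <- fit_gene_set_model(d$genes, d$expr, d$meta, sp)
  expect_identical(fit$K, 0L)
  expect_false("batch" %in% names(fit$var_components))
  # shifting every value leaves the test untouched
  fit_sh <- fit_gene_set_model(d$genes, d$expr + 5, d$meta, sp)
  expect_equal(fit_sh$raw_p, fit$raw_p, tolerance = 1e-7)
  expect_equal(fit_sh$beta_hat, fit$beta_hat, tolerance = 1e-6)
})

test_that("variance components respect the non-negativity floor", {
  d <- tiny_instance(G = 5, n1 = 5, n2 = 5, seed = 71, K_true = 2)
  fit <- fit_gene_set_model(d$genes, d$expr, d$meta, model_spec())
  expect_true(all(fit$var_components >= 1e-8 - 1e-12))
  expect_true(all(is.finite(fit$var_components)))
  expect_gte(fit$raw_p, 0)
  expect_lte(fit$raw_p, 1)
})
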