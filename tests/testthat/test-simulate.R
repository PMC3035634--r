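test_that("invalid configurations list every offending field", {
  err <- tryCatch(simulation_config(n_case = 1, genes_per_set = 1,
                                    frac_nonnull = 2),
                  error = function(e) conditionMessage(e))
  expect_match(err, "n_case")
  expect_match(err, "genes_per_set")
  expect_match(err, "frac_nonnull")
  expect_error(simulation_config(K_true = 2, factor_sds = 0.5),
               "factor_sds")
})

test_that("the generator is deterministic under its seed", {
  a <- simulate_dataset(simulation_config(seed = 77))
  b <- simulate_dataset(simulation_config(seed = 77))
  expect_identical(a$expression, b$expression)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_dataset(simulation_config(seed = 78))
  expect_false(identical(a$expression, c2$expression))
})

test_that("truth labels respect the configured non-null count", {
  d0 <- simulate_dataset(simulation_config(frac_nonnull = 0, seed = 5))
  expect_false(any(d0$truth$is_nonnull))
  expect_true(all(d0$truth$true_delta == 0))
  d3 <- simulate_dataset(simulation_config(n_sets = 10, frac_nonnull = 0.3,
                                           delta = 0.7, seed = 6))
  expect_identical(sum(d3$truth$is_nonnull), 3L)
  expect_equal(d3$truth$true_delta[d3$truth$is_nonnull], rep(0.7, 3))
})

test_that("structure of the simulated data matches the metadata contract", {
  cfg <- simulation_config(n_case = 8, n_control = 4, n_batches = 2,
                           n_sets = 3, seed = 9)
  d <- simulate_dataset(cfg)
  expect_identical(dim(d$expression), c(60L, 12L))
  expect_identical(d$metadata$sample, colnames(d$expression))
  expect_identical(table(d$metadata$group),
                   table(factor(rep(c("case", "control"), c(8, 4)))))
  # round-robin batches balance the groups across batches
  expect_identical(as.integer(table(d$metadata$batch)), c(6L, 6L))
  # disjoint sets that tile the matrix
  genes <- unlist(unclass(d$collection))
  expect_identical(anyDuplicated(genes), 0L)
  expect_setequal(genes, rownames(d$expression))
})

test_that("pure-residual data show no gene-gene covariance", {
  cfg <- simulation_config(n_case = 100, n_control = 100, n_batches = 1,
                           batch_sd = 0, subject_sd = 0, residual_sd = 1,
                           K_true = 0, factor_sds = numeric(0), n_sets = 1,
                           genes_per_set = 10, frac_nonnull = 0, seed = 13)
  d <- simulate_dataset(cfg)
  S <- stats::cov(t(d$expression))
  off <- S[upper.tri(S)]
  expect_lt(abs(mean(off)), 3 / sqrt(200))
  expect_equal(mean(diag(S)), 1, tolerance = 0.2)
})

test_that("marginal covariance converges to the generative structure", {
  cfg <- simulation_config(n_case = 500, n_control = 500, n_batches = 1,
                           batch_sd = 0, n_sets = 1, genes_per_set = 12,
                           frac_nonnull = 0, seed = 17)
  d <- simulate_dataset(cfg)
  E <- attr(d$truth, "loadings")[[1]]
  vc <- attr(d$truth, "variance_components")
  G <- nrow(d$expression)
  V_true <- vc[["subject"]] * matrix(1, G, G) +
    E %*% diag(cfg$factor_sds^2) %*% t(E) +
    vc[["residual"]] * diag(G)
  S <- stats::cov(t(d$expression))
  rel_err <- norm(S - V_true, "F") / norm(V_true, "F")
  expect_lt(rel_err, 0.2)
})

test_that("simulated qPCR tables are deterministic and well-formed", {
  a <- simulate_qpcr(seed = 21)
  b <- simulate_qpcr(seed = 21)
  expect_identical(a, b)
  expect_identical(sort(unique(a$ct$gene)), c("ACTB", "TARGET"))
  expect_identical(nrow(a$ct), 24L * 3L * 2L)
  expect_true(all(a$ct$ct > 0 & a$ct$ct <= 45))
  expect_error(simulate_qpcr(sd = 0), "sd")
  expect_error(simulate_qpcr(n_case = 1), "at least 2")
})

test_that("a -1 dCt shift doubles the fold change on average", {
  reps <- 200
  log_fc <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_qpcr(delta_dct = -1, seed = 3000 + r)
    rel <- relative_expression(sim$ct, "TARGET", "ACTB")
    grp <- sim$samples$group[match(rel$sample, sim$samples$sample)]
    fc <- mean(rel$rel_expr[grp == "case"]) /
      mean(rel$rel_expr[grp == "control"])
    log_fc[r] <- log2(fc)
  }
  expect_equal(2^mean(log_fc), 2, tolerance = 0.1)
})

test_that("null qPCR p-values are uniform", {
  reps <- 500
  ps <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_qpcr(delta_dct = 0, seed = 4000 + r)
    rel <- relative_expression(sim$ct, "TARGET", "ACTB")
    grp <- sim$samples$group[match(rel$sample, sim$samples$sample)]
    ps[r] <- compare_groups(rel$rel_expr[grp == "case"],
                            rel$rel_expr[grp == "control"])$p_value
  }
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
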