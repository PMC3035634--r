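# Small builders used across test files. Fixtures are generated in code;
# nothing is read from disk except files the tests themselves write.

single_gene_data <- function(n1, n2, seed, delta = 0) {
  set.seed(seed)
  n <- n1 + n2
  y <- c(stats::rnorm(n1, delta), stats::rnorm(n2))
  expr <- matrix(y, 1L, n,
                 dimnames = list("G1", sprintf("s%02d", seq_len(n))))
  meta <- data.frame(sample = colnames(expr),
                     group = rep(c("case", "control"), c(n1, n2)),
                     batch = "b1",
                     subject = sprintf("p%02d", seq_len(n)),
                     stringsAsFactors = FALSE)
  list(expr = expr, meta = meta, y = y, n1 = n1, n2 = n2)
}

# a small multi-gene instance with latent factor structure and batches
tiny_instance <- function(G, n1, n2, seed, K_true = 1, delta = 0,
                          n_batches = 2) {
  cfg <- simulation_config(
    n_case = n1, n_control = n2, n_batches = n_batches,
    K_true = K_true, factor_sds = rep(0.5, K_true),
    n_sets = 1, genes_per_set = G,
    frac_nonnull = if (delta != 0) 1 else 0, delta = delta, seed = seed)
  d <- simulate_dataset(cfg)
  list(expr = d$expression, meta = d$metadata,
       genes = d$collection[[1]], d = d)
}

# Monte-Carlo rejection rate of the set-level test at alpha. Each replicate
# set gets its own simulated cohort (chunk = 1) so the replicates are
# independent; sets simulated within one cohort share its batch/subject
# draws and would be strongly dependent.
mm_reject_rate <- function(delta, reps, n_per_group, seed_base,
                           chunk = 1L, alpha = 0.05,
                           spec = model_spec()) {
  hits <- 0L
  done <- 0L
  chunk_i <- 0L
  while (done < reps) {
    chunk_i <- chunk_i + 1L
    nset <- min(chunk, reps - done)
    cfg <- simulation_config(
      n_case = n_per_group, n_control = n_per_group, n_sets = nset,
      frac_nonnull = if (delta > 0) 1 else 0, delta = delta,
      seed = seed_base + chunk_i)
    d <- simulate_dataset(cfg)
    for (s in names(d$collection)) {
      p <- fit_gene_set_model(d$collection[[s]], d$expression, d$metadata,
                              spec, set_name = s)$raw_p
      hits <- hits + (p <= alpha)
    }
    done <- done + nset
  }
  hits / reps
}

write_tmp_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
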