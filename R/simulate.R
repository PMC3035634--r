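#' Configuration for the synthetic expression generator
#'
#' The generator runs the set-level mixed model forward, so the simulated
#' covariance is exactly the structure the fitter assumes: per sample,
#' `subject_sd^2 * J + sum_k factor_sds_k^2 * E_k E_k' + residual_sd^2 * I`
#' across the genes of a set, plus batch offsets shared across genes.
#' Defaults mirror a small two-group microarray cohort on the log2 scale:
#' 8 cases vs 4 controls, two batches, and factor structure of rank 2.
#'
#' @param n_case,n_control Samples per group (each >= 2; defaults 8 and 4).
#' @param n_batches Number of batches, assigned round-robin (default 2).
#' @param batch_sd,subject_sd,residual_sd Random-effect standard deviations
#'   in log2 units (defaults 0.2, 0.3, 0.5).
#' @param K_true Number of latent co-expression factors per set (default 2).
#' @param factor_sds Standard deviations of the factor scores, length
#'   `K_true` (default `c(1.8, 1.2)`). Loadings are orthonormal, so a
#'   factor's per-gene contribution is `factor_sd / sqrt(genes_per_set)`:
#'   the defaults give per-gene co-expression of roughly 0.40 and 0.27 log2
#'   units at 20 genes per set, a substantial (~35%) share of per-gene
#'   variance as in genuinely co-expressed modules.
#' @param n_sets Number of disjoint gene sets (default 10).
#' @param genes_per_set Genes per set (default 20, >= 2).
#' @param frac_nonnull Fraction of sets carrying a group effect; the exact
#'   count is `round(frac_nonnull * n_sets)` (default 0.2).
#' @param delta Case-minus-control shift, log2 units, applied to every gene
#'   of a non-null set (default 0.5).
#' @param baseline_mean Baseline log2 expression (default 7).
#' @param seed Integer seed; identical configs give byte-identical output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_case = 8L, n_control = 4L, n_batches = 2L,
                              batch_sd = 0.2, subject_sd = 0.3,
                              residual_sd = 0.5, K_true = 2L,
                              factor_sds = c(1.8, 1.2), n_sets = 10L,
                              genes_per_set = 20L, frac_nonnull = 0.2,
                              delta = 0.5, baseline_mean = 7, seed = 1L) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_batches = as.integer(n_batches), batch_sd = batch_sd,
              subject_sd = subject_sd, residual_sd = residual_sd,
              K_true = as.integer(K_true), factor_sds = as.numeric(factor_sds),
              n_sets = as.integer(n_sets),
              genes_per_set = as.integer(genes_per_set),
              frac_nonnull = frac_nonnull, delta = delta,
              baseline_mean = baseline_mean, seed = as.integer(seed))
  bad <- character(0)
  if (cfg$n_case < 2L) bad <- c(bad, "n_case must be >= 2")
  if (cfg$n_control < 2L) bad <- c(bad, "n_control must be >= 2")
  if (cfg$n_batches < 1L) bad <- c(bad, "n_batches must be >= 1")
  if (cfg$batch_sd < 0) bad <- c(bad, "batch_sd must be >= 0")
  if (cfg$subject_sd < 0) bad <- c(bad, "subject_sd must be >= 0")
  if (cfg$residual_sd < 0) bad <- c(bad, "residual_sd must be >= 0")
  if (cfg$K_true < 0L) bad <- c(bad, "K_true must be >= 0")
  if (length(cfg$factor_sds) != cfg$K_true) {
    bad <- c(bad, "factor_sds must have length K_true")
  }
  if (any(cfg$factor_sds < 0)) bad <- c(bad, "factor_sds must be >= 0")
  if (cfg$n_sets < 1L) bad <- c(bad, "n_sets must be >= 1")
  if (cfg$genes_per_set < 2L) bad <- c(bad, "genes_per_set must be >= 2")
  if (cfg$frac_nonnull < 0 || cfg$frac_nonnull > 1) {
    bad <- c(bad, "frac_nonnull must lie in [0, 1]")
  }
  if (length(bad)) {
    stop("invalid simulation config: ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate an expression dataset with known truth
#'
#' Generates a complete screen input: a log2 expression matrix, sample
#' metadata, a collection of disjoint gene sets, and per-set ground-truth
#' labels. For each set an orthonormal `genes_per_set x K_true` loading
#' matrix `E` is drawn (QR of a standard-normal matrix), and
#' `y_gs = baseline + delta * I(case, non-null set) + b_batch(s) + u_s +
#' sum_k a_sk E_gk + eps_gs` with the configured standard deviations.
#' Batch and subject effects are drawn once per sample (an array-level
#' offset shared by every gene of the sample); factor scores and residuals
#' are per set. Samples go to batches round-robin, which balances groups
#' across batches.
#'
#' @param config A [simulation_config()].
#' @return List with `expression`, `metadata`, `collection`, `truth`
#'   (data frame: `set_name`, `is_nonnull`, `true_delta`; the generating
#'   variance components and the per-set loading matrices are attached as
#'   attributes `"variance_components"` and `"loadings"`), and the
#'   `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_case + config$n_control
  G <- config$genes_per_set
  K <- config$K_true
  sample_id <- c(sprintf("case_%03d", seq_len(config$n_case)),
                 sprintf("ctrl_%03d", seq_len(config$n_control)))
  group <- rep(c("case", "control"), c(config$n_case, config$n_control))
  batch <- sprintf("b%d", ((seq_len(n) - 1L) %% config$n_batches) + 1L)
  subject <- sprintf("subj_%03d", seq_len(n))
  metadata <- data.frame(sample = sample_id, group = group, batch = batch,
                         subject = subject, stringsAsFactors = FALSE)
  n_nonnull <- round(config$frac_nonnull * config$n_sets)
  is_nonnull <- rep(FALSE, config$n_sets)
  if (n_nonnull > 0L) {
    is_nonnull[sample.int(config$n_sets, n_nonnull)] <- TRUE
  }
  b_eff <- stats::rnorm(config$n_batches, 0, config$batch_sd)
  u_eff <- stats::rnorm(n, 0, config$subject_sd)
  sample_off <- b_eff[((seq_len(n) - 1L) %% config$n_batches) + 1L] + u_eff
  case_ind <- as.numeric(group == "case")
  blocks <- vector("list", config$n_sets)
  sets <- vector("list", config$n_sets)
  loadings <- vector("list", config$n_sets)
  set_names <- sprintf("SET_%03d", seq_len(config$n_sets))
  for (i in seq_len(config$n_sets)) {
    Yi <- matrix(stats::rnorm(G * n, 0, config$residual_sd), G, n)
    if (K > 0L) {
      E <- qr.Q(qr(matrix(stats::rnorm(G * K), G, K)))
      a <- matrix(stats::rnorm(K * n), K, n) * config$factor_sds
      Yi <- Yi + E %*% a
      loadings[[i]] <- E
    }
    Yi <- Yi + config$baseline_mean +
      matrix(sample_off, G, n, byrow = TRUE)
    if (is_nonnull[i]) {
      Yi <- Yi + config$delta * matrix(case_ind, G, n, byrow = TRUE)
    }
    genes <- sprintf("%s_G%03d", set_names[i], seq_len(G))
    rownames(Yi) <- genes
    blocks[[i]] <- Yi
    sets[[i]] <- genes
  }
  expression <- do.call(rbind, blocks)
  colnames(expression) <- sample_id
  names(sets) <- set_names
  truth <- data.frame(set_name = set_names, is_nonnull = is_nonnull,
                      true_delta = ifelse(is_nonnull, config$delta, 0),
                      stringsAsFactors = FALSE)
  names(loadings) <- set_names
  attr(truth, "loadings") <- loadings
  attr(truth, "variance_components") <- c(
    batch = config$batch_sd^2, subject = config$subject_sd^2,
    residual = config$residual_sd^2,
    if (K > 0L) stats::setNames(config$factor_sds^2,
                                paste0("factor", seq_len(K))))
  list(expression = expression, metadata = metadata,
       collection = gene_set_collection(sets), truth = truth,
       config = config)
}

#' Simulate a qPCR confirmation experiment
#'
#' Draws per-sample reference-gene Ct values around 20 cycles (sd 0.2), a
#' target-gene dCt of `N(base_dct, sd)` with the case-group mean shifted by
#' `delta_dct`, and triplicate technical jitter of sd 0.1 cycles. A
#' `delta_dct` of -1 corresponds to a twofold higher target expression in
#' cases.
#'
#' @param n_case,n_control Samples per group (>= 2; defaults 12, the size of
#'   a typical confirmation cohort).
#' @param delta_dct Case-minus-control shift in dCt cycles (default 0).
#' @param sd Biological sd of the dCt values (> 0, default 0.5).
#' @param seed Integer seed.
#' @param base_dct Control-group mean dCt (default 5).
#' @param n_replicates Technical replicates per (sample, gene) (default 3).
#' @return List with `ct` (data frame `sample`, `gene`, `replicate`, `ct`;
#'   genes `"TARGET"` and `"ACTB"`) and `samples` (data frame `sample`,
#'   `group`).
#' @export
simulate_qpcr <- function(n_case = 12L, n_control = 12L, delta_dct = 0,
                          sd = 0.5, seed = 1L, base_dct = 5,
                          n_replicates = 3L) {
  if (n_case < 2L || n_control < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  if (sd <= 0) stop("sd must be > 0", call. = FALSE)
  set.seed(as.integer(seed))
  n <- n_case + n_control
  sample_id <- c(sprintf("case_%02d", seq_len(n_case)),
                 sprintf("ctrl_%02d", seq_len(n_control)))
  group <- rep(c("case", "control"), c(n_case, n_control))
  ref_mean <- stats::rnorm(n, 20, 0.2)
  dct <- stats::rnorm(n, base_dct + delta_dct * (group == "case"), sd)
  tgt_mean <- ref_mean + dct
  rep_idx <- seq_len(n_replicates)
  rows <- expand.grid(replicate = rep_idx, sample = seq_len(n),
                      gene = c("TARGET", "ACTB"), stringsAsFactors = FALSE)
  mu <- ifelse(rows$gene == "TARGET", tgt_mean[rows$sample],
               ref_mean[rows$sample])
  ct <- data.frame(sample = sample_id[rows$sample], gene = rows$gene,
                   replicate = rows$replicate,
                   ct = mu + stats::rnorm(nrow(rows), 0, 0.1),
                   stringsAsFactors = FALSE)
  list(ct = ct,
       samples = data.frame(sample = sample_id, group = group,
                            stringsAsFactors = FALSE))
}
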