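#' @title Ct-method qPCR quantification
#' @name qpcr
#' @description Relative quantification of qPCR confirmation experiments:
#'   reference-gene normalization by the threshold-cycle (Ct) method,
#'   fold changes via 2^(-ddCt), and Welch group comparisons. Amplification
#'   efficiency is fixed at 2 (perfect doubling per cycle).
NULL

validate_ct_table <- function(ct) {
  req <- c("sample", "gene", "replicate", "ct")
  miss <- setdiff(req, names(ct))
  if (length(miss)) {
    stop("Ct table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ct <- as.data.frame(ct, stringsAsFactors = FALSE)
  ct$ct <- as.numeric(ct$ct)
  if (anyNA(ct$ct)) stop("non-numeric Ct value(s)", call. = FALSE)
  if (any(ct$ct <= 0 | ct$ct > 45)) {
    stop("Ct values must lie in (0, 45]", call. = FALSE)
  }
  ct
}

#' Read a qPCR Ct table from TSV
#'
#' Expects header `sample<TAB>gene<TAB>replicate<TAB>ct`; Ct values must lie
#' in (0, 45].
#'
#' @param path TSV path.
#' @return Validated data frame.
#' @export
read_ct_table <- function(path) {
  validate_ct_table(utils::read.delim(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}

#' Write a qPCR Ct table as TSV
#'
#' @param ct Ct data frame (columns `sample`, `gene`, `replicate`, `ct`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  ct <- validate_ct_table(ct)
  utils::write.table(ct[, c("sample", "gene", "replicate", "ct")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-sample relative expression by the Ct method
#'
#' Replicate Ct values are averaged on the Ct scale per (sample, gene);
#' then, per sample, `dct = mean Ct(target) - mean Ct(reference)` and the
#' relative expression is `2^(-dct)`. Adding a constant number of cycles to
#' both genes leaves the result unchanged.
#'
#' @param ct Ct table (see [read_ct_table()]).
#' @param target_gene Target gene symbol.
#' @param reference_gene Internal-control gene symbol (e.g. beta-actin).
#' @return Data frame with columns `sample`, `delta_ct`, `rel_expr`.
#' @export
relative_expression <- function(ct, target_gene, reference_gene) {
  ct <- validate_ct_table(ct)
  samples <- unique(ct$sample)
  tmean <- function(s, g) {
    v <- ct$ct[ct$sample == s & ct$gene == g]
    if (length(v) == 0L) {
      stop(sprintf("sample '%s' has no Ct values for gene '%s'", s, g),
           call. = FALSE)
    }
    mean(v)
  }
  dct <- vapply(samples, function(s) {
    tmean(s, target_gene) - tmean(s, reference_gene)
  }, numeric(1))
  data.frame(sample = samples, delta_ct = unname(dct),
             rel_expr = 2^(-unname(dct)), stringsAsFactors = FALSE)
}

#' Fold change between paired relative expressions
#'
#' `treated / control`, elementwise; equivalently `2^(-ddCt)` where
#' `ddCt = dCt(treated) - dCt(control)`.
#'
#' @param treated Numeric vector of treated relative expressions.
#' @param control Numeric vector of control relative expressions (same
#'   length, pair-matched).
#' @return Numeric vector of fold changes.
#' @export
fold_change <- function(treated, control) {
  if (length(treated) != length(control)) {
    stop("treated and control must be pair-matched vectors of equal length",
         call. = FALSE)
  }
  if (any(control == 0)) {
    stop("zero control relative expression: fold change undefined",
         call. = FALSE)
  }
  treated / control
}

#' Welch two-sample comparison of qPCR quantities
#'
#' Compares two groups of relative-expression values with Welch's t-test.
#' By default the test is run on the log2 scale (i.e. on -dCt), since
#' 2^(-dCt) quantities are log-normal-like; set `on_log_scale = FALSE` to
#' test the raw values.
#'
#' @param values_a,values_b Numeric vectors, at least 2 values each; must be
#'   positive when `on_log_scale`.
#' @param on_log_scale Test on log2-transformed values (default TRUE).
#' @return List with `p_value`, `statistic`, `df`, and per-group `mean`/`sd`
#'   (on the tested scale).
#' @export
compare_groups <- function(values_a, values_b, on_log_scale = TRUE) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (on_log_scale) {
    if (any(values_a <= 0) || any(values_b <= 0)) {
      stop("log-scale comparison requires positive values", call. = FALSE)
    }
    values_a <- log2(values_a)
    values_b <- log2(values_b)
  }
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(p_value = unname(tt$p.value), statistic = unname(tt$statistic),
       df = unname(tt$parameter),
       mean_a = mean(values_a), sd_a = stats::sd(values_a),
       mean_b = mean(values_b), sd_b = stats::sd(values_b))
}
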