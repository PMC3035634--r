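#' Test a single gene for differential expression
#'
#' Fits the single-gene reduction of the set-level mixed model (group fixed
#' effect; batch random intercept when the design has more than one batch;
#' no eigenvector terms) and reports the group p-value together with a
#' direction-of-change call. With one batch and one sample per subject the
#' default Wald test is exactly the pooled two-sample t-test. The direction
#' is the sign of the raw case-minus-control mean difference on the log2
#' scale, `"up"` meaning higher in cases.
#'
#' @param gene Gene symbol, present in `expression`.
#' @param expression Numeric log2 expression matrix.
#' @param metadata Sample metadata (see [validate_metadata()]).
#' @param spec A [model_spec()]; the default uses `K_max = 0` and the Wald
#'   test, i.e. the same model family as the screen restricted to one gene.
#' @return A list of class `gene_level_result` with elements `gene`,
#'   `direction` (`"up"`, `"down"`, `"none"`), `p`, and `delta` (case mean
#'   minus control mean, log2 scale).
#' @export
test_gene <- function(gene, expression, metadata,
                      spec = model_spec(K_max = 0L, test = "Wald")) {
  if (!gene %in% rownames(expression)) {
    stop("gene not measured: ", gene, call. = FALSE)
  }
  metadata <- validate_metadata(metadata, samples = colnames(expression))
  y <- expression[gene, ]
  if (stats::var(y) <= 0) {
    stop("degenerate input: gene has zero variance: ", gene, call. = FALSE)
  }
  fit <- fit_gene_set_model(gene, expression, metadata, spec,
                            set_name = gene)
  delta <- mean(y[metadata$group == "case"]) -
    mean(y[metadata$group == "control"])
  structure(list(
    gene = gene,
    direction = if (delta > 0) "up" else if (delta < 0) "down" else "none",
    p = fit$raw_p,
    delta = delta
  ), class = "gene_level_result")
}

#' @export
print.gene_level_result <- function(x, ...) {
  cat(sprintf("%s: %s (delta = %.4g log2 units), p = %.4g\n",
              x$gene, x$direction, x$delta, x$p))
  invisible(x)
}

#' Per-gene differential expression table for one gene set
#'
#' Runs [test_gene()] on every measured member of the named set and keeps
#' genes with `p <= alpha`, sorted by ascending p-value (ties by gene name).
#' The inclusion threshold is a reporting choice for the follow-up table,
#' not a multiplicity-adjusted inference.
#'
#' @param set_name Name of a set in `collection`.
#' @param collection A [gene_set_collection()].
#' @param expression Numeric log2 expression matrix.
#' @param metadata Sample metadata.
#' @param spec A [model_spec()] for the per-gene test (default: single-gene
#'   reduction with the Wald test).
#' @param alpha Per-gene inclusion threshold (default 0.05); `alpha = 1`
#'   keeps every member gene.
#' @return Data frame with columns `gene`, `direction`, `p`, `delta`,
#'   ascending in `p`. Unmeasured or zero-variance members are skipped (the
#'   latter with a warning).
#' @export
table_for_set <- function(set_name, collection, expression, metadata,
                          spec = model_spec(K_max = 0L, test = "Wald"),
                          alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!set_name %in% names(collection)) {
    stop("unknown gene set: ", set_name, call. = FALSE)
  }
  metadata <- validate_metadata(metadata, samples = colnames(expression))
  genes <- intersect(collection[[set_name]], rownames(expression))
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    r <- tryCatch(test_gene(genes[i], expression, metadata, spec),
                  error = function(e) e)
    if (inherits(r, "error")) {
      warning("skipping gene '", genes[i], "': ", conditionMessage(r),
              call. = FALSE)
      next
    }
    rows[[i]] <- data.frame(gene = r$gene, direction = r$direction,
                            p = r$p, delta = r$delta,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(gene = character(0), direction = character(0),
                      p = numeric(0), delta = numeric(0))
  }
  out <- out[out$p <= alpha, , drop = FALSE]
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a gene-level table as TSV
#'
#' Emits the three reporting columns `gene`, `direction`, `p` with p-values
#' at 4 significant digits.
#'
#' @param x Data frame from [table_for_set()].
#' @param path Output TSV path.
#' @param signif_digits Significant digits for `p` (default 4).
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(x, path, signif_digits = 4L) {
  df <- x[, c("gene", "direction", "p")]
  df$p <- signif(df$p, signif_digits)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
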