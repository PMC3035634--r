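#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment of a vector of nominal p-values: the adjusted value of
#' the i-th smallest p is `min over j >= i of min(1, m * p_(j) / j)`. Output
#' order matches input order; `NA`s (e.g. failed fits) are passed through and
#' excluded from the family size. Delegates to [stats::p.adjust()], whose
#' `"BH"` method is exactly this construction.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr_adjust <- function(pvals) {
  if (!is.numeric(pvals)) stop("pvals must be numeric", call. = FALSE)
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Screen a gene set collection with the set-level mixed model
#'
#' Restricts the collection to measured genes, fits the mixed model of
#' [fit_gene_set_model()] to every surviving set, and adjusts the nominal
#' p-values by Benjamini-Hochberg FDR across *all* screened sets (the
#' adjustment family is the full screen, never a displayed subset). A set
#' whose fit fails is reported with `converged = FALSE` and `NA` p-values
#' rather than aborting the screen.
#'
#' @param collection A [gene_set_collection()].
#' @param expression Numeric log2 expression matrix, genes x samples.
#' @param metadata Sample metadata (see [validate_metadata()]).
#' @param spec A [model_spec()].
#' @param min_size Minimum post-restriction set size (default 5).
#' @return A data frame of class `mmgsa_screen` with columns `set_name`,
#'   `size`, `raw_p`, `fdr_p`, `beta_hat`, `converged`, sorted by ascending
#'   `raw_p` with ties broken by set name. Fit warnings are collected in the
#'   `"warnings"` attribute.
#' @export
screen_gene_sets <- function(collection, expression, metadata,
                             spec = model_spec(), min_size = 5L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  expression <- validate_expression(expression)
  metadata <- validate_metadata(metadata, samples = colnames(expression))
  collection <- restrict_to_measured(collection, rownames(expression),
                                     min_size = min_size)
  if (length(collection) == 0L) {
    stop("no gene set survives restriction to the measured universe",
         call. = FALSE)
  }
  nset <- length(collection)
  res <- data.frame(
    set_name = names(collection), size = NA_integer_, raw_p = NA_real_,
    fdr_p = NA_real_, beta_hat = NA_real_, converged = FALSE,
    stringsAsFactors = FALSE)
  notes <- character(0)
  for (i in seq_len(nset)) {
    nm <- names(collection)[i]
    fit <- withCallingHandlers(
      tryCatch(fit_gene_set_model(collection[[i]], expression, metadata,
                                  spec, set_name = nm),
               error = function(e) e),
      warning = function(w) {
        notes <<- c(notes, paste0(nm, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (inherits(fit, "error")) {
      notes <- c(notes, paste0(nm, ": ", conditionMessage(fit)))
      res$size[i] <- length(collection[[i]])
      next
    }
    res$size[i] <- fit$size
    res$raw_p[i] <- fit$raw_p
    res$beta_hat[i] <- fit$beta_hat
    res$converged[i] <- fit$converged
  }
  res$fdr_p <- bh_fdr_adjust(res$raw_p)
  ord <- order(res$raw_p, res$set_name, na.last = TRUE)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "warnings") <- notes
  class(res) <- c("mmgsa_screen", "data.frame")
  res
}

#' @export
print.mmgsa_screen <- function(x, n = 10L, ...) {
  cat(sprintf("mmgsa screen: %d gene set(s)\n", nrow(x)))
  df <- as.data.frame(utils::head(x, n))
  df$raw_p <- signif(df$raw_p, 4)
  df$fdr_p <- signif(df$fdr_p, 4)
  df$beta_hat <- signif(df$beta_hat, 4)
  print(df, row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("  ... and %d more row(s)\n", nrow(x) - n))
  nw <- length(attr(x, "warnings"))
  if (nw) cat(sprintf("  %d warning(s); see attr(x, \"warnings\")\n", nw))
  invisible(x)
}

#' Write a screen table as TSV
#'
#' Human-readable output: p-values are printed with 4 significant digits.
#' Keep the returned object (or the pipeline manifest JSON) for
#' full-precision values.
#'
#' @param x An `mmgsa_screen` data frame from [screen_gene_sets()].
#' @param path Output TSV path.
#' @param signif_digits Significant digits for `raw_p`, `fdr_p` and
#'   `beta_hat` (default 4).
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(x, path, signif_digits = 4L) {
  df <- as.data.frame(x)[, c("set_name", "size", "raw_p", "fdr_p",
                             "beta_hat", "converged")]
  for (cc in c("raw_p", "fdr_p", "beta_hat")) {
    df[[cc]] <- signif(df[[cc]], signif_digits)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
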