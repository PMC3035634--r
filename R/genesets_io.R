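#' @title Gene set collections and expression input
#' @name genesets_io
#' @description Readers, writers and validators for the three inputs of a
#'   screen: a GMT gene set collection, a log2 expression matrix (genes x
#'   samples, TSV) and per-sample metadata (group / batch / subject).
NULL

new_gene_set_collection <- function(sets, descriptions) {
  stopifnot(is.list(sets), length(sets) == length(descriptions))
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' Construct a gene set collection from a named list
#'
#' @param sets Named list of character vectors of gene symbols. Names are the
#'   set names and must be unique; genes within a set are deduplicated
#'   (first occurrence kept).
#' @param descriptions Optional character vector of per-set descriptions
#'   (recycled `"na"` when missing).
#' @return A `gene_set_collection`: a named list of character vectors with a
#'   `descriptions` attribute.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set must be named", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(trimws(as.character(g))))
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "), call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  descriptions <- as.character(descriptions)
  names(descriptions) <- names(sets)
  new_gene_set_collection(sets, descriptions)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection with %d set(s)\n", length(x)))
  sz <- lengths(x)
  if (length(x)) {
    cat(sprintf("  set sizes: min %d, median %s, max %d\n",
                min(sz), format(stats::median(sz)), max(sz)))
    show <- utils::head(names(x), 5L)
    cat("  ", paste(show, collapse = ", "),
        if (length(x) > 5L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  sets <- unclass(x)[i]
  new_gene_set_collection(sets, attr(x, "descriptions")[names(sets)])
}

#' Read a gene set collection from a GMT file
#'
#' Parses the tab-separated GMT dialect used by MSigDB: one set per line,
#' fields `name`, `description`, then one or more gene symbols. File order is
#' preserved, duplicate genes within a line are collapsed to their first
#' occurrence, and empty trailing fields are ignored.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @seealso [write_gmt()], [restrict_to_measured()]
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    if (length(f) > 2L) f <- f[c(TRUE, TRUE, nzchar(f[-(1:2)]))]
    if (length(f) < 3L) {
      stop(sprintf(
        "malformed GMT line %d: need name, description and at least one gene",
        lineno[i]), call. = FALSE)
    }
    nm[i] <- f[1L]
    desc[i] <- f[2L]
    sets[[i]] <- unique(f[-(1:2)])
  }
  if (anyDuplicated(nm)) {
    stop("duplicate gene set name(s) in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  names(sets) <- nm
  names(desc) <- nm
  new_gene_set_collection(sets, desc)
}

#' Write a gene set collection to a GMT file
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(s) {
    paste(c(s, desc[[s]], collection[[s]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a collection to measured genes and a minimum set size
#'
#' Intersects every set with the measured gene universe (e.g. the rownames of
#' an expression matrix) and drops sets whose post-intersection size falls
#' below `min_size`. The reported set size downstream is always this
#' post-intersection count. The operation is idempotent.
#'
#' @param collection A [gene_set_collection()].
#' @param measured Character vector of measured gene symbols.
#' @param min_size Minimum number of surviving genes for a set to be kept
#'   (default 5; must be >= 2).
#' @return The filtered `gene_set_collection`.
#' @export
restrict_to_measured <- function(collection, measured, min_size = 5L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(measured) == 0L) {
    stop("measured gene universe is empty", call. = FALSE)
  }
  if (min_size < 2L) stop("min_size must be >= 2", call. = FALSE)
  measured <- unique(trimws(as.character(measured)))
  sets <- lapply(unclass(collection), function(g) g[g %in% measured])
  keep <- lengths(sets) >= min_size
  new_gene_set_collection(sets[keep],
                          attr(collection, "descriptions")[names(sets)[keep]])
}

#' Validate per-sample metadata
#'
#' Checks the group/batch/subject design: `group` must take values in
#' `{case, control}` with at least two samples per group, and each subject
#' must belong to exactly one group. When `samples` is supplied the metadata
#' is additionally required to cover exactly those samples and is returned
#' reordered to match.
#'
#' @param metadata Data frame with columns `sample`, `group`, `batch`,
#'   `subject`.
#' @param samples Optional character vector of sample ids to align to.
#' @return The validated (and possibly reordered) metadata data frame.
#' @export
validate_metadata <- function(metadata, samples = NULL) {
  req <- c("sample", "group", "batch", "subject")
  miss <- setdiff(req, names(metadata))
  if (length(miss)) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  for (cc in req) metadata[[cc]] <- as.character(metadata[[cc]])
  if (anyDuplicated(metadata$sample)) {
    stop("duplicated sample id(s) in metadata: ",
         paste(unique(metadata$sample[duplicated(metadata$sample)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(metadata$group), c("case", "control"))
  if (length(bad)) {
    stop("group labels must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(samples)) {
    only_meta <- setdiff(metadata$sample, samples)
    only_mat <- setdiff(samples, metadata$sample)
    if (length(only_meta) || length(only_mat)) {
      stop("sample sets differ between matrix and metadata; ",
           if (length(only_mat))
             paste0("missing from metadata: ",
                    paste(only_mat, collapse = ", "), "; ") else "",
           if (length(only_meta))
             paste0("missing from matrix: ",
                    paste(only_meta, collapse = ", ")) else "",
           call. = FALSE)
    }
    metadata <- metadata[match(samples, metadata$sample), , drop = FALSE]
    rownames(metadata) <- NULL
  }
  tab <- table(metadata$group)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("need at least 2 samples in each of the case and control groups",
         call. = FALSE)
  }
  gps <- tapply(metadata$group, metadata$subject,
                function(g) length(unique(g)))
  if (any(gps > 1L)) {
    stop("subject(s) mapped to more than one group: ",
         paste(names(gps)[gps > 1L], collapse = ", "), call. = FALSE)
  }
  metadata
}

validate_expression <- function(x, min_genes = 2L, min_samples = 4L) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression must be a numeric matrix (genes x samples)",
         call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicated gene id(s): ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicated sample id(s): ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("expression matrix contains non-finite values", call. = FALSE)
  }
  if (nrow(x) < min_genes || ncol(x) < min_samples) {
    stop(sprintf("expression matrix needs at least %d genes and %d samples",
                 min_genes, min_samples), call. = FALSE)
  }
  x
}

#' Read an expression matrix and its sample metadata
#'
#' The expression TSV has gene ids in the first column and one column per
#' sample of log2 expression values; the metadata TSV has columns
#' `sample`, `group`, `batch`, `subject`. The two files are cross-validated:
#' they must describe the same sample set, and the returned metadata rows are
#' ordered to match the matrix columns. `control` is the reference level for
#' the group effect, so a positive group coefficient means higher expression
#' in cases.
#'
#' @param path Expression TSV path.
#' @param meta_path Metadata TSV path.
#' @return A list with elements `expression` (numeric matrix) and
#'   `metadata` (data frame).
#' @export
read_expression <- function(path, meta_path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression TSV has no sample columns", call. = FALSE)
  genes <- as.character(raw[[1L]])
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) && !anyNA(v)) {
        stop(sprintf("non-numeric expression value(s) in column '%s'",
                     names(vals)[j]), call. = FALSE)
      }
      vals[[j]] <- vn
    }
  }
  x <- as.matrix(vals)
  rownames(x) <- genes
  x <- validate_expression(x)
  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  meta <- validate_metadata(meta, samples = colnames(x))
  list(expression = x, metadata = meta)
}

#' Write an expression matrix (and optionally metadata) as TSV
#'
#' @param expression Numeric matrix, genes x samples.
#' @param path Output TSV path for the matrix.
#' @param metadata Optional metadata data frame.
#' @param meta_path Output TSV path for the metadata (required when
#'   `metadata` is given).
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, path, metadata = NULL,
                             meta_path = NULL) {
  df <- data.frame(gene = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata)) {
    if (is.null(meta_path)) stop("meta_path required with metadata",
                                 call. = FALSE)
    utils::write.table(
      metadata[, c("sample", "group", "batch", "subject")], meta_path,
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
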