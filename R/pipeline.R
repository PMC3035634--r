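#' Configuration for an end-to-end screen run
#'
#' @param expression,metadata,gmt Input file paths (expression TSV, metadata
#'   TSV, GMT collection).
#' @param out_dir Output directory (created if needed).
#' @param K_max,test,include_batch,variance_floor Model options, see
#'   [model_spec()].
#' @param min_size Minimum post-restriction set size (default 5).
#' @param alpha Gene-level inclusion threshold carried in the manifest
#'   (default 0.05).
#' @param seed Integer seed recorded in the manifest (the screen itself is
#'   deterministic given its inputs).
#' @param verbose Print progress to stderr (default TRUE).
#' @return A list of class `run_config`.
#' @export
run_config <- function(expression, metadata, gmt, out_dir,
                       K_max = 5L, test = "LRT", include_batch = TRUE,
                       variance_floor = 1e-8, min_size = 5L, alpha = 0.05,
                       seed = 1L, verbose = TRUE) {
  structure(list(expression = expression, metadata = metadata, gmt = gmt,
                 out_dir = out_dir, K_max = as.integer(K_max), test = test,
                 include_batch = include_batch,
                 variance_floor = variance_floor,
                 min_size = as.integer(min_size), alpha = alpha,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

#' Run a complete gene set screen from files
#'
#' Reads the expression matrix, metadata and GMT collection named in the
#' config, restricts to measured genes, fits the set-level mixed model to
#' every surviving set, adjusts by BH FDR, and writes three files to
#' `out_dir`: `screen_table.tsv` (4-significant-digit p-values),
#' `screen_table.json` (full precision) and `manifest.json` (config,
#' versions, per-set warnings). Outputs are fully determined by the config
#' and inputs, so a re-run reproduces the table byte for byte.
#'
#' @param config A [run_config()] or the path of a YAML file for
#'   [read_run_config()].
#' @return The `mmgsa_screen` table, invisibly.
#' @export
run_screen <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message(...)
  for (f in c(config$expression, config$metadata, config$gmt)) {
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say("reading inputs")
  dat <- read_expression(config$expression, config$metadata)
  collection <- read_gmt(config$gmt)
  spec <- model_spec(K_max = config$K_max, test = config$test,
                     include_batch = config$include_batch,
                     variance_floor = config$variance_floor)
  say(sprintf("screening %d candidate set(s)", length(collection)))
  tab <- screen_gene_sets(collection, dat$expression, dat$metadata,
                          spec = spec, min_size = config$min_size)
  write_screen_table(tab, file.path(config$out_dir, "screen_table.tsv"))
  jsonlite::write_json(as.data.frame(tab),
                       file.path(config$out_dir, "screen_table.json"),
                       digits = NA, auto_unbox = TRUE)
  manifest <- list(
    tool = "mmgsa", version = as.character(utils::packageVersion("mmgsa")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config),
    n_sets_screened = nrow(tab),
    n_converged = sum(tab$converged),
    warnings = as.list(attr(tab, "warnings")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  say(sprintf("done: %d set(s) screened, %d converged",
              nrow(tab), sum(tab$converged)))
  invisible(tab)
}

#' Export a row-standardized heat-map matrix for one gene set
#'
#' Standardizes each member gene (subtract row mean, divide by row SD) and
#' orders columns controls first, then cases, preserving within-group input
#' order -- the layout used for expression heat maps of a candidate set.
#' Constant rows are emitted as zeros with a warning.
#'
#' @param set_name Name of a set in `collection`.
#' @param collection A [gene_set_collection()].
#' @param expression Numeric log2 expression matrix.
#' @param metadata Sample metadata.
#' @param path Optional TSV output path.
#' @return The standardized matrix (invisible when `path` is given), with
#'   the column ordering in attribute `"sample_order"`.
#' @export
export_heatmap_matrix <- function(set_name, collection, expression,
                                  metadata, path = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!set_name %in% names(collection)) {
    stop("unknown gene set: ", set_name, call. = FALSE)
  }
  metadata <- validate_metadata(metadata, samples = colnames(expression))
  genes <- intersect(collection[[set_name]], rownames(expression))
  if (length(genes) == 0L) {
    stop("no measured genes in set: ", set_name, call. = FALSE)
  }
  ord <- c(which(metadata$group == "control"),
           which(metadata$group == "case"))
  x <- expression[genes, ord, drop = FALSE]
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  flat <- sdv == 0
  if (any(flat)) {
    warning("constant row(s) emitted as zeros: ",
            paste(genes[flat], collapse = ", "), call. = FALSE)
    sdv[flat] <- 1
  }
  z <- (x - mu) / sdv
  z[flat, ] <- 0
  attr(z, "sample_order") <- colnames(expression)[ord]
  if (!is.null(path)) {
    df <- data.frame(gene = rownames(z), z, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(z))
  }
  z
}
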