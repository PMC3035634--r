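test_that("read_gmt parses well-formed records and dedups genes", {
  path <- write_tmp_gmt(c("APOPTOSIS_GO\tna\tHDAC3\tNFKB1",
                          "S1\tdesc\tG1\tG1\tG2"))
  gsc <- read_gmt(path)
  expect_s3_class(gsc, "gene_set_collection")
  expect_identical(names(gsc), c("APOPTOSIS_GO", "S1"))
  expect_identical(gsc[["APOPTOSIS_GO"]], c("HDAC3", "NFKB1"))
  expect_identical(gsc[["S1"]], c("G1", "G2"))
  expect_identical(unname(attr(gsc, "descriptions")["S1"]), "desc")
})

test_that("read_gmt ignores empty trailing fields and blank lines", {
  path <- write_tmp_gmt(c("S1\tna\tG1\tG2\t\t", "", "S2\tna\tG3"))
  gsc <- read_gmt(path)
  expect_identical(lengths(unclass(gsc)), c(S1 = 2L, S2 = 1L))
})

test_that("read_gmt rejects malformed lines naming the line number", {
  path <- write_tmp_gmt(c("OK\tna\tG1", "S1\tna"))
  expect_error(read_gmt(path), "line 2")
  path2 <- write_tmp_gmt(c("S1\tna\tG1", "S1\tna\tG2"))
  expect_error(read_gmt(path2), "duplicate")
})

test_that("GMT write then read round-trips to an identical collection", {
  sets <- list(A = c("G1", "G2", "G3"), B = c("G4", "G2"))
  gsc <- gene_set_collection(sets, descriptions = c("first", "second"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gsc, path)
  back <- read_gmt(path)
  expect_identical(unclass(back)[], unclass(gsc)[])
  expect_identical(attr(back, "descriptions"), attr(gsc, "descriptions"))
})

test_that("restrict_to_measured applies the size filter on measured genes", {
  gsc <- gene_set_collection(list(
    big = sprintf("G%02d", 1:10),   # 6 measured
    small = sprintf("G%02d", 1:10), # only 4 measured after universe cut
    all_in = c("G01", "G02", "G03", "G04", "G05")))
  measured6 <- sprintf("G%02d", 1:6)
  r <- restrict_to_measured(gsc[c("big", "all_in")], measured6, min_size = 5)
  expect_identical(lengths(unclass(r)), c(big = 6L, all_in = 5L))
  r2 <- restrict_to_measured(gsc["small"], sprintf("G%02d", 1:4), min_size = 5)
  expect_length(r2, 0L)
  # all genes measured -> identity
  r3 <- restrict_to_measured(gsc, sprintf("G%02d", 1:10), min_size = 5)
  expect_identical(unclass(r3)[], unclass(gsc)[])
})

test_that("restrict_to_measured is idempotent and validates inputs", {
  gsc <- gene_set_collection(list(A = sprintf("G%d", 1:8)))
  once <- restrict_to_measured(gsc, sprintf("G%d", 1:6))
  twice <- restrict_to_measured(once, sprintf("G%d", 1:6))
  expect_identical(unclass(once)[], unclass(twice)[])
  expect_error(restrict_to_measured(gsc, character(0)), "empty")
  expect_error(restrict_to_measured(gsc, "G1", min_size = 1), "min_size")
})

test_that("expression/metadata TSVs round-trip and cross-validate", {
  d <- tiny_instance(G = 3, n1 = 4, n2 = 4, seed = 3)
  ep <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_expression(d$expr, ep, d$meta, mp)
  back <- read_expression(ep, mp)
  expect_equal(back$expression, d$expr, tolerance = 1e-12)
  expect_identical(back$metadata$sample, colnames(d$expr))

  # metadata missing one sample -> error listing it
  meta_bad <- d$meta[-2L, ]
  mp2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(meta_bad, mp2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_expression(ep, mp2), d$meta$sample[2L])
})

test_that("read_expression rejects duplicate genes and non-numeric cells", {
  d <- tiny_instance(G = 3, n1 = 4, n2 = 4, seed = 4)
  ep <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  dup <- rbind(d$expr, d$expr[1L, , drop = FALSE])
  df <- data.frame(gene = rownames(dup), dup, check.names = FALSE)
  utils::write.table(df, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(d$meta, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(ep, mp), "duplicated gene")

  df2 <- data.frame(gene = rownames(d$expr), d$expr, check.names = FALSE)
  df2[2L, 3L] <- "not_a_number"
  utils::write.table(df2, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(ep, mp), "non-numeric")
})

test_that("metadata validation enforces the group/subject design", {
  d <- tiny_instance(G = 2, n1 = 4, n2 = 4, seed = 5)
  m <- d$meta
  m$group[1L] <- "patient"
  expect_error(validate_metadata(m), "case")
  m2 <- d$meta
  m2$subject <- "same_person"           # one subject spanning both groups
  expect_error(validate_metadata(m2), "more than one group")
  m3 <- d$meta
  m3$group <- c("case", rep("control", 7L))
  expect_error(validate_metadata(m3), "at least 2 samples")
})
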