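test_that("series-matrix parsing returns the probe-by-sample table", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_series_matrix_fixture(
    path, c("ID_REF", "GSM1", "GSM2"),
    list(c("p1", "3.1", "4.2"), c("p2", "5.0", "6.0"), c("p3", "2.2", "2.4")))
  ds <- read_series_matrix(path)
  expect_s3_class(ds, "expression_dataset")
  expect_equal(dim(ds$values), c(3L, 2L))
  expect_equal(ds$gene_ids, c("p1", "p2", "p3"))
  expect_equal(ds$sample_ids, c("GSM1", "GSM2"))
  expect_equal(ds$scale, "log2")   # values all <= 30
  expect_null(ds$group_labels)
  expect_equal(unname(ds$values["p2", ]), c(5, 6))
})

test_that("series-matrix format violations are rejected", {
  no_end <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("!series_matrix_table_begin", "ID_REF\tGSM1", "p1\t3"), no_end)
  expect_error(read_series_matrix(no_end), "delimiters")

  ragged <- withr::local_tempfile(fileext = ".txt")
  write_series_matrix_fixture(ragged, c("ID_REF", "GSM1", "GSM2"),
                              list(c("p1", "3.1", "4.2"), c("p2", "5.0")))
  expect_error(read_series_matrix(ragged), "ragged")

  dup <- withr::local_tempfile(fileext = ".txt")
  write_series_matrix_fixture(dup, c("ID_REF", "GSM1"),
                              list(c("p1", "3"), c("p1", "4")))
  expect_error(read_series_matrix(dup), "duplicate ID_REF")
})

test_that("probes with missing-value tokens are dropped, the rest kept", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_series_matrix_fixture(
    path, c("ID_REF", "GSM1", "GSM2"),
    list(c("p1", "3.5", "null"), c("p2", "5.0", "6.0"),
         c("p3", "NA", "2.4"), c("p4", "7.5", "8.0")))
  ds <- read_series_matrix(path)
  expect_equal(ds$gene_ids, c("p2", "p4"))
  expect_equal(dim(ds$values), c(2L, 2L))
})

test_that("log-scale detection uses the 99th percentile, not the maximum", {
  expect_equal(detect_log_scale(matrix(runif(50, 2, 14), 10)), "log2")
  expect_equal(detect_log_scale(matrix(runif(50, 50, 20000), 10)), "linear")
  # 199 log-like values plus one enormous outlier: 99th percentile is 10
  with_outlier <- c(rep(10, 199), 1e6)
  expect_equal(unname(quantile(with_outlier, 0.99)), 10)
  expect_equal(detect_log_scale(with_outlier), "log2")
  expect_error(detect_log_scale(matrix(NA_real_, 2, 2)), "no finite values")
})

test_that("to_linear exponentiates base 2 and is idempotent", {
  ds <- make_dataset(matrix(c(3, 0, 1, 2), 2), scale = "log2")
  lin <- to_linear(ds)
  expect_equal(lin$scale, "linear")
  expect_equal(unname(lin$values), matrix(c(8, 1, 2, 4), 2))
  expect_identical(to_linear(lin), lin)
  already <- make_dataset(matrix(c(100, 200, 300, 400), 2), scale = "linear")
  expect_identical(to_linear(already), already)
})

test_that("sample annotation validates coverage and both groups", {
  ds <- make_dataset(matrix(1:8, 2), annotate = FALSE)
  ok <- annotate_samples(ds, c(s1 = "condition", s2 = "condition",
                               s3 = "control", s4 = "control"))
  expect_equal(ok$group_labels, c("condition", "condition", "control", "control"))
  expect_error(annotate_samples(ds, rep("condition", 4)), "control")
  expect_error(annotate_samples(ds, c(s1 = "condition", s2 = "control",
                                      s3 = "control", sX = "condition")),
               "unknown sample")
  expect_error(annotate_samples(ds, c(s1 = "condition", s2 = "control")),
               "without a label")
})

test_that("probe collapsing keeps the max-mean probe and drops unmapped ones", {
  vals <- rbind(p1 = c(100, 100, 100, 100),   # gene G, mean 100
                p2 = c(400, 400, 400, 400),   # gene G, mean 400 -> wins
                p3 = c(50, 60, 70, 80),       # gene H, single probe
                p4 = c(1, 2, 3, 4))           # unmapped -> dropped
  ds <- make_dataset(vals)
  map <- mapping_table(c("p1", "p2", "p3"), c("G", "G", "H"), "probe_to_gene")
  out <- collapse_probes(ds, map)
  expect_setequal(out$gene_ids, c("G", "H"))
  expect_equal(unname(out$values["G", ]), rep(400, 4))
  expect_equal(unname(out$values["H", ]), c(50, 60, 70, 80))
  none <- mapping_table("pX", "G", "probe_to_gene")
  expect_error(collapse_probes(ds, none), "no probe")
})

test_that("gene harmonization unions gene sets without inventing ids", {
  a <- make_dataset(matrix(1:8, 2, dimnames = list(c("a", "b"), NULL)))
  b <- make_dataset(matrix(1:8, 2, dimnames = list(c("b", "c"), NULL)))
  out <- harmonize_genes(list(a, b))
  expect_equal(attr(out, "universe"), c("a", "b", "c"))
  presence <- table(unlist(lapply(out, `[[`, "gene_ids")))
  expect_equal(unname(presence[c("a", "b", "c")]), c(1L, 2L, 1L),
               ignore_attr = TRUE)
  expect_equal(out[[1]]$gene_ids, c("a", "b"))  # same organism: untouched
})

test_that("cross-organism harmonization maps ortholog groups or fails", {
  mouse <- make_dataset(matrix(1:8, 2, dimnames = list(c("m1", "m2"), NULL)),
                        organism = "mouse")
  rat <- make_dataset(matrix(1:8, 2, dimnames = list(c("r1", "r3"), NULL)),
                      organism = "rat")
  expect_error(harmonize_genes(list(mouse, rat)), "ortholog")
  orth <- mapping_table(c("m1", "r1", "m2", "r3"),
                        c("og1", "og1", "og2", "og3"), "ortholog")
  out <- harmonize_genes(list(mouse, rat), orth)
  expect_equal(out[[1]]$gene_ids, c("og1", "og2"))
  expect_equal(out[[2]]$gene_ids, c("og1", "og3"))
  expect_equal(attr(out, "universe"), c("og1", "og2", "og3"))
})

test_that("TSV write/read round trip reproduces the matrix exactly", {
  set.seed(42)
  ds <- make_dataset(matrix(rlnorm(24, 5, 2), 4), id = "rt")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(ds, path)
  back <- read_expression_tsv(path, dataset_id = "rt", scale = "linear")
  expect_equal(back$values, ds$values)
  expect_equal(back$gene_ids, ds$gene_ids)
  expect_equal(back$sample_ids, ds$sample_ids)
})

test_that("cleaning drops missing and nonpositive gene rows", {
  vals <- rbind(ok = c(1, 2, 3, 4), neg = c(1, -2, 3, 4),
                zero = c(0, 1, 2, 3), na = c(1, NA, 3, 4))
  ds <- make_dataset(vals)
  out <- drop_incomplete_genes(ds)
  expect_equal(out$gene_ids, "ok")
})
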