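#' Read a GEO series-matrix file
#'
#' Parses the tab-separated exchange format used by the Gene Expression
#' Omnibus: metadata lines prefixed `!`, then a probe-by-sample table
#' between `!series_matrix_table_begin` and `!series_matrix_table_end`
#' whose first column is `ID_REF` and whose remaining columns are sample
#' accessions. Values may be quoted; `null`, `NA` and empty tokens are
#' treated as missing and any probe row containing a missing value is
#' dropped (no imputation). The measurement scale is guessed with
#' [detect_log_scale()]; samples are returned unannotated.
#'
#' @param path path to an uncompressed series-matrix text file.
#' @param dataset_id provenance label; defaults to the file name.
#' @return an [expression_dataset()] with probe-level gene ids.
#' @export
read_series_matrix <- function(path, dataset_id = NULL) {
  if (is.null(dataset_id))
    dataset_id <- sub("\\.(txt|tsv)$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1 || length(end) != 1 || end <= begin + 1)
    stop("not a series-matrix file: table delimiters missing or empty table")
  body <- lines[(begin + 1):(end - 1)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) gsub('^"|"$', "", f))
  widths <- lengths(fields)
  if (length(unique(widths)) != 1)
    stop("ragged series-matrix table: rows have differing column counts")
  header <- fields[[1]]
  if (toupper(header[1]) != "ID_REF")
    stop("series-matrix table must start with an ID_REF column")
  sample_ids <- header[-1]
  rows <- fields[-1]
  probes <- vapply(rows, `[[`, character(1), 1L)
  if (anyDuplicated(probes))
    stop("duplicate ID_REF entries: ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  vals <- t(vapply(rows, function(f) {
    x <- f[-1]
    x[x %in% c("", "null", "NULL", "NA", "na")] <- NA_character_
    suppressWarnings(as.numeric(x))
  }, numeric(length(sample_ids))))
  keep <- apply(vals, 1L, function(x) !anyNA(x))
  vals <- vals[keep, , drop = FALSE]
  probes <- probes[keep]
  if (nrow(vals) == 0) stop("series-matrix table contains no complete probe rows")
  expression_dataset(vals, gene_ids = probes, sample_ids = sample_ids,
                     dataset_id = dataset_id)
}

#' Read / write plain TSV expression matrices
#'
#' The TSV dialect: a header row of sample ids, a first column of gene ids
#' (any column name), numeric values elsewhere. [write_expression_tsv()]
#' uses full precision so a write/read round trip reproduces the matrix
#' exactly.
#'
#' @param path file path.
#' @param dataset_id provenance label; defaults to the file name.
#' @param scale `"linear"`, `"log2"`, or `NULL` to auto-detect.
#' @param organism passed to [expression_dataset()].
#' @return an [expression_dataset()] (unannotated).
#' @export
read_expression_tsv <- function(path, dataset_id = NULL, scale = NULL,
                                organism = "unknown") {
  if (is.null(dataset_id))
    dataset_id <- sub("\\.(txt|tsv)$", "", basename(path))
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression TSV needs a gene-id column plus samples")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  expression_dataset(vals, gene_ids = as.character(tab[[1]]),
                     sample_ids = colnames(tab)[-1],
                     scale = scale, dataset_id = dataset_id,
                     organism = organism)
}

#' @rdname read_expression_tsv
#' @param dataset an [expression_dataset()] to write.
#' @export
write_expression_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- data.frame(gene_id = dataset$gene_ids,
                   format(dataset$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", dataset$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an identifier mapping table
#'
#' Two-column headerless TSV of `(source_id, target_id)` pairs: probe to
#' gene, or organism-specific gene to ortholog-group id. Source ids may
#' repeat (several probes per gene); empty ids are rejected.
#'
#' @param path file path.
#' @param direction `"probe_to_gene"` or `"ortholog"`.
#' @return a `mapping_table`: data frame `(source_id, target_id)` with a
#'   `direction` attribute.
#' @export
read_mapping_table <- function(path, direction = c("probe_to_gene", "ortholog")) {
  direction <- match.arg(direction)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("mapping table needs two columns")
  mapping_table(tab[[1]], tab[[2]], direction)
}

#' @rdname read_mapping_table
#' @param source_id,target_id character vectors of equal length.
#' @export
mapping_table <- function(source_id, target_id,
                          direction = c("probe_to_gene", "ortholog")) {
  direction <- match.arg(direction)
  source_id <- as.character(source_id)
  target_id <- as.character(target_id)
  if (length(source_id) != length(target_id))
    stop("source and target id vectors differ in length")
  if (any(!nzchar(source_id)) || any(!nzchar(target_id)))
    stop("mapping table contains empty identifiers")
  structure(data.frame(source_id = source_id, target_id = target_id,
                       stringsAsFactors = FALSE),
            direction = direction, class = c("mapping_table", "data.frame"))
}

#' Read a sample annotation table
#'
#' Two-column TSV `(sample_id, group)` with `group` in
#' `{"condition", "control"}`; a header row is detected and skipped when
#' its second field is not a valid group label.
#'
#' @param path file path.
#' @return named character vector of labels suitable for
#'   [annotate_samples()].
#' @export
read_sample_annotation <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("annotation table needs two columns")
  if (nrow(tab) > 0 && !(tab[[2]][1] %in% c("condition", "control")))
    tab <- tab[-1, , drop = FALSE]
  stats::setNames(tab[[2]], tab[[1]])
}
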