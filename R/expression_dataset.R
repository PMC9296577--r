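#' Expression data set container
#'
#' Bundles one study's gene-by-sample expression matrix with the sample
#' annotation (condition vs control), the measurement scale and a provenance
#' id. All downstream scoring expects a *linear*-scale, fully annotated
#' data set; use [to_linear()] and [annotate_samples()] to get there.
#'
#' @param values numeric matrix, genes in rows and samples in columns.
#'   Row names are taken as gene (or probe) ids, column names as sample ids;
#'   both may instead be supplied via `gene_ids` / `sample_ids`.
#' @param gene_ids,sample_ids character vectors overriding the dimnames.
#' @param group_labels optional per-sample labels, each `"condition"` or
#'   `"control"`, either unnamed (in column order) or named by sample id.
#' @param scale `"linear"` or `"log2"`; defaults to [detect_log_scale()]
#'   applied to `values`.
#' @param dataset_id short text label identifying the study.
#' @param organism text label (used only to decide whether ortholog mapping
#'   is needed when several data sets are combined).
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `dataset_id`, `gene_ids`, `sample_ids`, `values`, `group_labels`
#'   (`NULL` until annotated), `scale`, `organism`.
#' @export
expression_dataset <- function(values, gene_ids = NULL, sample_ids = NULL,
                               group_labels = NULL, scale = NULL,
                               dataset_id = "dataset", organism = "unknown") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required (dimnames or arguments)")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match the matrix dimensions")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers")
  dimnames(values) <- list(gene_ids, sample_ids)
  if (is.null(scale)) scale <- detect_log_scale(values)
  scale <- match.arg(scale, c("linear", "log2"))
  ds <- structure(
    list(dataset_id = as.character(dataset_id)[1],
         gene_ids = gene_ids, sample_ids = sample_ids,
         values = values, group_labels = NULL,
         scale = scale, organism = as.character(organism)[1]),
    class = "expression_dataset")
  if (!is.null(group_labels)) ds <- annotate_samples(ds, group_labels)
  ds
}

#' @export
print.expression_dataset <- function(x, ...) {
  ann <- if (is.null(x$group_labels)) "unannotated"
         else sprintf("%d condition / %d control",
                      sum(x$group_labels == "condition"),
                      sum(x$group_labels == "control"))
  cat(sprintf("expression_dataset '%s': %d genes x %d samples, %s scale, %s (%s)\n",
              x$dataset_id, nrow(x$values), ncol(x$values), x$scale, ann,
              x$organism))
  invisible(x)
}

is_annotated <- function(dataset) !is.null(dataset$group_labels)

#' Guess whether an expression matrix is log2- or linear-scale
#'
#' GEO series matrices rarely state their scale. The heuristic used here
#' calls a matrix log2 when its 99th-percentile value is at most 30 —
#' log2 microarray intensities live roughly in \[0, 20\] while linear
#' intensities reach the thousands — so a handful of extreme outliers in an
#' otherwise log-looking matrix does not flip the call.
#'
#' @param values numeric matrix or vector.
#' @return `"log2"` or `"linear"`.
#' @export
detect_log_scale <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) == 0) stop("cannot detect scale: no finite values")
  if (stats::quantile(x, 0.99, names = FALSE) <= 30) "log2" else "linear"
}

#' Convert a data set to linear scale
#'
#' Most public expression data sets ship log2-transformed; the coefficient
#' of variation and group fold change are defined on raw values, so
#' log2-scale matrices are exponentiated (base 2) first. Linear data sets
#' pass through unchanged, making the operation idempotent.
#'
#' @param dataset an [expression_dataset()].
#' @return the data set on linear scale.
#' @export
to_linear <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$scale == "linear") return(dataset)
  dataset$values <- 2^dataset$values
  dataset$scale <- "linear"
  dataset
}

#' Annotate samples as condition or control
#'
#' @param dataset an [expression_dataset()].
#' @param labels per-sample labels in `{"condition", "control"}`, either a
#'   character vector named by sample id (any order, must cover every sample
#'   exactly once), an unnamed vector in column order, or a two-column
#'   data frame `(sample_id, group)`.
#' @return the data set with `group_labels` set; both groups are guaranteed
#'   non-empty.
#' @export
annotate_samples <- function(dataset, labels) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.data.frame(labels)) {
    if (ncol(labels) < 2) stop("annotation table needs two columns (sample_id, group)")
    labels <- stats::setNames(as.character(labels[[2]]), as.character(labels[[1]]))
  }
  labels <- unlist(labels)
  if (is.null(names(labels))) {
    if (length(labels) != length(dataset$sample_ids))
      stop("unnamed labels must match the number of samples")
    names(labels) <- dataset$sample_ids
  }
  unknown <- setdiff(names(labels), dataset$sample_ids)
  if (length(unknown) > 0)
    stop("labels given for unknown sample ids: ", paste(unknown, collapse = ", "))
  missing <- setdiff(dataset$sample_ids, names(labels))
  if (length(missing) > 0)
    stop("samples without a label: ", paste(missing, collapse = ", "))
  if (anyDuplicated(names(labels))) stop("duplicate labels for a sample id")
  labels <- labels[dataset$sample_ids]
  if (!all(labels %in% c("condition", "control")))
    stop("labels must be 'condition' or 'control'")
  if (!all(c("condition", "control") %in% labels))
    stop("both a condition and a control group are required")
  dataset$group_labels <- unname(labels)
  dataset
}

#' Drop gene rows unusable for scoring
#'
#' CV and fold change are undefined for genes with missing or nonpositive
#' linear values, so such rows are removed from the data set (and treated
#' downstream as absent from it). No imputation is attempted.
#'
#' @param dataset a linear-scale [expression_dataset()].
#' @return the data set restricted to complete, strictly positive gene rows.
#' @export
drop_incomplete_genes <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$scale != "linear")
    stop("convert to linear scale before cleaning (to_linear)")
  ok <- apply(dataset$values, 1L, function(x) all(is.finite(x)) && all(x > 0))
  if (!all(ok)) {
    dataset$values <- dataset$values[ok, , drop = FALSE]
    dataset$gene_ids <- dataset$gene_ids[ok]
  }
  if (nrow(dataset$values) == 0)
    stop("no usable gene rows left in dataset '", dataset$dataset_id, "'")
  dataset
}
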