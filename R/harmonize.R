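#' Collapse probe-level rows to genes
#'
#' Microarray platforms carry several probes per gene. For each gene the
#' probe with the highest mean expression is kept as the gene's row —
#' averaging would blend cross-hybridizing probes of very different
#' intensity. Probes without a mapping entry are dropped.
#'
#' @param dataset an [expression_dataset()] with probe-level gene ids.
#' @param mapping a `mapping_table` with direction `"probe_to_gene"`.
#' @return the data set re-indexed by gene id.
#' @export
collapse_probes <- function(dataset, mapping) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(mapping, "mapping_table"))
  if (attr(mapping, "direction") != "probe_to_gene")
    stop("mapping direction must be probe_to_gene")
  hit <- match(dataset$gene_ids, mapping$source_id)
  keep <- which(!is.na(hit))
  if (length(keep) == 0)
    stop("no probe of dataset '", dataset$dataset_id,
         "' is present in the mapping table")
  genes <- mapping$target_id[hit[keep]]
  vals <- dataset$values[keep, , drop = FALSE]
  means <- rowMeans(vals)
  # max-mean probe per gene; ties broken by probe order for reproducibility
  ord <- order(genes, -means, keep)
  sel <- ord[!duplicated(genes[ord])]
  dataset$values <- vals[sel, , drop = FALSE]
  dataset$gene_ids <- genes[sel]
  rownames(dataset$values) <- dataset$gene_ids
  dataset
}

#' Put several data sets on a shared gene namespace
#'
#' When the data sets come from one organism the gene ids are already
#' comparable and pass through unchanged. Across organisms an ortholog
#' table is required; every gene with an entry is renamed to its
#' ortholog-group id (should two genes of one data set land in the same
#' group, the higher-mean row is kept). Gene sets are *not* intersected:
#' each data set keeps its own genes, and the union of all gene ids forms
#' the universe over which rankings are aggregated.
#'
#' @param datasets list of probe-collapsed [expression_dataset()] objects.
#' @param orthology optional `mapping_table` with direction `"ortholog"`.
#' @return the list of data sets, with a `universe` attribute holding the
#'   sorted union of gene ids (see also [gene_universe()]).
#' @export
harmonize_genes <- function(datasets, orthology = NULL) {
  stopifnot(length(datasets) >= 1,
            all(vapply(datasets, inherits, logical(1), "expression_dataset")))
  organisms <- unique(vapply(datasets, `[[`, character(1), "organism"))
  if (length(organisms) > 1 && is.null(orthology))
    stop("data sets span organisms (", paste(organisms, collapse = ", "),
         ") but no ortholog table was supplied")
  if (!is.null(orthology)) {
    if (attr(orthology, "direction") != "ortholog")
      stop("mapping direction must be ortholog")
    datasets <- lapply(datasets, function(ds) {
      hit <- match(ds$gene_ids, orthology$source_id)
      new_ids <- ifelse(is.na(hit), ds$gene_ids, orthology$target_id[hit])
      if (anyDuplicated(new_ids)) {
        means <- rowMeans(ds$values)
        ord <- order(new_ids, -means, seq_along(new_ids))
        sel <- sort(ord[!duplicated(new_ids[ord])])
        ds$values <- ds$values[sel, , drop = FALSE]
        new_ids <- new_ids[sel]
      }
      ds$gene_ids <- new_ids
      rownames(ds$values) <- new_ids
      ds
    })
  }
  structure(datasets, universe = gene_universe(datasets))
}

#' @rdname harmonize_genes
#' @export
gene_universe <- function(datasets) {
  sort(unique(unlist(lapply(datasets, `[[`, "gene_ids"))))
}
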