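# shared fixture builders: everything generated in code, nothing on disk

# quick annotated linear dataset; first half of columns = condition
make_dataset <- function(values, scale = "linear", id = "ds",
                         annotate = TRUE, organism = "mouse") {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  labels <- if (annotate)
    rep(c("condition", "control"), each = ncol(values) / 2)
  expression_dataset(values, group_labels = labels, scale = scale,
                     dataset_id = id, organism = organism)
}

# minimal GEO series-matrix file; rows = character vectors of cells
write_series_matrix_fixture <- function(path, header, rows,
                                        begin = "!series_matrix_table_begin",
                                        end = "!series_matrix_table_end") {
  lines <- c("!Series_title\t\"fixture\"",
             begin,
             paste(header, collapse = "\t"),
             vapply(rows, paste, character(1), collapse = "\t"),
             end)
  writeLines(lines[nzchar(lines)], path)
  path
}

# hand-rolled dataset_ranking for aggregation tests
make_ranking <- function(id, gene_ids, dataset_rank) {
  structure(list(dataset_id = id,
                 scores = data.frame(gene_id = gene_ids,
                                     cv = NA_real_, fc = NA_real_,
                                     rank_cv = NA_real_, rank_fc = NA_real_,
                                     rank_product = dataset_rank,
                                     dataset_rank = dataset_rank,
                                     stringsAsFactors = FALSE)),
            class = "dataset_ranking")
}

# hand-rolled rank_distribution for penalty tests
make_distribution <- function(gene_ids, mean_rank, presence, n_datasets) {
  structure(list(table = data.frame(gene_id = gene_ids, mean_rank = mean_rank,
                                    rank_sd = 0, presence_count = presence,
                                    stringsAsFactors = FALSE),
                 n_datasets = n_datasets, repetitions = 1L, seed = NA_integer_,
                 samples = NULL),
            class = "rank_distribution")
}

# exact bootstrap expectation for TWO data sets: enumerate the resampling
# multisets {AA, AB, BB} with probabilities 1/4, 1/2, 1/4
enumerate_two_dataset_bootstrap <- function(rankings, universe) {
  G <- length(universe)
  rank_mat <- sapply(rankings, function(r)
    r$scores$dataset_rank[match(universe, r$scores$gene_id)])
  per_multiset <- function(cols) {
    m <- rowMeans(rank_mat[, cols, drop = FALSE], na.rm = TRUE)
    m[!is.finite(m)] <- G
    rank(m, ties.method = "average")
  }
  r_aa <- per_multiset(c(1, 1)); r_ab <- per_multiset(c(1, 2))
  r_bb <- per_multiset(c(2, 2))
  mean_rank <- 0.25 * r_aa + 0.5 * r_ab + 0.25 * r_bb
  var_rank <- 0.25 * (r_aa - mean_rank)^2 + 0.5 * (r_ab - mean_rank)^2 +
    0.25 * (r_bb - mean_rank)^2
  list(mean = mean_rank, var = var_rank)
}

# exact hypergeometric upper tail by direct summation over choose()
brute_force_overlap_tail <- function(k, n1, n2, universe) {
  j <- k:min(n1, n2)
  sum(choose(n1, j) * choose(universe - n1, n2 - j)) / choose(universe, n2)
}
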