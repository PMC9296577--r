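#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the arithmetic
#' mean — the unitless dispersion measure that lets genes of very different
#' absolute expression be compared on one noise scale. A good reference
#' gene has a low CV across *all* samples of a study, condition and control
#' alike.
#'
#' @param values positive numeric vector, length at least 2.
#' @return non-negative scalar.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2)
    stop("coefficient of variation needs at least two values")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("coefficient of variation requires strictly positive finite values")
  stats::sd(values) / mean(values)
}

#' Condition-vs-control fold change, inverted below 1
#'
#' Ratio of group means on linear scale; ratios below 1 are reciprocated so
#' that 1 means "unchanged" and larger values mean stronger change in
#' either direction. Reference-gene candidates should sit near 1.
#'
#' @param condition_values,control_values positive numeric vectors.
#' @return scalar fold change, always >= 1.
#' @export
group_fold_change <- function(condition_values, control_values) {
  if (length(condition_values) == 0 || length(control_values) == 0)
    stop("both sample groups must be non-empty")
  if (any(c(condition_values, control_values) <= 0))
    stop("fold change requires strictly positive linear-scale values")
  fc <- mean(condition_values) / mean(control_values)
  if (fc < 1) 1 / fc else fc
}

#' Score one data set: CV + fold change -> joint rank product
#'
#' For every gene the CV is computed over all samples and the inverted
#' fold change between condition and control group means. Both criteria
#' are ranked independently in ascending order (low = good, ties averaged)
#' and multiplied into a joint rank product; the data set's final per-gene
#' rank (`dataset_rank`) is the ascending rank of that product, so that
#' rankings from data sets of different gene counts live on comparable
#' rank scales before aggregation.
#'
#' @param dataset an annotated, linear-scale [expression_dataset()] with
#'   strictly positive values (see [drop_incomplete_genes()]).
#' @return a `dataset_ranking`: list with `dataset_id` and a data frame
#'   `scores` holding per gene `cv`, `fc`, `rank_cv`, `rank_fc`,
#'   `rank_product` and `dataset_rank`.
#' @export
score_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!is_annotated(dataset))
    stop("dataset '", dataset$dataset_id, "' has no condition/control annotation")
  if (dataset$scale != "linear")
    stop("dataset '", dataset$dataset_id, "' must be linear scale (to_linear)")
  v <- dataset$values
  if (nrow(v) < 2)
    stop("dataset '", dataset$dataset_id, "' has fewer than two genes")
  if (any(!is.finite(v)) || any(v <= 0))
    stop("dataset '", dataset$dataset_id,
         "' contains missing or nonpositive values; run drop_incomplete_genes first")
  n <- ncol(v)
  mu <- rowMeans(v)
  cv <- sqrt(rowSums((v - mu)^2) / (n - 1)) / mu
  cond <- dataset$group_labels == "condition"
  fc <- rowMeans(v[, cond, drop = FALSE]) / rowMeans(v[, !cond, drop = FALSE])
  fc <- ifelse(fc < 1, 1 / fc, fc)
  rank_cv <- rank(cv, ties.method = "average")
  rank_fc <- rank(fc, ties.method = "average")
  rank_product <- rank_cv * rank_fc
  structure(
    list(dataset_id = dataset$dataset_id,
         scores = data.frame(
           gene_id = dataset$gene_ids, cv = cv, fc = fc,
           rank_cv = rank_cv, rank_fc = rank_fc,
           rank_product = rank_product,
           dataset_rank = rank(rank_product, ties.method = "average"),
           row.names = NULL, stringsAsFactors = FALSE)),
    class = "dataset_ranking")
}

#' Aggregate per-dataset rankings by dataset-level bootstrapping
#'
#' Resamples whole *data sets* with replacement (D draws from D data sets
#' per repetition). In each repetition every gene receives the mean of its
#' `dataset_rank` over the drawn data sets in which it is present; a gene
#' absent from every drawn data set scores the universe size (the worst
#' plausible rank), and the genes are then ranked by that mean (ascending,
#' ties averaged) to give one bootstrap rank per gene per repetition.
#' Because only ranks cross data-set boundaries, studies from different
#' platforms can be combined without cross-platform normalization or batch
#' correction.
#'
#' @param rankings list of at least two `dataset_ranking` objects.
#' @param universe gene universe; defaults to the union of genes over the
#'   rankings (supplying it explicitly only makes sense to add genes known
#'   to exist but measured nowhere).
#' @param repetitions number of bootstrap repetitions (default 10000).
#' @param seed integer seed making the resampling reproducible; `NULL`
#'   uses the current RNG state.
#' @param keep_samples if `TRUE` the full repetitions-by-genes matrix of
#'   bootstrap ranks is retained in the result (memory grows with
#'   `repetitions * |universe|`).
#' @return a `rank_distribution`: list with `table` (data frame `gene_id`,
#'   `mean_rank`, `rank_sd`, `presence_count`), `n_datasets`,
#'   `repetitions`, `seed`, and optionally `samples`.
#' @export
bootstrap_rankings <- function(rankings, universe = NULL, repetitions = 10000L,
                               seed = NULL, keep_samples = FALSE) {
  stopifnot(all(vapply(rankings, inherits, logical(1), "dataset_ranking")))
  if (length(rankings) < 2)
    stop("at least two data sets are required for bootstrapping")
  repetitions <- as.integer(repetitions)
  if (is.na(repetitions) || repetitions < 1)
    stop("repetitions must be a positive integer")
  if (is.null(universe))
    universe <- sort(unique(unlist(lapply(rankings,
                                          function(r) r$scores$gene_id))))
  D <- length(rankings)
  G <- length(universe)
  ranks <- matrix(NA_real_, nrow = G, ncol = D,
                  dimnames = list(universe, NULL))
  for (d in seq_len(D)) {
    s <- rankings[[d]]$scores
    idx <- match(s$gene_id, universe)
    if (anyNA(idx)) stop("ranking contains genes outside the universe")
    ranks[idx, d] <- s$dataset_rank
  }
  presence <- as.integer(rowSums(!is.na(ranks)))
  if (!is.null(seed)) set.seed(as.integer(seed))
  s1 <- numeric(G)
  s2 <- numeric(G)
  samples <- if (keep_samples)
    matrix(NA_real_, nrow = G, ncol = repetitions,
           dimnames = list(universe, NULL))
  for (r in seq_len(repetitions)) {
    drawn <- sample.int(D, D, replace = TRUE)
    m <- rowMeans(ranks[, drawn, drop = FALSE], na.rm = TRUE)
    m[!is.finite(m)] <- G
    br <- rank(m, ties.method = "average")
    s1 <- s1 + br
    s2 <- s2 + br^2
    if (keep_samples) samples[, r] <- br
  }
  mean_rank <- s1 / repetitions
  rank_sd <- if (repetitions > 1)
    sqrt(pmax(0, (s2 - repetitions * mean_rank^2) / (repetitions - 1)))
  else rep(NA_real_, G)
  structure(
    list(table = data.frame(gene_id = universe, mean_rank = mean_rank,
                            rank_sd = rank_sd, presence_count = presence,
                            row.names = NULL, stringsAsFactors = FALSE),
         n_datasets = D, repetitions = repetitions,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         samples = samples),
    class = "rank_distribution")
}

#' Final candidate ranking with absence penalty
#'
#' A gene measured in only part of the compendium is supported by less
#' evidence than one measured everywhere, so its mean bootstrap rank is
#' inflated multiplicatively by `n_datasets / presence_count`. A gene
#' present in every data set keeps its mean rank unchanged; a gene present
#' nowhere scores `+Inf` and is excluded from the reported candidates.
#' Ordering is ascending in the penalized score with a lexicographic
#' tie-break on gene id so that equal scores always list in the same
#' order.
#'
#' @param dist a `rank_distribution` from [bootstrap_rankings()].
#' @param top_n number of candidates to report (default 25).
#' @return a `final_ranking`: list with the full ordered `table`
#'   (`gene_id`, `mean_bootstrap_rank`, `rank_sd`, `presence_count`,
#'   `penalized_score`, `final_rank`), the `top_genes` character vector,
#'   and `top_n`.
#' @export
final_ranking <- function(dist, top_n = 25L) {
  stopifnot(inherits(dist, "rank_distribution"))
  top_n <- as.integer(top_n)
  if (is.na(top_n) || top_n < 1) stop("top_n must be a positive integer")
  tab <- dist$table
  score <- ifelse(tab$presence_count == 0, Inf,
                  tab$mean_rank * dist$n_datasets / tab$presence_count)
  ord <- order(score, tab$gene_id)
  out <- data.frame(gene_id = tab$gene_id[ord],
                    mean_bootstrap_rank = tab$mean_rank[ord],
                    rank_sd = tab$rank_sd[ord],
                    presence_count = tab$presence_count[ord],
                    penalized_score = score[ord],
                    final_rank = seq_along(ord),
                    row.names = NULL, stringsAsFactors = FALSE)
  eligible <- out$gene_id[is.finite(out$penalized_score)]
  structure(list(table = out,
                 top_genes = utils::head(eligible, top_n),
                 top_n = top_n),
            class = "final_ranking")
}

#' @export
print.final_ranking <- function(x, ...) {
  cat(sprintf("final_ranking: %d genes, top %d candidates\n",
              nrow(x$table), x$top_n))
  print(utils::head(x$table, min(x$top_n, 10L)), row.names = FALSE)
  invisible(x)
}

#' Write a final ranking as TSV
#'
#' Columns: `gene_id`, `mean_bootstrap_rank`, `rank_sd`, `presence_count`,
#' `penalized_score`, `final_rank`; one row per universe gene in final
#' order.
#'
#' @param ranking a `final_ranking`.
#' @param path output file.
#' @export
write_ranking_tsv <- function(ranking, path) {
  stopifnot(inherits(ranking, "final_ranking"))
  utils::write.table(ranking$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a ranking TSV back as an ordered gene list
#'
#' @param path a TSV written by [write_ranking_tsv()].
#' @return character vector of gene ids in final-rank order (genes with a
#'   non-finite penalized score excluded).
#' @export
read_ranking_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "final_rank") %in% colnames(tab)))
    stop("not a ranking TSV: gene_id / final_rank columns missing")
  tab <- tab[order(tab$final_rank), ]
  if ("penalized_score" %in% colnames(tab))
    tab <- tab[is.finite(tab$penalized_score), ]
  tab$gene_id
}
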