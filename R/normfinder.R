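#' NormFinder-style expression stability score
#'
#' Models each gene's log2 expression as gene effect + group effect +
#' residual and scores stability from the group-wise residuals. With
#' `z[i,g]` the mean log2 expression of gene `i` in group `g`:
#' `alpha[i]` is the gene's mean over groups, `theta[g]` the *centered*
#' group effect (group mean of `z` over genes minus the grand mean), and
#' `f[i,g] = z[i,g] - theta[g] - alpha[i]` the gene-by-group interaction
#' residual. The stability value is `rho[i] = |mean_g(f[i,g]) +
#' sd_g(f[i,g])|`; small values flag genes whose expression moves with
#' neither group, and `rho < cutoff` calls a gene stable (0.15 by
#' convention for log2 data). Centering `theta` guarantees that an
#' all-constant data set scores exactly 0 while leaving the ordering of
#' genes untouched.
#'
#' @param dataset an annotated [expression_dataset()]; linear-scale values
#'   are log2-transformed internally (genes with nonpositive linear values
#'   are dropped with a warning), log2-scale values are used as-is.
#' @param cutoff stability threshold on rho (default 0.15).
#' @return a `stability_result` data frame with columns `gene_id`, `rho`,
#'   `stable`, plus attributes `f_values` (genes x groups residual matrix)
#'   and `cutoff`.
#' @export
normfinder_stability <- function(dataset, cutoff = 0.15) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!is_annotated(dataset))
    stop("dataset must be annotated with condition/control groups")
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  groups <- unique(dataset$group_labels)
  if (length(groups) < 2) stop("stability scoring needs at least two groups")
  v <- dataset$values
  ids <- dataset$gene_ids
  if (dataset$scale == "linear") {
    ok <- apply(v, 1L, function(x) all(is.finite(x)) && all(x > 0))
    if (!all(ok)) {
      warning(sum(!ok), " gene(s) with missing or nonpositive values dropped")
      v <- v[ok, , drop = FALSE]
      ids <- ids[ok]
    }
    v <- log2(v)
  }
  if (nrow(v) < 2) stop("stability scoring needs at least two genes")
  z <- vapply(groups,
              function(g) rowMeans(v[, dataset$group_labels == g, drop = FALSE]),
              numeric(nrow(v)))
  alpha <- rowMeans(z)
  theta <- colMeans(z) - mean(z)
  f <- sweep(z - alpha, 2L, theta, "-")
  rho <- abs(rowMeans(f) + apply(f, 1L, stats::sd))
  res <- data.frame(gene_id = ids, rho = rho, stable = rho < cutoff,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, f_values = structure(f, dimnames = list(ids, groups)),
            cutoff = cutoff, class = c("stability_result", "data.frame"))
}

#' Fraction of ranked candidates confirmed stable
#'
#' Cross-validates a candidate list against an independent stability
#' assessment: the fraction of the listed genes whose `stable` call is
#' `TRUE`.
#'
#' @param top_genes character vector of candidate gene ids (e.g.
#'   `final_ranking$top_genes`).
#' @param stability a `stability_result` covering every candidate.
#' @return fraction in \[0, 1\].
#' @export
concordance_with_ranking <- function(top_genes, stability) {
  stopifnot(inherits(stability, "stability_result"))
  if (length(top_genes) == 0) stop("empty candidate list")
  hit <- match(top_genes, stability$gene_id)
  if (anyNA(hit))
    stop("no stability result for: ",
         paste(top_genes[is.na(hit)], collapse = ", "))
  mean(stability$stable[hit])
}
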