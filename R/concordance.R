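#' Overlap coefficient of two gene lists
#'
#' `|A intersect B| / min(|A|, |B|)` — 1 when one list contains the other,
#' 0 when disjoint. The standard measure for agreement of fixed-size
#' top-k candidate lists.
#'
#' @param a,b non-empty character vectors without duplicates.
#' @return value in \[0, 1\].
#' @export
overlap_coefficient <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("gene lists must be non-empty")
  if (anyDuplicated(a) || anyDuplicated(b))
    stop("gene lists must not contain duplicates")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Reproducibility measure R over repeated runs
#'
#' The mean pairwise overlap coefficient of the top-k candidate lists from
#' two or more runs (conventionally k = 50). Values near 1 mean the
#' ranking is insensitive to the stochastic part of the procedure (seeds,
#' resampling); values near 0 mean the runs disagree.
#'
#' @param lists list of at least two ordered gene-id vectors.
#' @param k truncation length applied to each list before comparison
#'   (default 50); shorter lists are used whole, with a warning.
#' @return value in \[0, 1\].
#' @export
reproducibility_R <- function(lists, k = 50L) {
  if (!is.list(lists) || length(lists) < 2)
    stop("reproducibility needs at least two gene lists")
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("k must be a positive integer")
  if (any(lengths(lists) < k))
    warning("some lists are shorter than k = ", k, "; used at full length")
  tops <- lapply(lists, utils::head, k)
  pairs <- utils::combn(length(tops), 2L)
  mean(apply(pairs, 2L, function(p)
    overlap_coefficient(tops[[p[1]]], tops[[p[2]]])))
}

#' Hypergeometric overlap test for two gene lists
#'
#' One-sided tail probability `P(X >= k_overlap)` of observing at least
#' the given overlap between a list of `n1` and a list of `n2` genes drawn
#' without replacement from a universe of `universe` genes
#' (`X ~ Hypergeometric(universe, n1, n2)`). Small values mean the two
#' lists share more genes than chance draws from the universe would.
#'
#' @param k_overlap observed intersection size.
#' @param n1,n2 list sizes.
#' @param universe number of genes either list could have drawn from
#'   (typically the ranking's gene-universe size).
#' @return probability in (0, 1].
#' @export
overlap_pvalue <- function(k_overlap, n1, n2, universe) {
  k_overlap <- as.integer(k_overlap); n1 <- as.integer(n1)
  n2 <- as.integer(n2); universe <- as.integer(universe)
  if (anyNA(c(k_overlap, n1, n2, universe)))
    stop("counts must be integers")
  if (k_overlap < 0 || k_overlap > min(n1, n2) || max(n1, n2) > universe)
    stop("inconsistent counts: need 0 <= k_overlap <= min(n1, n2) <= universe")
  stats::phyper(k_overlap - 1L, n1, universe - n1, n2, lower.tail = FALSE)
}
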