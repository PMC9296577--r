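#' Combine a reference panel's Ct values per sample
#'
#' The per-sample arithmetic mean of the panel genes' threshold cycles —
#' equivalent to the geometric mean of their linear expression levels,
#' the standard way of building a multi-gene reference for relative
#' quantification. A panel of one gene returns that gene's Ct unchanged.
#'
#' @param cts data frame or matrix of Ct values, samples in rows, one
#'   column per gene.
#' @param panel character vector of panel gene names (columns of `cts`).
#' @return numeric vector, one combined reference Ct per sample.
#' @export
panel_reference_ct <- function(cts, panel) {
  if (length(panel) == 0) stop("reference panel must contain at least one gene")
  panel <- unique(panel)
  missing <- setdiff(panel, colnames(cts))
  if (length(missing) > 0)
    stop("panel gene(s) not measured: ", paste(missing, collapse = ", "))
  m <- as.matrix(cts[, panel, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m)))
    stop("missing Ct value for a panel gene")
  rowMeans(m)
}

#' Relative quantification by the comparative 2^-ddCt method
#'
#' For every sample, `dCt = Ct(target) - Ct(reference panel)`;
#' `ddCt = dCt - mean(dCt over the control group)`; the relative
#' expression is `2^-ddCt` (amplification efficiency fixed at 2, i.e. a
#' perfect doubling per cycle). Control samples average to a fold change
#' of 1 by construction; condition samples report induction (> 1) or
#' repression (< 1) of the target relative to the reference. Using a
#' multi-gene panel dilutes any instability of an individual reference
#' gene: a +1 Ct shift of one panel member in the condition group inflates
#' the apparent fold change 2-fold when that gene is the sole reference
#' but only 2^(1/k)-fold in a k-gene panel.
#'
#' @param table data frame with columns `sample_id`, `group` (each
#'   `"condition"` or `"control"`), and one numeric Ct column per gene.
#' @param target name of the target gene column.
#' @param panel character vector of reference gene columns.
#' @return list with `per_sample` (data frame `sample_id`, `group`,
#'   `delta_ct`, `delta_delta_ct`, `fold_change`) and `summary` (per-group
#'   mean fold change and its standard error).
#' @export
ddct_fold_change <- function(table, target, panel) {
  if (!all(c("sample_id", "group") %in% colnames(table)))
    stop("Ct table needs sample_id and group columns")
  if (!all(table$group %in% c("condition", "control")))
    stop("group must be 'condition' or 'control'")
  if (!any(table$group == "control")) stop("control group is empty")
  if (!any(table$group == "condition")) stop("condition group is empty")
  if (!(target %in% colnames(table))) stop("target gene not measured: ", target)
  tgt <- as.numeric(table[[target]])
  if (anyNA(tgt) || any(!is.finite(tgt)))
    stop("missing Ct value for the target gene")
  ref <- panel_reference_ct(table, panel)
  dct <- tgt - ref
  ddct <- dct - mean(dct[table$group == "control"])
  fc <- 2^(-ddct)
  per_sample <- data.frame(sample_id = table$sample_id, group = table$group,
                           delta_ct = dct, delta_delta_ct = ddct,
                           fold_change = fc,
                           row.names = NULL, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(c("condition", "control"), function(g) {
    x <- fc[table$group == g]
    data.frame(group = g, n = length(x), mean_fold_change = mean(x),
               sem = stats::sd(x) / sqrt(length(x)),
               stringsAsFactors = FALSE)
  }))
  list(per_sample = per_sample, summary = summ)
}

#' Read a Ct table TSV
#'
#' Columns: `sample_id`, `group`, then one numeric column per gene.
#'
#' @param path file path.
#' @return data frame suitable for [ddct_fold_change()].
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(tab)))
    stop("Ct table needs sample_id and group columns")
  tab
}
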