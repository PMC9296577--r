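#' Rank reference-gene candidates across a compendium
#'
#' The core in-memory pipeline: every annotated data set is brought to
#' linear scale, rows with missing or nonpositive values are dropped,
#' each data set is scored on its own (CV and inverted fold change ranked
#' into a joint rank product), the per-dataset rankings are aggregated by
#' dataset-level bootstrapping, and the mean bootstrap ranks are
#' penalized for genes absent from part of the compendium.
#'
#' @param datasets list of at least two annotated [expression_dataset()]s
#'   on a shared gene namespace (see [harmonize_genes()]).
#' @param repetitions bootstrap repetitions (default 10000).
#' @param top_n candidates to report (default 25).
#' @param seed integer seed for the bootstrap.
#' @param keep_samples passed to [bootstrap_rankings()].
#' @return list with `ranking` (a `final_ranking`), `distribution` (a
#'   `rank_distribution`) and `dataset_rankings`.
#' @export
rank_reference_genes <- function(datasets, repetitions = 10000L, top_n = 25L,
                                 seed = NULL, keep_samples = FALSE) {
  if (length(datasets) < 2)
    stop("at least two data sets are required")
  clean <- lapply(datasets, function(ds) drop_incomplete_genes(to_linear(ds)))
  rankings <- lapply(clean, score_dataset)
  universe <- gene_universe(clean)
  dist <- bootstrap_rankings(rankings, universe = universe,
                             repetitions = repetitions, seed = seed,
                             keep_samples = keep_samples)
  list(ranking = final_ranking(dist, top_n = top_n),
       distribution = dist, dataset_rankings = rankings)
}

read_any_expression <- function(path, ...) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 1 && startsWith(first, "!"))
    read_series_matrix(path, ...)
  else read_expression_tsv(path, ...)
}

write_session <- function(path, command, parameters, outputs) {
  session <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  command = command, parameters = parameters,
                  outputs = outputs)
  jsonlite::write_json(session, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the full ranking workflow from files
#'
#' Reads each data set (GEO series-matrix or plain TSV, auto-detected),
#' annotates samples, optionally collapses probes to genes and maps
#' ortholog groups, then runs [rank_reference_genes()] and writes
#' `ranking.tsv` plus a `session.json` recording every parameter so the
#' run can be reproduced bit-for-bit.
#'
#' @param dataset_paths character vector (length >= 2) of expression
#'   files.
#' @param annotation_paths sample-annotation TSVs, one per data set.
#' @param mapping_path optional probe-to-gene mapping TSV (applied to
#'   every data set that shares probes with it).
#' @param ortholog_path optional ortholog mapping TSV.
#' @param organisms optional character vector of organism labels, one per
#'   data set.
#' @param repetitions,top_n,seed see [rank_reference_genes()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the [rank_reference_genes()] result.
#' @export
run_rank <- function(dataset_paths, annotation_paths, mapping_path = NULL,
                     ortholog_path = NULL, organisms = NULL,
                     repetitions = 10000L, top_n = 25L, seed = 1L,
                     out_dir = ".") {
  if (length(dataset_paths) < 2)
    stop("at least two data sets are required")
  if (length(annotation_paths) != length(dataset_paths))
    stop("one annotation file per data set is required")
  stage <- function(what, id, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s: %s", what, id, conditionMessage(e)), call. = FALSE))
  }
  datasets <- mapply(function(p, a, i) {
    ds <- stage("read", p, read_any_expression(p))
    if (!is.null(organisms)) ds$organism <- organisms[i]
    stage("annotate", ds$dataset_id,
          annotate_samples(ds, read_sample_annotation(a)))
  }, dataset_paths, annotation_paths, seq_along(dataset_paths),
  SIMPLIFY = FALSE)
  if (!is.null(mapping_path)) {
    map <- read_mapping_table(mapping_path, "probe_to_gene")
    datasets <- lapply(datasets, function(ds) {
      if (!any(ds$gene_ids %in% map$source_id)) return(ds)  # already gene-level
      stage("collapse", ds$dataset_id, collapse_probes(ds, map))
    })
  }
  orth <- if (!is.null(ortholog_path))
    read_mapping_table(ortholog_path, "ortholog")
  datasets <- stage("harmonize", "all", harmonize_genes(datasets, orth))
  res <- stage("rank", "all",
               rank_reference_genes(datasets, repetitions = repetitions,
                                    top_n = top_n, seed = seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ranking_path <- file.path(out_dir, "ranking.tsv")
  write_ranking_tsv(res$ranking, ranking_path)
  write_session(file.path(out_dir, "session.json"), "rank",
                list(dataset_paths = dataset_paths,
                     annotation_paths = annotation_paths,
                     mapping_path = mapping_path,
                     ortholog_path = ortholog_path,
                     repetitions = as.integer(repetitions),
                     top_n = as.integer(top_n), seed = as.integer(seed)),
                list(ranking = ranking_path,
                     top_genes = res$ranking$top_genes))
  invisible(res)
}

#' Run the stability scoring workflow from files
#'
#' @param dataset_path expression file (series-matrix or TSV).
#' @param annotation_path sample-annotation TSV.
#' @param cutoff stability cutoff on rho (default 0.15).
#' @param out_dir output directory; writes `stability.tsv` + `session.json`.
#' @return invisibly, the `stability_result`.
#' @export
run_normfinder <- function(dataset_path, annotation_path, cutoff = 0.15,
                           out_dir = ".") {
  ds <- annotate_samples(read_any_expression(dataset_path),
                         read_sample_annotation(annotation_path))
  res <- normfinder_stability(ds, cutoff = cutoff)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(out_dir, "stability.tsv")
  utils::write.table(as.data.frame(res), out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_session(file.path(out_dir, "session.json"), "normfinder",
                list(dataset_path = dataset_path,
                     annotation_path = annotation_path, cutoff = cutoff),
                list(stability = out, n_stable = sum(res$stable)))
  invisible(res)
}

#' Compare two or more ranking lists
#'
#' Computes all pairwise overlap coefficients of the top-k genes, the
#' reproducibility measure R (their mean), and — for exactly two lists —
#' the hypergeometric overlap p-value against the given universe size.
#'
#' @param ranking_paths two or more ranking TSVs
#'   (see [write_ranking_tsv()]).
#' @param k truncation length (default 50).
#' @param universe universe size for the overlap test; defaults to the
#'   union of genes over the rankings.
#' @param out_dir output directory; writes `comparison.json` + session.
#' @return invisibly, a list with `R`, `pairwise` and (two lists only)
#'   `p_value`.
#' @export
run_compare <- function(ranking_paths, k = 50L, universe = NULL,
                        out_dir = ".") {
  if (length(ranking_paths) < 2)
    stop("at least two ranking files are required")
  lists <- lapply(ranking_paths, read_ranking_tsv)
  if (is.null(universe))
    universe <- length(unique(unlist(lists)))
  tops <- lapply(lists, utils::head, k)
  pairs <- utils::combn(length(tops), 2L)
  pairwise <- data.frame(
    list_a = ranking_paths[pairs[1, ]], list_b = ranking_paths[pairs[2, ]],
    overlap = apply(pairs, 2L, function(p)
      overlap_coefficient(tops[[p[1]]], tops[[p[2]]])),
    stringsAsFactors = FALSE)
  res <- list(R = reproducibility_R(lists, k = k), pairwise = pairwise)
  if (length(tops) == 2) {
    shared <- length(intersect(tops[[1]], tops[[2]]))
    res$p_value <- overlap_pvalue(shared, length(tops[[1]]),
                                  length(tops[[2]]), universe)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(out_dir, "comparison.json")
  jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  write_session(file.path(out_dir, "session.json"), "compare",
                list(ranking_paths = ranking_paths, k = as.integer(k),
                     universe = universe),
                list(comparison = out, R = res$R))
  invisible(res)
}

#' Simulate a compendium and write it to disk
#'
#' Writes one expression TSV and one annotation TSV per simulated study,
#' the ground truth as JSON, and a session file.
#'
#' @param config a [simulation_config()]; additional arguments in `...`
#'   override its fields via [simulation_config()].
#' @param out_dir output directory.
#' @param ... fields passed to [simulation_config()] when `config` is
#'   missing.
#' @return invisibly, the `simulated_collection`.
#' @export
run_simulate <- function(config = NULL, out_dir = ".", ...) {
  if (is.null(config)) config <- simulation_config(...)
  sim <- simulate_collection(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (ds in sim$datasets) {
    write_expression_tsv(ds, file.path(out_dir,
                                       paste0(ds$dataset_id, "_expr.tsv")))
    utils::write.table(
      data.frame(sample_id = ds$sample_ids, group = ds$group_labels),
      file.path(out_dir, paste0(ds$dataset_id, "_groups.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(roles = as.list(sim$truth$roles),
         datasets = lapply(sim$truth$datasets, function(t)
           list(retained_genes = t$retained_genes, scale = t$scale))),
    truth_path, auto_unbox = TRUE, pretty = TRUE)
  write_session(file.path(out_dir, "session.json"), "simulate",
                unclass(config)[!vapply(unclass(config), is.null, logical(1))],
                list(truth = truth_path,
                     datasets = vapply(sim$datasets, `[[`, character(1),
                                       "dataset_id")))
  invisible(sim)
}

#' Run the qPCR normalization workflow from files
#'
#' @param ct_path Ct table TSV (see [read_ct_table()]).
#' @param target target gene column name.
#' @param panel character vector of reference gene columns.
#' @param out_dir output directory; writes per-sample and summary TSVs
#'   plus a session file.
#' @return invisibly, the [ddct_fold_change()] result.
#' @export
run_qpcr <- function(ct_path, target, panel, out_dir = ".") {
  tab <- read_ct_table(ct_path)
  res <- ddct_fold_change(tab, target = target, panel = panel)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  per_sample <- file.path(out_dir, "qpcr_per_sample.tsv")
  summary_path <- file.path(out_dir, "qpcr_summary.tsv")
  utils::write.table(res$per_sample, per_sample, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(res$summary, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_session(file.path(out_dir, "session.json"), "qpcr",
                list(ct_path = ct_path, target = target, panel = panel),
                list(per_sample = per_sample, summary = summary_path))
  invisible(res)
}
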