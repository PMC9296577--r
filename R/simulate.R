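#' Configuration for a synthetic expression compendium
#'
#' Describes a heterogeneous multi-study compendium with known ground
#' truth: a shared gene universe in which a small set of planted *stable*
#' genes is highly and tightly expressed with no condition effect, a set
#' of condition-*responsive* genes carries a planted fold change, and the
#' remaining *background* genes fluctuate with higher noise. Each study
#' independently drops a fraction of genes (platforms measure different
#' gene sets) and part of the studies are emitted log2-transformed, so the
#' preprocessing path is exercised too.
#'
#' @param n_datasets number of studies (default 4).
#' @param n_genes universe size (default 2000).
#' @param n_planted_stable planted reference genes (default 50).
#' @param n_condition_responsive genes with a planted condition effect
#'   (default 200).
#' @param samples_per_group samples per group per study (default 10).
#' @param dropout_fraction fraction of genes each study fails to measure,
#'   in \[0, 1) (default 0.1).
#' @param log_scale_fraction fraction of studies emitted log2-scale
#'   (default 0.5).
#' @param noise_cv_stable,noise_cv_background multiplicative-noise CV of
#'   planted stable genes (default 0.05) and of all other genes (default
#'   0.30); must satisfy `0 < noise_cv_stable < noise_cv_background`.
#' @param responsive_fc_range fold-change range for responsive genes,
#'   applied up- or downward with equal probability (default c(2, 8)).
#' @param baseline_mean_range log2-scale baseline range for background and
#'   responsive genes (default c(4, 12)).
#' @param stable_mean_range log2-scale baseline range for planted stable
#'   genes — deliberately high, as reference genes are (default c(10, 14)).
#' @param stable_genes,responsive_genes optional explicit gene indices for
#'   the planted roles (default: drawn at random from the seed). Supplying
#'   them makes compendia with chosen, e.g. disjoint, planted sets.
#' @param organism organism label given to every study (default "mouse").
#' @param seed integer seed; the whole compendium is a deterministic
#'   function of the configuration.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_datasets = 4L, n_genes = 2000L,
                              n_planted_stable = 50L,
                              n_condition_responsive = 200L,
                              samples_per_group = 10L,
                              dropout_fraction = 0.1,
                              log_scale_fraction = 0.5,
                              noise_cv_stable = 0.05,
                              noise_cv_background = 0.30,
                              responsive_fc_range = c(2, 8),
                              baseline_mean_range = c(4, 12),
                              stable_mean_range = c(10, 14),
                              stable_genes = NULL, responsive_genes = NULL,
                              organism = "mouse", seed = 1L) {
  cfg <- list(n_datasets = as.integer(n_datasets),
              n_genes = as.integer(n_genes),
              n_planted_stable = as.integer(n_planted_stable),
              n_condition_responsive = as.integer(n_condition_responsive),
              samples_per_group = as.integer(samples_per_group),
              dropout_fraction = dropout_fraction,
              log_scale_fraction = log_scale_fraction,
              noise_cv_stable = noise_cv_stable,
              noise_cv_background = noise_cv_background,
              responsive_fc_range = responsive_fc_range,
              baseline_mean_range = baseline_mean_range,
              stable_mean_range = stable_mean_range,
              stable_genes = if (!is.null(stable_genes)) as.integer(stable_genes),
              responsive_genes = if (!is.null(responsive_genes))
                as.integer(responsive_genes),
              organism = organism, seed = as.integer(seed))
  with(cfg, {
    if (n_datasets < 1 || n_genes < 2 || n_planted_stable < 1 ||
        n_condition_responsive < 1 || samples_per_group < 2)
      stop("all counts must be positive (and >= 2 genes / samples per group)")
    if (n_planted_stable + n_condition_responsive > n_genes)
      stop("planted roles exceed the gene universe")
    if (dropout_fraction < 0 || dropout_fraction >= 1)
      stop("dropout_fraction must lie in [0, 1)")
    if (log_scale_fraction < 0 || log_scale_fraction > 1)
      stop("log_scale_fraction must lie in [0, 1]")
    if (!(noise_cv_background > noise_cv_stable && noise_cv_stable > 0))
      stop("need noise_cv_background > noise_cv_stable > 0")
    if (length(responsive_fc_range) != 2 || responsive_fc_range[1] <= 1 ||
        diff(responsive_fc_range) < 0)
      stop("responsive_fc_range must be an ordered pair with low > 1")
    if (diff(baseline_mean_range) < 0 || diff(stable_mean_range) < 0)
      stop("mean ranges must be ordered")
  })
  if (!is.null(cfg$stable_genes) && !is.null(cfg$responsive_genes) &&
      length(intersect(cfg$stable_genes, cfg$responsive_genes)) > 0)
    stop("stable and responsive gene sets must be disjoint")
  structure(cfg, class = "simulation_config")
}

# log2-normal noise sd giving a target CV on linear scale:
# CV of lognormal = sqrt(exp(sigma_ln^2) - 1)  =>  sigma_log2 = sqrt(ln(1+CV^2))/ln 2
cv_to_sd_log2 <- function(cv) sqrt(log(1 + cv^2)) / log(2)

#' Simulate a multi-study compendium with planted ground truth
#'
#' Generates `n_datasets` annotated expression data sets from one shared
#' gene universe under the log-normal multiplicative noise model: each
#' study draws its own per-gene baselines (platforms differ in absolute
#' intensity), planted stable genes get high baselines and tight noise
#' with fold change 1, responsive genes a fold change drawn from
#' `responsive_fc_range` applied to the condition group (direction up or
#' down with equal probability), background genes loose noise and fold
#' change 1. Each study then drops a random `dropout_fraction` of genes
#' (never all planted stable ones), and the first
#' `round(log_scale_fraction * n_datasets)` studies are emitted
#' log2-transformed with `scale = "log2"`.
#'
#' @param config a [simulation_config()].
#' @return a `simulated_collection`: list with `datasets` (annotated
#'   [expression_dataset()]s), `truth` (per-gene `roles`; per-study
#'   retained genes, scale, and generative parameter tables) and `config`.
#' @export
simulate_collection <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  G <- config$n_genes
  gene_ids <- sprintf("g%0*d", nchar(G), seq_len(G))
  roles <- rep("background", G)
  if (is.null(config$stable_genes)) {
    picked <- sample.int(G, config$n_planted_stable + config$n_condition_responsive)
    stable_idx <- picked[seq_len(config$n_planted_stable)]
    responsive_idx <- picked[-seq_len(config$n_planted_stable)]
  } else {
    stable_idx <- config$stable_genes
    responsive_idx <- config$responsive_genes
    if (is.null(responsive_idx)) {
      pool <- setdiff(seq_len(G), stable_idx)
      responsive_idx <- sample(pool, config$n_condition_responsive)
    }
  }
  roles[stable_idx] <- "stable"
  roles[responsive_idx] <- "responsive"
  names(roles) <- gene_ids

  spg <- config$samples_per_group
  n_log <- round(config$log_scale_fraction * config$n_datasets)
  datasets <- vector("list", config$n_datasets)
  truth_ds <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    baseline <- stats::runif(G, config$baseline_mean_range[1],
                             config$baseline_mean_range[2])
    baseline[roles == "stable"] <-
      stats::runif(sum(roles == "stable"), config$stable_mean_range[1],
                   config$stable_mean_range[2])
    cv <- ifelse(roles == "stable", config$noise_cv_stable,
                 config$noise_cv_background)
    fc <- rep(1, G)
    fc[roles == "responsive"] <-
      stats::runif(sum(roles == "responsive"), config$responsive_fc_range[1],
                   config$responsive_fc_range[2])
    direction <- sample(c(-1, 1), G, replace = TRUE)
    shift <- ifelse(roles == "responsive", direction * log2(fc), 0)

    n_drop <- floor(config$dropout_fraction * G)
    dropped <- if (n_drop > 0) sample.int(G, n_drop) else integer(0)
    if (all(stable_idx %in% dropped))    # keep at least one planted gene
      dropped <- setdiff(dropped, stable_idx[1])
    retained <- setdiff(seq_len(G), dropped)

    sd_log2 <- cv_to_sd_log2(cv)
    n_ret <- length(retained)
    ctrl <- matrix(stats::rnorm(n_ret * spg, mean = baseline[retained],
                                sd = sd_log2[retained]),
                   nrow = n_ret, ncol = spg)
    cond <- matrix(stats::rnorm(n_ret * spg,
                                mean = baseline[retained] + shift[retained],
                                sd = sd_log2[retained]),
                   nrow = n_ret, ncol = spg)
    logvals <- cbind(cond, ctrl)
    sample_ids <- sprintf("ds%d_s%02d", d, seq_len(2 * spg))
    labels <- rep(c("condition", "control"), each = spg)
    is_log <- d <= n_log
    vals <- if (is_log) logvals else 2^logvals
    datasets[[d]] <- expression_dataset(
      vals, gene_ids = gene_ids[retained], sample_ids = sample_ids,
      group_labels = labels, scale = if (is_log) "log2" else "linear",
      dataset_id = sprintf("sim%02d", d), organism = config$organism)
    truth_ds[[d]] <- list(
      retained_genes = gene_ids[retained],
      scale = if (is_log) "log2" else "linear",
      params = data.frame(gene_id = gene_ids, baseline_log2 = baseline,
                          cv = cv, fc = ifelse(shift == 0, 1, 2^abs(shift)),
                          row.names = NULL, stringsAsFactors = FALSE))
  }
  structure(list(datasets = datasets,
                 truth = list(roles = roles, datasets = truth_ds),
                 config = config),
            class = "simulated_collection")
}

#' Planted-gene recovery of a final ranking
#'
#' The in-silico analog of wet-lab validation: the fraction of the top-k
#' ranked candidates whose true simulated role is "stable".
#'
#' @param ranking a `final_ranking` computed on a simulated compendium.
#' @param truth the `truth` element of a `simulated_collection` (or the
#'   collection itself).
#' @param k how many top candidates to check.
#' @return fraction in \[0, 1\].
#' @export
recovery_metrics <- function(ranking, truth, k = 10L) {
  stopifnot(inherits(ranking, "final_ranking"))
  if (inherits(truth, "simulated_collection")) truth <- truth$truth
  k <- as.integer(k)
  if (is.na(k) || k < 1 || k > nrow(ranking$table))
    stop("k must lie between 1 and the universe size")
  top <- utils::head(ranking$table$gene_id[is.finite(ranking$table$penalized_score)], k)
  mean(truth$roles[top] == "stable")
}
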