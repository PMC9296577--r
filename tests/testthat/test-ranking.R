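test_that("coefficient of variation matches the sd/mean definition", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(2, 4, 6)), 0.5)  # sd 2, mean 4
  for (k in c(0.01, 1, 7, 1e4))
    expect_equal(coefficient_of_variation(k * c(2, 4, 6)), 0.5)
  expect_error(coefficient_of_variation(5), "at least two")
  expect_error(coefficient_of_variation(c(1, -1, 2)), "positive")
})

test_that("group fold change is the mean ratio, inverted below 1", {
  expect_equal(group_fold_change(c(8, 8), c(2, 2)), 4)
  expect_equal(group_fold_change(c(2, 2), c(8, 8)), 4)   # 0.25 inverted
  expect_equal(group_fold_change(c(3, 5), c(4, 4)), 1)
  expect_error(group_fold_change(numeric(0), c(1, 2)), "non-empty")
  # inversion symmetry: swapping the groups never changes the value
  set.seed(11)
  for (i in 1:20) {
    a <- rlnorm(4, 3); b <- rlnorm(4, 5)
    expect_equal(group_fold_change(a, b), group_fold_change(b, a))
    expect_gte(group_fold_change(a, b), 1)
  }
})

test_that("dataset scoring ranks CV and FC independently into a rank product", {
  # gene A: lowest CV, middle FC; gene B: FC exactly 1, middle CV;
  # gene C: worst on both -> rank products 2, 2, 9 and ranks 1.5, 1.5, 3
  vals <- rbind(A = c(10, 10, 11, 11),
                B = c(10, 14, 10, 14),
                C = c(5, 10, 20, 40))
  ds <- make_dataset(vals)
  sc <- score_dataset(ds)$scores
  expect_equal(sc$rank_cv, c(1, 2, 3))
  expect_equal(sc$rank_fc, c(2, 1, 3))
  expect_equal(sc$rank_product, c(2, 2, 9))
  expect_equal(sc$dataset_rank, c(1.5, 1.5, 3))
  expect_equal(sc$rank_product, sc$rank_cv * sc$rank_fc)
})

test_that("a constant gene with equal group means ranks first", {
  set.seed(3)
  vals <- rbind(flat = rep(500, 6),
                matrix(rlnorm(30, 5, 1), 5,
                       dimnames = list(sprintf("v%d", 1:5), NULL)))
  sc <- score_dataset(make_dataset(vals))$scores
  expect_equal(sc$dataset_rank[sc$gene_id == "flat"], 1)
  expect_equal(sc$cv[sc$gene_id == "flat"], 0)
  expect_equal(sc$fc[sc$gene_id == "flat"], 1)
})

test_that("dataset scoring is invariant to gene order", {
  set.seed(9)
  vals <- matrix(rlnorm(48, 6, 0.8), 8,
                 dimnames = list(sprintf("g%d", 1:8), NULL))
  sc1 <- score_dataset(make_dataset(vals))$scores
  perm <- sample(8)
  sc2 <- score_dataset(make_dataset(vals[perm, ]))$scores
  expect_equal(sc2$dataset_rank[match(sc1$gene_id, sc2$gene_id)],
               sc1$dataset_rank)
})

test_that("bootstrapping identical data sets yields a degenerate distribution", {
  set.seed(5)
  ds <- make_dataset(matrix(rlnorm(24, 5, 1), 6,
                            dimnames = list(sprintf("g%d", 1:6), NULL)))
  r <- score_dataset(ds)
  dist <- bootstrap_rankings(list(r, r), repetitions = 200, seed = 1)
  expect_equal(dist$table$rank_sd, rep(0, 6))
  expect_equal(dist$table$mean_rank,
               r$scores$dataset_rank[match(dist$table$gene_id,
                                           r$scores$gene_id)])
  expect_equal(dist$table$presence_count, rep(2L, 6))
})

test_that("the same seed reproduces the bootstrap exactly", {
  rA <- make_ranking("A", c("a", "b", "c", "d"), c(1, 2, 3, 4))
  rB <- make_ranking("B", c("b", "c", "d", "e"), c(4, 1, 2, 3))
  d1 <- bootstrap_rankings(list(rA, rB), repetitions = 500, seed = 99)
  d2 <- bootstrap_rankings(list(rA, rB), repetitions = 500, seed = 99)
  expect_identical(d1$table, d2$table)
  d3 <- bootstrap_rankings(list(rA, rB), repetitions = 500, seed = 100)
  expect_false(identical(d1$table$mean_rank, d3$table$mean_rank))
})

test_that("every bootstrap repetition is a valid average-tie ranking", {
  rA <- make_ranking("A", c("a", "b", "c", "d"), c(1, 2, 3, 4))
  rB <- make_ranking("B", c("b", "c", "d", "e"), c(4, 1, 2, 3))
  dist <- bootstrap_rankings(list(rA, rB), repetitions = 50, seed = 2,
                             keep_samples = TRUE)
  G <- nrow(dist$table)
  expect_equal(unname(colSums(dist$samples)), rep(G * (G + 1) / 2, 50))
})

test_that("bootstrap mean ranks match exhaustive enumeration for two data sets", {
  rA <- make_ranking("A", c("a", "b", "c", "d"), c(1, 2, 3, 4))
  rB <- make_ranking("B", c("b", "c", "d", "e"), c(4, 1, 2, 3))
  universe <- c("a", "b", "c", "d", "e")
  exact <- enumerate_two_dataset_bootstrap(list(rA, rB), universe)
  reps <- 10000
  dist <- bootstrap_rankings(list(rA, rB), universe = universe,
                             repetitions = reps, seed = 7)
  se <- sqrt(exact$var / reps)
  expect_true(all(abs(dist$table$mean_rank - exact$mean) <= 3 * se + 1e-9))
})

test_that("fewer than two data sets is a configuration error", {
  rA <- make_ranking("A", c("a", "b"), c(1, 2))
  expect_error(bootstrap_rankings(list(rA), repetitions = 10),
               "at least two")
})

test_that("the absence penalty multiplies mean rank by n_datasets/presence", {
  dist <- make_distribution(c("full", "half", "none"),
                            mean_rank = c(10, 10, 1),
                            presence = c(4L, 2L, 0L), n_datasets = 4L)
  fr <- final_ranking(dist, top_n = 2)
  tab <- fr$table
  expect_equal(tab$penalized_score[tab$gene_id == "full"], 10)   # x 4/4
  expect_equal(tab$penalized_score[tab$gene_id == "half"], 20)   # x 4/2
  expect_equal(tab$penalized_score[tab$gene_id == "none"], Inf)
  expect_equal(fr$top_genes, c("full", "half"))  # absent gene never reported
  expect_error(final_ranking(dist, top_n = 0), "positive")
})

test_that("ties in the penalized score break lexicographically", {
  dist <- make_distribution(c("zeta", "alpha", "mid"),
                            mean_rank = c(5, 5, 7),
                            presence = c(3L, 3L, 3L), n_datasets = 3L)
  fr <- final_ranking(dist, top_n = 3)
  expect_equal(fr$table$gene_id, c("alpha", "zeta", "mid"))
})

test_that("losing presence never improves the final position", {
  set.seed(21)
  for (i in 1:25) {
    G <- 8
    ids <- sprintf("g%d", 1:G)
    mean_rank <- runif(G, 1, G)
    presence <- sample(1:4, G, replace = TRUE)
    base <- final_ranking(make_distribution(ids, mean_rank, presence, 4L),
                          top_n = G)
    pick <- sample(which(presence > 1), 1)
    worse <- presence; worse[pick] <- worse[pick] - 1L
    after <- final_ranking(make_distribution(ids, mean_rank, worse, 4L),
                           top_n = G)
    pos <- function(fr) match(ids[pick], fr$table$gene_id)
    expect_gte(pos(after), pos(base))
  }
})

test_that("ranking TSV round trip preserves order and contents", {
  dist <- make_distribution(c("b", "a", "c"), c(2, 1, 3), c(2L, 2L, 1L), 2L)
  fr <- final_ranking(dist, top_n = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranking_tsv(fr, path)
  expect_equal(read_ranking_tsv(path), fr$table$gene_id)
})
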