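test_that("phylo_bins matches brute-force single-linkage clustering", {
  fx <- small_sim(seed = 71, n_taxa = 50, n_groups = 1, samples_per_group = 6)
  pb <- phylo_bins(fx$tree, fx$sim$table, distance_threshold = 0.2,
                   min_bin_size = 1)
  # brute-force union-find single linkage on the patristic matrix
  taxa <- sort(rownames(fx$sim$table))
  pd <- stats::cophenetic(fx$tree)[taxa, taxa]
  parent <- seq_along(taxa)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(taxa)) for (j in seq_along(taxa))
    if (pd[i, j] <= 0.2) parent[find(i)] <- find(j)
  brute <- vapply(seq_along(taxa), find, integer(1))
  got <- pb$membership[taxa]
  # same partition up to relabelling: co-membership matrices identical
  expect_identical(unname(outer(got, got, "==")), outer(brute, brute, "=="))
  # bins partition the taxa
  expect_setequal(unlist(pb$bins), taxa)
  expect_equal(anyDuplicated(unlist(pb$bins)), 0)
})

test_that("phylo_bins honours star and two-clade geometries and merging", {
  # star tree: all pairwise distances 2, threshold >= 2 -> one bin
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  tab <- matrix(5L, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                          paste0("S", 1:4)))
  pb1 <- phylo_bins(star, tab, distance_threshold = 2, min_bin_size = 1)
  expect_equal(length(pb1$bins), 1)

  # two tight clades far apart -> exactly the clades
  two <- ape::read.tree(
    text = "((A:0.05,B:0.05):1,(C:0.05,D:0.05):1);")
  pb2 <- phylo_bins(two, tab, distance_threshold = 0.2, min_bin_size = 2)
  expect_equal(length(pb2$bins), 2)
  expect_setequal(pb2$bins[[pb2$membership[["A"]]]], c("A", "B"))

  # undersized bins merge into their phylogenetically nearest bin
  pb3 <- phylo_bins(two, tab, distance_threshold = 0.2, min_bin_size = 3)
  expect_equal(length(pb3$bins), 1)

  expect_error(phylo_bins(two, rbind(tab, E = 1L)), class = "missing_tip")
})

test_that("beta_nri is a standardized effect size with seeded determinism", {
  fx <- small_sim(seed = 72, n_taxa = 20, n_groups = 1, samples_per_group = 4)
  bin <- sort(rownames(fx$sim$table))[1:8]
  pair <- c("S1", "S2")
  v1 <- beta_nri(fx$sim$table, pair, bin, fx$tree, n_null = 500, seed = 5)
  v2 <- beta_nri(fx$sim$table, pair, bin, fx$tree, n_null = 500, seed = 5)
  expect_identical(v1, v2)

  # duplicate-implementation oracle replaying the same shuffles
  sub <- fx$sim$table[bin, pair]
  d <- stats::cophenetic(ape::keep.tip(fx$tree, bin))[bin, bin]
  fa <- sub[, 1] / sum(sub[, 1]); fb <- sub[, 2] / sum(sub[, 2])
  obs <- sum(outer(fa, fb) * d)
  set.seed(5)
  null <- replicate(500, {
    p <- sample(length(bin))
    sum(outer(fa, fb) * d[p, p])
  })
  expect_equal(v1, (obs - mean(null)) / sd(null), tolerance = 1e-12)

  # identical abundances on a star tree: shuffle-invariant, sd = 0
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  tab <- matrix(c(5L, 5L, 5L, 5L), 4, 2,
                dimnames = list(c("A", "B", "C", "D"), c("S1", "S2")))
  expect_error(beta_nri(tab, c("S1", "S2"), c("A", "B", "C", "D"), star,
                        n_null = 100), class = "undefined_ses")
})

test_that("rc_bray ranks the observed dissimilarity against its null", {
  fx <- small_sim(seed = 73, n_taxa = 12, n_groups = 1, samples_per_group = 4)
  bin <- sort(rownames(fx$sim$table))[1:6]
  v1 <- rc_bray(fx$sim$table, c("S1", "S2"), bin, n_null = 999, seed = 9)
  v2 <- rc_bray(fx$sim$table, c("S1", "S2"), bin, n_null = 999, seed = 9)
  expect_identical(v1, v2)
  expect_gte(v1, -1); expect_lte(v1, 1)

  # duplicate-implementation oracle with the same draw sequence
  sub_all <- fx$sim$table[bin, ]
  sub <- sub_all[, c("S1", "S2")]
  obs <- as.numeric(vegan::vegdist(t(sub), "bray"))
  occupancy <- rowMeans(sub_all > 0)
  mean_rel <- rowMeans(sweep(sub_all, 2, colSums(sub_all), "/"))
  k <- length(bin)
  set.seed(9)
  draw_null <- function(richness, n_reads) {
    cnt <- numeric(k)
    richness <- min(richness, sum(occupancy > 0))
    chosen <- sample(k, richness, prob = occupancy)
    cnt[chosen] <- 1
    extra <- n_reads - richness
    if (extra > 0)
      cnt[chosen] <- cnt[chosen] +
        as.vector(stats::rmultinom(1, extra, mean_rel[chosen]))
    cnt
  }
  null <- replicate(999, {
    a <- draw_null(sum(sub[, 1] > 0), sum(sub[, 1]))
    b <- draw_null(sum(sub[, 2] > 0), sum(sub[, 2]))
    as.numeric(vegan::vegdist(rbind(a, b), "bray"))
  })
  expect_equal(v1, 2 * ((sum(null < obs) + 0.5 * sum(null == obs)) / 999) - 1,
               tolerance = 1e-12)
  expect_error(rc_bray(sub_all * 0L + 0L, c("S1", "S2"), bin, 100),
               class = "empty_bin")
})

test_that("classify_turnover applies the decision rules", {
  expect_equal(classify_turnover(-2.5, 0.1), "homogeneous_selection")
  expect_equal(classify_turnover(2.5, 0.1), "heterogeneous_selection")
  expect_equal(classify_turnover(0.3, 0.99), "dispersal_limitation")
  expect_equal(classify_turnover(0.3, -0.99), "homogenizing_dispersal")
  expect_equal(classify_turnover(0, 0), "drift")
  expect_error(classify_turnover(NaN, 0))
})

test_that("aggregate_processes weights by bin abundance and normalizes", {
  bins <- structure(list(
    bins = list(bin1 = c("A", "B"), bin2 = c("C", "D")),
    membership = c(A = "bin1", B = "bin1", C = "bin2", D = "bin2"),
    bin_abundance = c(bin1 = 0.5, bin2 = 0.5),
    distance_threshold = 0.2, min_bin_size = 2), class = "phylo_bins")
  scores <- data.frame(
    sample_a = "S1", sample_b = "S2", group = "G1",
    bin = c("bin1", "bin2"), beta_nri = c(-3, 0), rc = c(0, 0),
    process = c("homogeneous_selection", "drift"),
    stringsAsFactors = FALSE)
  agg <- aggregate_processes(scores, bins)
  expect_equal(agg$homogeneous_selection, 0.5)
  expect_equal(agg$drift, 0.5)
  expect_equal(sum(agg[1, -1]), 1, tolerance = 1e-9)

  # all-drift degenerates to a point mass
  scores$process <- "drift"
  agg2 <- aggregate_processes(scores, bins)
  expect_equal(agg2$drift, 1)
  expect_true(all(agg2[, setdiff(names(agg2)[-1], "drift")] == 0))
})

test_that("score_turnovers covers within-group pairs and flags exclusions", {
  fx <- small_sim(seed = 74, n_taxa = 30, n_groups = 2, samples_per_group = 3)
  bins <- phylo_bins(fx$tree, fx$sim$table, min_bin_size = 5)
  sc <- score_turnovers(fx$sim$table, fx$tree, bins, fx$sim$metadata,
                        n_null = 100, seed = 1)
  # 2 groups x choose(3,2) pairs x bins
  expect_equal(nrow(sc), 2 * 3 * length(bins$bins))
  expect_true(all(sc$group %in% c("G1", "G2")))
  ok <- !is.na(sc$process)
  expect_true(all(sc$process[ok] %in% micronet:::assembly_processes))
  # determinism
  sc2 <- score_turnovers(fx$sim$table, fx$tree, bins, fx$sim$metadata,
                         n_null = 100, seed = 1)
  expect_identical(sc, sc2)

  md_bad <- fx$sim$metadata[-c(1, 2), ]  # leaves G1 with one sample
  expect_error(score_turnovers(fx$sim$table, fx$tree, bins, md_bad,
                               n_null = 100, seed = 1),
               class = "insufficient_pairs")
})
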