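# Shared fixtures, generated in code.

# Small simulated community used by several suites.
small_sim <- function(seed = 42, n_taxa = 60, n_groups = 2,
                      samples_per_group = 8, depth = 1500, n_blocks = 0, ...) {
  cfg <- sim_config(n_taxa = n_taxa, n_groups = n_groups,
                    samples_per_group = samples_per_group, depth = depth,
                    n_blocks = n_blocks, seed = seed, ...)
  tree <- simulate_tree(n_taxa, seed = seed + 1)
  sim <- simulate_communities(cfg, tree)
  list(cfg = cfg, tree = tree, sim = sim)
}

# Deterministic association matrix from explicit values.
assoc_fixture <- function(r) {
  stopifnot(isSymmetric(r))
  if (is.null(rownames(r)))
    rownames(r) <- colnames(r) <- paste0("T", seq_len(nrow(r)))
  micronet:::new_assoc(r, "pearson", "relative")
}

# Planted two-block association matrix: strong within-block entries,
# weak cross-block noise.
two_block_assoc <- function(n_per_block = 30, within = c(0.75, 0.95),
                            cross = 0.2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_block
  r <- matrix(stats::runif(n * n, -cross, cross), n)
  r <- (r + t(r)) / 2
  blk <- function(k) {
    w <- matrix(stats::runif(k * k, within[1], within[2]), k)
    (w + t(w)) / 2
  }
  i1 <- seq_len(n_per_block); i2 <- n_per_block + i1
  r[i1, i1] <- blk(n_per_block)
  r[i2, i2] <- blk(n_per_block)
  diag(r) <- 1
  rownames(r) <- colnames(r) <- paste0("T", seq_len(n))
  list(assoc = assoc_fixture(r), block = rep(1:2, each = n_per_block))
}

# Signed graph from an explicit edge data.frame (from, to, weight).
graph_fixture <- function(edges, domains = NULL) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::E(g)$sign <- ifelse(igraph::E(g)$weight >= 0, "positive", "negative")
  if (!is.null(domains)) igraph::V(g)$domain <- domains[igraph::V(g)$name]
  g
}

# Complete graph with all edge weights +1 (or a given constant).
complete_graph <- function(n, weight = 1) {
  pairs <- t(utils::combn(paste0("N", seq_len(n)), 2))
  graph_fixture(data.frame(from = pairs[, 1], to = pairs[, 2],
                           weight = weight, stringsAsFactors = FALSE))
}
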