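# Stability (wMIS robustness) and complexity (cohesion) of co-occurrence
# networks.

#' Abundance-weighted mean interaction strength (wMIS)
#'
#' \deqn{wMIS_i = \sum_{j \ne i} b_j s_{ij} / \sum_{j \ne i} b_j}
#' where the sum runs over the node's current neighbours, \eqn{b_j} is the
#' neighbour's relative abundance and \eqn{s_{ij}} the signed association
#' strength on the edge. A node without neighbours returns 0 (extinct by
#' convention in the robustness simulation).
#'
#' @param node taxon id present in the network.
#' @param network an igraph graph with signed `weight` edge attributes.
#' @param abundance named vector of relative abundances covering the node's
#'   neighbours.
#' @return a single wMIS value.
#' @export
wmis <- function(node, network, abundance) {
  if (!node %in% igraph::V(network)$name)
    stop(sprintf("node '%s' not in network", node), call. = FALSE)
  nb <- igraph::neighbors(network, node)$name
  if (length(nb) == 0) return(0)
  if (!all(nb %in% names(abundance)))
    mn_stop("missing_abundance",
            paste0("no abundance for neighbour(s): ",
                   paste(setdiff(nb, names(abundance)), collapse = ", ")))
  eids <- igraph::get_edge_ids(network, rbind(rep(node, length(nb)), nb))
  s <- igraph::E(network)$weight[eids]
  b <- abundance[nb]
  if (sum(b) == 0) return(0)
  sum(b * s) / sum(b)
}

# wMIS for every node of a (sub)graph at once.
wmis_all <- function(network, abundance) {
  nodes <- igraph::V(network)$name
  adj <- igraph::as_adjacency_matrix(network, attr = "weight", sparse = FALSE)
  b <- abundance[nodes]
  num <- as.vector(adj %*% b)
  den <- as.vector((adj != 0) %*% b)
  out <- ifelse(den == 0, 0, num / den)
  stats::setNames(out, nodes)
}

#' Robustness under random node removal
#'
#' Per replicate, `floor(removal_fraction * N)` nodes are removed uniformly
#' at random; secondary extinction then removes every node whose wMIS on
#' the remaining subgraph is <= 0 (isolated survivors count as extinct),
#' iterating to a fixed point when `iterate_secondary` is on. Robustness is
#' the proportion of the original nodes remaining.
#'
#' @param network an igraph graph with >= 4 nodes and signed `weight`
#'   edge attributes.
#' @param abundance named relative-abundance vector covering all nodes
#'   (conventionally each taxon's mean relative abundance over the group's
#'   samples).
#' @param removal_fraction fraction of nodes removed at random, in (0, 1)
#'   (default 0.5).
#' @param n_replicates number of random-removal replicates.
#' @param iterate_secondary iterate extinction to a fixed point (TRUE,
#'   default) or apply a single pass (FALSE).
#' @param seed integer seed.
#' @return list of class `robustness_result`: `per_replicate`, `mean`, `sd`,
#'   plus the configuration used.
#' @export
robustness_simulation <- function(network, abundance, removal_fraction = 0.5,
                                  n_replicates = 100, iterate_secondary = TRUE,
                                  seed = 1L) {
  stopifnot(removal_fraction > 0, removal_fraction < 1, n_replicates >= 1)
  n <- igraph::vcount(network)
  if (n < 4) stop("network must have >= 4 nodes", call. = FALSE)
  nodes <- igraph::V(network)$name
  if (!all(nodes %in% names(abundance)))
    mn_stop("missing_abundance", "abundance must cover every node")
  set.seed(seed)
  n_remove <- floor(removal_fraction * n)
  vals <- vapply(seq_len(n_replicates), function(rep) {
    keep <- setdiff(nodes, sample(nodes, n_remove))
    repeat {
      if (length(keep) == 0) break
      g <- igraph::induced_subgraph(network, keep)
      w <- wmis_all(g, abundance)
      dead <- names(w)[w <= 0]
      if (length(dead) == 0) break
      keep <- setdiff(keep, dead)
      if (!iterate_secondary) break
    }
    length(keep) / n
  }, numeric(1))
  structure(list(per_replicate = vals, mean = mean(vals),
                 sd = stats::sd(vals), removal_fraction = removal_fraction,
                 n_replicates = n_replicates,
                 iterate_secondary = iterate_secondary),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("robustness: %.4f +/- %.4f (%d replicates, %.0f%% removal)\n",
              x$mean, x$sd, x$n_replicates, 100 * x$removal_fraction))
  invisible(x)
}

#' Connectedness: null-corrected mean pairwise correlation per taxon
#'
#' Observed pairwise Pearson correlations on per-sample relative abundances
#' are corrected by subtracting, pair by pair, the mean correlation over
#' `n_null` taxa-shuffle permutations (each taxon's abundance vector
#' permuted independently across samples). A taxon's positive (negative)
#' connectedness is the mean of its positive (negative) corrected
#' correlations, 0 if it has none.
#'
#' @param table taxa x samples count matrix (>= 3 taxa, >= 5 samples).
#' @param n_null number of permutation datasets (default 200).
#' @param seed integer seed.
#' @return data.frame: taxon, r_pos (>= 0), r_neg (<= 0). The corrected
#'   correlation matrix is attached as attribute `corrected`.
#' @export
connectedness <- function(table, n_null = 200, seed = 1L) {
  check_count_table(table)
  if (ncol(table) < 5) stop("need >= 5 samples", call. = FALSE)
  if (nrow(table) < 3) stop("need >= 3 taxa", call. = FALSE)
  x <- relative_abundance(table)
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance taxa: ",
            paste(rownames(x)[v == 0], collapse = ", "))
    x <- x[v > 0, , drop = FALSE]
  }
  obs <- stats::cor(t(x))
  set.seed(seed)
  null_sum <- matrix(0, nrow(x), nrow(x))
  for (b in seq_len(n_null)) {
    xp <- t(apply(x, 1, sample))
    # re-close the permuted composition so the null carries the same
    # compositional bias as the observed correlations
    xp <- sweep(xp, 2, colSums(xp), "/")
    null_sum <- null_sum + stats::cor(t(xp))
  }
  corrected <- obs - null_sum / n_null
  diag(corrected) <- 0
  r_pos <- apply(corrected, 1, function(r) {
    r <- r[r > 0]; if (length(r)) mean(r) else 0
  })
  r_neg <- apply(corrected, 1, function(r) {
    r <- r[r < 0]; if (length(r)) mean(r) else 0
  })
  out <- data.frame(taxon = rownames(x), r_pos = r_pos, r_neg = r_neg,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "corrected") <- corrected
  out
}

#' Positive and negative cohesion per sample
#'
#' \deqn{c_j^{pos} = \sum_i a_{ij} \bar{r}_{i}^{pos}, \qquad
#'       c_j^{neg} = \sum_i a_{ij} \bar{r}_{i}^{neg}}
#' with \eqn{a_{ij}} the relative abundance of taxon i in sample j and
#' \eqn{\bar{r}} the taxon's connectedness. Positive cohesion indexes
#' cooperative community structure, negative cohesion competitive
#' structure.
#'
#' @param table taxa x samples count matrix.
#' @param conn connectedness data.frame from [connectedness()] (columns
#'   taxon, r_pos, r_neg) computed on the same taxon set.
#' @return data.frame: sample, positive (>= 0), negative (<= 0).
#' @export
cohesion <- function(table, conn) {
  check_count_table(table)
  if (!all(conn$taxon %in% rownames(table)))
    mn_stop("alignment_error",
            "connectedness taxa missing from the count table")
  x <- relative_abundance(table[conn$taxon, , drop = FALSE])
  data.frame(sample = colnames(x),
             positive = as.vector(t(x) %*% conn$r_pos),
             negative = as.vector(t(x) %*% conn$r_neg),
             row.names = NULL, stringsAsFactors = FALSE)
}
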