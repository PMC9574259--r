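# Topological indices of molecular ecological networks: scale-free fit,
# small-world path length, modularity and module detection, Zi-Pi node
# roles, degree-preserving nulls, and bipartite descriptors.

#' Power-law fit of the degree distribution
#'
#' Least-squares fit of log(frequency) against log(degree) over observed
#' degrees >= 1. A high R-squared is the conventional scale-free check in
#' ecological network analysis.
#'
#' @param network an igraph graph.
#' @return list with `exponent` (negated slope) and `r_squared`.
#' @export
powerlaw_fit <- function(network) {
  deg <- igraph::degree(network)
  deg <- deg[deg >= 1]
  freq <- table(deg)
  if (length(freq) < 3)
    mn_stop("degenerate_degree_distribution",
            "need >= 3 distinct degree values for a power-law fit")
  k <- log(as.numeric(names(freq)))
  f <- log(as.numeric(freq))
  fit <- stats::lm(f ~ k)
  list(exponent = -unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared)
}

#' Average path length (GD)
#'
#' Mean shortest-path length over all connected node pairs, with edges
#' treated as unweighted and undirected; disconnected pairs are excluded
#' and counted.
#'
#' @param network an igraph graph.
#' @return list with `gd`, `n_pairs` (connected pairs) and
#'   `n_disconnected_pairs`.
#' @export
avg_path_length <- function(network) {
  n <- igraph::vcount(network)
  if (n == 0) mn_stop("no_paths", "empty network")
  d <- igraph::distances(network, weights = NA)
  up <- d[upper.tri(d)]
  finite <- is.finite(up)
  if (!any(finite)) mn_stop("no_paths", "no connected node pair")
  list(gd = mean(up[finite]), n_pairs = sum(finite),
       n_disconnected_pairs = sum(!finite))
}

#' Detect modules by greedy modularity maximization
#'
#' Greedy agglomerative optimization of Newman modularity
#' \eqn{Q = \sum_m (e_{mm} - a_m^2)} on absolute edge weights (sign is an
#' edge attribute, not a distance).
#'
#' @param network an igraph graph with >= 1 edge.
#' @param seed ignored (the greedy optimizer is deterministic); kept for
#'   interface symmetry with the stochastic stages. The global RNG state
#'   is never touched, so this function is safe inside resampling loops.
#' @return list with `membership` (named integer vector node -> module),
#'   `modularity` (Q of that partition) and `n_modules`.
#' @export
detect_modules <- function(network, seed = 1L) {
  if (igraph::ecount(network) < 1)
    stop("network has no edges", call. = FALSE)
  w <- abs(igraph::E(network)$weight %||% rep(1, igraph::ecount(network)))
  cl <- igraph::cluster_fast_greedy(network, weights = w)
  memb <- igraph::membership(cl)
  q <- igraph::modularity(network, memb, weights = w)
  if (q <= 0) {
    # no split improves on the trivial partition (Q = 0): one module
    memb <- stats::setNames(rep(1L, igraph::vcount(network)),
                            igraph::V(network)$name)
    q <- 0
  }
  list(membership = stats::setNames(as.integer(memb), names(memb)),
       modularity = q,
       n_modules = length(unique(memb)))
}

#' Zi-Pi node roles
#'
#' Within-module degree z-score \eqn{Z_i = (k_{i,in} - \bar{k}_{in}) /
#' sd(k_{in})} (0 when the module's sd is 0) and among-module connectivity
#' \eqn{P_i = 1 - \sum_m (k_{i,m}/k_i)^2}, computed on the unweighted
#' adjacency. Roles follow the Guimera-Amaral convention: network hubs
#' (\eqn{Z_i \ge} `z_threshold` and \eqn{P_i \ge} `p_threshold`), module
#' hubs (high Z only), connectors (high P only), else peripherals. Module
#' hubs, connectors and network hubs are the keystone candidates.
#'
#' @param network an igraph graph.
#' @param membership named node -> module map covering all nodes (from
#'   [detect_modules()]).
#' @param z_threshold within-module degree z-score cut (default 2.5).
#' @param p_threshold among-module connectivity cut (default 0.62).
#' @return data.frame: taxon, module, zi, pi, role. Degree-zero nodes are
#'   excluded with a warning.
#' @export
zi_pi <- function(network, membership, z_threshold = 2.5, p_threshold = 0.62) {
  nodes <- igraph::V(network)$name
  if (!all(nodes %in% names(membership)))
    stop("membership must cover every node", call. = FALSE)
  deg <- igraph::degree(network)
  if (any(deg == 0)) {
    warning("excluding degree-0 node(s): ",
            paste(nodes[deg == 0], collapse = ", "))
    nodes <- nodes[deg > 0]
  }
  memb <- membership[nodes]
  adj <- igraph::as_adjacency_matrix(network, sparse = FALSE)
  adj <- (adj[nodes, nodes, drop = FALSE] != 0) * 1
  mods <- sort(unique(memb))
  # k_im: links of node i into module m
  k_im <- sapply(mods, function(m) rowSums(adj[, memb == m, drop = FALSE]))
  if (is.null(dim(k_im))) k_im <- matrix(k_im, nrow = length(nodes))
  k <- rowSums(k_im)
  k_in <- k_im[cbind(seq_along(nodes), match(memb, mods))]
  zi <- numeric(length(nodes))
  for (m in mods) {
    sel <- memb == m
    mu <- mean(k_in[sel]); sdv <- stats::sd(k_in[sel])
    zi[sel] <- if (is.na(sdv) || sdv == 0) 0 else (k_in[sel] - mu) / sdv
  }
  pi <- 1 - rowSums((k_im / k)^2)
  role <- ifelse(zi >= z_threshold & pi >= p_threshold, "network_hub",
          ifelse(zi >= z_threshold, "module_hub",
          ifelse(pi >= p_threshold, "connector", "peripheral")))
  data.frame(taxon = nodes, module = as.integer(memb), zi = zi, pi = pi,
             role = role, row.names = NULL, stringsAsFactors = FALSE)
}

#' Degree-preserving random network null
#'
#' Generates `n_random` rewired graphs (edge swaps preserving the degree
#' sequence; `10 |E|` successful swaps each), computes average path length
#' and modularity for each, and contrasts the empirical values against the
#' ensemble with a one-sample Student's t test.
#'
#' @param network an igraph graph with >= 2 edges.
#' @param n_random ensemble size (>= 10).
#' @param seed integer seed.
#' @return list with `gd` and `modularity`, each holding `empirical`,
#'   `null_mean`, `null_sd`, `t`, `p_value`, `null_values`.
#' @export
random_network_null <- function(network, n_random = 100, seed = 1L) {
  stopifnot(n_random >= 10)
  if (igraph::ecount(network) < 2)
    mn_stop("null_infeasible", "graph too small to rewire (< 2 edges)")
  set.seed(seed)
  emp_gd <- avg_path_length(network)$gd
  emp_q <- detect_modules(network)$modularity
  gd0 <- q0 <- numeric(n_random)
  deg0 <- sort(igraph::degree(network))
  for (i in seq_len(n_random)) {
    g <- igraph::rewire(network,
                        igraph::keeping_degseq(niter = 10 * igraph::ecount(network)))
    stopifnot(identical(sort(igraph::degree(g)), deg0))
    igraph::E(g)$weight <- 1
    gd0[i] <- avg_path_length(g)$gd
    q0[i] <- detect_modules(g)$modularity
  }
  one_sample <- function(null, emp) {
    if (stats::sd(null) < 1e-12) {
      # degenerate ensemble: every rewiring gives the same value
      tt <- list(statistic = if (abs(mean(null) - emp) < 1e-12) 0 else
                   sign(mean(null) - emp) * Inf, p.value = NA_real_)
    } else tt <- stats::t.test(null, mu = emp)
    list(empirical = emp, null_mean = mean(null), null_sd = stats::sd(null),
         t = unname(tt$statistic), p_value = tt$p.value, null_values = null)
  }
  list(gd = one_sample(gd0, emp_gd), modularity = one_sample(q0, emp_q))
}

#' Bipartite network descriptors
#'
#' Connectance \eqn{L/(R C)}, web asymmetry \eqn{(C - R)/(C + R)} (rows
#' \eqn{R} = fungal, columns \eqn{C} = bacterial node counts), links per
#' species \eqn{L/(R + C)}, NODF nestedness on the binary incidence matrix,
#' and bipartite modularity by greedy maximization on the incidence graph.
#'
#' @param network a bipartite igraph graph whose vertices carry a `domain`
#'   attribute with exactly two levels (`"bacteria"`, `"fungi"`).
#' @return list: n_bacteria, n_fungi, n_links, connectance, web_asymmetry,
#'   links_per_species, nodf, modularity.
#' @export
bipartite_metrics <- function(network) {
  dom <- igraph::V(network)$domain
  if (is.null(dom) || !all(dom %in% c("bacteria", "fungi")))
    stop("network vertices need a bacteria/fungi `domain` attribute",
         call. = FALSE)
  el <- igraph::as_edgelist(network)
  dmap <- stats::setNames(dom, igraph::V(network)$name)
  bad <- dmap[el[, 1]] == dmap[el[, 2]]
  if (any(bad))
    mn_stop("domain_violation",
            paste0("within-domain edge(s): ",
                   paste(el[bad, 1], el[bad, 2], sep = "--", collapse = ", ")))
  bac <- igraph::V(network)$name[dom == "bacteria"]
  fun <- igraph::V(network)$name[dom == "fungi"]
  r <- length(fun); cc <- length(bac); l <- nrow(el)
  inc <- matrix(0, r, cc, dimnames = list(fun, bac))
  for (e in seq_len(l)) {
    f <- if (dmap[el[e, 1]] == "fungi") el[e, 1] else el[e, 2]
    b <- if (dmap[el[e, 1]] == "bacteria") el[e, 1] else el[e, 2]
    inc[f, b] <- 1
  }
  q <- detect_modules(network)$modularity
  list(n_bacteria = cc, n_fungi = r, n_links = l,
       connectance = l / (r * cc),
       web_asymmetry = (cc - r) / (cc + r),
       links_per_species = l / (r + cc),
       nodf = unname(vegan::nestednodf(inc)$statistic["NODF"]),
       modularity = q)
}
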