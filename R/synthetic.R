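#' Simulation configuration for synthetic communities
#'
#' Bundles every knob of the synthetic community generator. The defaults
#' emulate the sampling layout of a continuous-cropping field survey scaled
#' to desk size: 8 groups (cultivar plots) of 6 composite samples each,
#' 200 taxa, 2,000 reads per sample.
#'
#' @param n_taxa number of taxa in the regional pool (>= 1).
#' @param n_groups number of sample groups (>= 1).
#' @param samples_per_group samples per group (>= 1).
#' @param depth sequencing depth (reads per sample, >= 100).
#' @param n_blocks number of planted correlation blocks.
#' @param block_size taxa per planted block.
#' @param block_strength latent-factor loading in [0, 1]; 0 plants nothing.
#' @param selection_strength niche-filtering weight (>= 0); abundance of a
#'   taxon with niche optimum \eqn{z} in a group with environment \eqn{e}
#'   is down-weighted by \eqn{\exp(-s (z - e)^2)}.
#' @param dispersal_rate migration probability in [0, 1]: each sample is a
#'   mixture \eqn{(1-m)} local + \eqn{m} metacommunity.
#' @param drift_steps rounds of multinomial resampling applied to the local
#'   community before a sample is drawn (ecological drift).
#' @param community_size effective number of individuals per drift round.
#' @param pool_sd log-normal sd of the metacommunity pool abundances.
#'   The default (0.3, a moderately even pool) keeps per-bin effective
#'   richness high enough for the phylogenetic null models to have power
#'   at desk scale; real communities reach the same effective richness
#'   through far larger taxon numbers.
#' @param group_env per-group environmental optimum; default all equal (0),
#'   so strong selection acts identically in every group (homogeneous
#'   selection). Distinct per-group optima still plant homogeneous
#'   selection for within-group turnover (each group's environment is
#'   internally uniform), mirroring plots that each select their own
#'   community.
#' @param niche_band optional length-2 vector of node ages (tree depth 1)
#'   confining niche evolution to that depth band: trait variance then
#'   accumulates on branches inside the band (fine-scale diversification
#'   with deep conservatism) instead of uniformly (`NULL`, plain Brownian
#'   motion). Patristic distances are always taken from the original tree.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return a list of class `sim_config`.
#' @seealso [regime_config()] for presets planting a known assembly regime.
#' @export
sim_config <- function(n_taxa = 200, n_groups = 8, samples_per_group = 6,
                       depth = 2000, n_blocks = 4, block_size = 10,
                       block_strength = 0.7, selection_strength = 5,
                       dispersal_rate = 0.3, drift_steps = 5,
                       community_size = 5000, pool_sd = 0.3,
                       group_env = NULL, niche_band = NULL, seed = 1L) {
  stopifnot(n_taxa >= 1, n_groups >= 1, samples_per_group >= 1,
            depth >= 100, n_blocks >= 0, block_size >= 2,
            community_size >= 10)
  if (block_strength < 0 || block_strength > 1)
    stop("block_strength must be in [0, 1]", call. = FALSE)
  if (dispersal_rate < 0 || dispersal_rate > 1)
    stop("dispersal_rate must be in [0, 1]", call. = FALSE)
  if (selection_strength < 0)
    stop("selection_strength must be >= 0", call. = FALSE)
  if (is.null(group_env)) group_env <- rep(0, n_groups)
  if (length(group_env) != n_groups)
    stop("group_env must have one value per group", call. = FALSE)
  if (!is.null(niche_band) &&
      (length(niche_band) != 2 || niche_band[1] >= niche_band[2]))
    stop("niche_band must be c(lo, hi) with lo < hi", call. = FALSE)
  structure(list(
    n_taxa = as.integer(n_taxa), n_groups = as.integer(n_groups),
    samples_per_group = as.integer(samples_per_group),
    depth = as.integer(depth), n_blocks = as.integer(n_blocks),
    block_size = as.integer(block_size), block_strength = block_strength,
    selection_strength = selection_strength, dispersal_rate = dispersal_rate,
    drift_steps = as.integer(drift_steps),
    community_size = as.integer(community_size), pool_sd = pool_sd,
    group_env = group_env, niche_band = niche_band, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Preset configurations planting one dominant assembly regime
#'
#' Each preset fixes the generator so that one ecological process dominates
#' community turnover, giving a known ground truth for the assembly stage:
#' \describe{
#'   \item{selection_dominated}{strong niche filtering against a shared
#'     environment in every group; turnover is expected to be read as
#'     homogeneous selection.}
#'   \item{drift_dominated}{no filtering, no migration, moderate multinomial
#'     drift whose per-sample noise stays within the taxonomic null band;
#'     expected label: drift.}
#'   \item{dispersal_limited}{no filtering, no migration and heavy drift, so
#'     samples diverge beyond the null band; expected label: dispersal
#'     limitation.}
#'   \item{homogenizing_dispersal}{near-complete mixing with the shared
#'     metacommunity; expected label: homogenizing dispersal.}
#' }
#'
#' @param regime one of `"selection_dominated"`, `"drift_dominated"`,
#'   `"dispersal_limited"`, `"homogenizing_dispersal"`.
#' @param ... overrides passed on to [sim_config()] (e.g. `n_taxa`, `seed`).
#' @return a `sim_config`.
#' @export
regime_config <- function(regime = c("selection_dominated", "drift_dominated",
                                     "dispersal_limited",
                                     "homogenizing_dispersal"), ...) {
  regime <- match.arg(regime)
  base <- switch(regime,
    selection_dominated   = list(selection_strength = 80, dispersal_rate = 0,
                                 drift_steps = 0,
                                 niche_band = c(0.02, 0.12)),
    drift_dominated       = list(selection_strength = 0, dispersal_rate = 0,
                                 drift_steps = 20, community_size = 200000),
    dispersal_limited     = list(selection_strength = 0, dispersal_rate = 0,
                                 drift_steps = 200),
    homogenizing_dispersal = list(selection_strength = 0, dispersal_rate = 0.95,
                                 drift_steps = 2))
  args <- utils::modifyList(base, list(...))
  if (regime == "selection_dominated" && is.null(args$group_env)) {
    ng <- args$n_groups %||% 8
    # each plot selects around its own optimum spread across the niche axis
    args$group_env <- seq(-0.45, 0.45, length.out = ng)
  }
  do.call(sim_config, args)
}

# Copy of `tree` whose branch lengths equal each branch's overlap with the
# node-age band [lo, hi] (tree depth 1), plus a small epsilon. Brownian
# traits on the copy accumulate variance only at those depths.
band_limit_tree <- function(tree, lo, hi, eps = 1e-4) {
  nd <- ape::node.depth.edgelength(tree)
  age <- max(nd) - nd
  for (e in seq_len(nrow(tree$edge))) {
    a_old <- age[tree$edge[e, 1]]; a_young <- age[tree$edge[e, 2]]
    tree$edge.length[e] <- max(0, min(a_old, hi) - max(a_young, lo)) + eps
  }
  tree
}

# Dominant planted process implied by a configuration.
regime_label <- function(config) {
  if (config$selection_strength >= 10) "selection_dominated"
  else if (config$dispersal_rate >= 0.9) "homogenizing_dispersal"
  else if (config$dispersal_rate <= 0.05 && config$drift_steps >= 50) "dispersal_limited"
  else "drift_dominated"
}

#' Simulate a rooted ultrametric phylogeny
#'
#' Produces a tree shaped like a cross-taxa OTU phylogeny rather than a
#' single-population genealogy: several deeply divergent clades
#' (phylum-like lineages) joined near the root, each with coalescent
#' branching structure inside. Rescaled to unit depth, tips labelled
#' `OTU_1 ... OTU_n`. Niche optima simulated along this tree by Brownian
#' evolution inherit its structure, which is what the assembly-stage null
#' models exploit. Small trees (fewer than 32 tips) fall back to a single
#' coalescent clade.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed.
#' @param n_clades number of deep clades; the default scales with `n_taxa`
#'   (about one clade per 16-20 taxa, at most 5).
#' @param clade_depth age of each clade's crown relative to total tree
#'   depth 1 (default 0.15): lineages within a clade are each other's
#'   close relatives, lineages across clades are distant.
#' @return an [ape::phylo] rooted binary ultrametric tree.
#' @export
simulate_tree <- function(n_taxa, seed = 1L,
                          n_clades = max(1, min(5, n_taxa %/% 16)),
                          clade_depth = 0.15) {
  if (n_taxa < 2) mn_stop("invalid_argument", "n_taxa must be >= 2")
  set.seed(seed)
  sizes <- rep(n_taxa %/% n_clades, n_clades)
  extra <- n_taxa - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  rescale <- function(tr, d) {
    tr$edge.length <- tr$edge.length * d / max(ape::node.depth.edgelength(tr))
    tr
  }
  if (n_clades == 1) {
    tree <- rescale(ape::rcoal(n_taxa), 1)
  } else {
    off <- c(0, cumsum(sizes))
    sub <- lapply(seq_len(n_clades), function(k) {
      tr <- rescale(ape::rcoal(sizes[k]), clade_depth)
      tr$tip.label <- paste0("t", off[k] + seq_len(sizes[k]))
      sub("();", ";", ape::write.tree(tr))
    })
    strip <- function(s) sub(";$", "", s)
    joins <- seq(1 - 0.01 * (n_clades - 2), 1, by = 0.01)
    cur <- strip(sub[[1]]); cur_age <- clade_depth
    for (k in 2:n_clades) {
      cur <- sprintf("(%s:%.8f,%s:%.8f)", cur, joins[k - 1] - cur_age,
                     strip(sub[[k]]), joins[k - 1] - clade_depth)
      cur_age <- joins[k - 1]
    }
    tree <- rescale(ape::read.tree(text = paste0(cur, ";")), 1)
  }
  tree$tip.label <- if (n_clades == 1) paste0("OTU_", seq_len(n_taxa))
                    else paste0("OTU_", sub("^t", "", tree$tip.label))
  tree
}

#' Simulate grouped communities with planted assembly processes
#'
#' Generative model: taxon niche optima evolve by Brownian motion along the
#' tree; a log-normal metacommunity pool is niche-filtered per group by
#' \eqn{\exp(-s (z_i - e_g)^2)}; each sample mixes the (drifted) local group
#' community with the metacommunity at the dispersal rate, applies
#' `drift_steps` rounds of multinomial resampling at `community_size`
#' individuals, and is finally sequenced by a multinomial draw of `depth`
#' reads.
#'
#' @param config a [sim_config()].
#' @param tree rooted tree whose tips cover `config$n_taxa` taxa; typically
#'   from [simulate_tree()].
#' @return a list with elements `table` (taxa x samples integer count
#'   matrix), `truth` (block membership, niche optima, per-group regime
#'   label), `metadata` (data.frame: sample, group) and `taxonomy`
#'   (data.frame: taxon, lineage — synthetic placeholder lineages).
#' @export
simulate_communities <- function(config, tree) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_taxa
  if (ape::Ntip(tree) < n)
    stop("tree has fewer tips than config$n_taxa", call. = FALSE)
  taxa <- tree$tip.label[seq_len(n)]

  set.seed(config$seed)
  trait_tree <- if (is.null(config$niche_band)) tree else
    band_limit_tree(tree, config$niche_band[1], config$niche_band[2])
  niche <- ape::rTraitCont(trait_tree, model = "BM", sigma = 1)[taxa]
  pool <- exp(stats::rnorm(n, 0, config$pool_sd))
  pool <- pool / sum(pool)
  names(pool) <- taxa

  n_samp <- config$n_groups * config$samples_per_group
  tab <- matrix(0L, n, n_samp, dimnames = list(
    taxa, paste0("S", seq_len(n_samp))))
  groups <- rep(paste0("G", seq_len(config$n_groups)),
                each = config$samples_per_group)

  m <- config$dispersal_rate
  J <- config$community_size
  col <- 0L
  for (g in seq_len(config$n_groups)) {
    w <- pool * exp(-config$selection_strength *
                      (niche - config$group_env[g])^2)
    if (sum(w) <= 0) mn_stop("simulation_degenerate",
                             sprintf("group %d: selection removed all taxa", g))
    p_group <- w / sum(w)
    for (s in seq_len(config$samples_per_group)) {
      col <- col + 1L
      p_loc <- p_group
      if (config$drift_steps > 0) {
        for (t in seq_len(config$drift_steps))
          p_loc <- as.vector(stats::rmultinom(1, J, p_loc)) / J
      }
      p <- (1 - m) * p_loc + m * pool
      cnt <- as.vector(stats::rmultinom(1, config$depth, p))
      if (sum(cnt) == 0)
        mn_stop("simulation_degenerate",
                sprintf("sample %s drew zero reads", colnames(tab)[col]))
      tab[, col] <- cnt
    }
  }

  block <- rep(NA_integer_, n)
  names(block) <- taxa
  if (config$n_blocks > 0) {
    need <- config$n_blocks * config$block_size
    if (need > n) mn_stop("invalid_argument",
                          "planted blocks larger than n_taxa")
    chosen <- sample(taxa, need)
    block[chosen] <- rep(seq_len(config$n_blocks), each = config$block_size)
  }

  phyla <- paste0("Phylum", 1 + (seq_len(n) - 1) %% 8)
  list(
    table = tab,
    truth = list(
      block_membership = block,
      niche_optimum = niche,
      regime_label = stats::setNames(
        rep(regime_label(config), config$n_groups),
        paste0("G", seq_len(config$n_groups)))
    ),
    metadata = data.frame(sample = colnames(tab), group = groups,
                          stringsAsFactors = FALSE),
    taxonomy = data.frame(
      taxon = taxa,
      lineage = paste0("k__Synthetic;p__", phyla),
      stringsAsFactors = FALSE)
  )
}

#' Plant correlated abundance blocks into a count table
#'
#' Taxa sharing a block are re-driven by a shared per-sample latent factor
#' \eqn{f_s \sim N(0,1)}: each block taxon's expected count is multiplied by
#' \eqn{\exp(\rho f_s - \rho^2/2)} where \eqn{\rho} is `block_strength`
#' (the -rho^2/2 term keeps the expectation unchanged). With
#' `resample = TRUE` (default) new counts are Poisson draws around that
#' expectation; with `resample = FALSE` they are deterministic rounded
#' expectations, which makes within-block correlations exact.
#'
#' @param table taxa x samples count matrix.
#' @param truth truth list from [simulate_communities()] (uses
#'   `block_membership`), or a named block-membership vector.
#' @param config a [sim_config()]; `block_strength` and `seed` are used.
#' @param resample draw Poisson counts (TRUE) or round expectations (FALSE).
#' @return count matrix of the same shape with block structure planted.
#' @export
plant_correlation_blocks <- function(table, truth, config, resample = TRUE) {
  check_count_table(table)
  membership <- if (is.list(truth)) truth$block_membership else truth
  membership <- membership[!is.na(membership)]
  if (length(membership) == 0) return(table)
  if (!all(names(membership) %in% rownames(table)))
    mn_stop("invalid_argument", "block members missing from count table")
  rho <- config$block_strength
  set.seed(config$seed + 104729L)  # offset so planting is independent of simulation draws
  out <- table
  for (b in sort(unique(membership))) {
    taxa_b <- names(membership)[membership == b]
    if (length(taxa_b) > nrow(table))
      mn_stop("invalid_argument", "block larger than table")
    f <- stats::rnorm(ncol(table))
    mult <- exp(rho * f - rho^2 / 2)
    lam <- sweep(table[taxa_b, , drop = FALSE], 2, mult, "*")
    if (resample) {
      out[taxa_b, ] <- matrix(stats::rpois(length(lam), lam), nrow(lam))
    } else {
      out[taxa_b, ] <- round(lam)
    }
  }
  storage.mode(out) <- "integer"
  out
}

#' Rarefy a count table to even depth
#'
#' Subsamples every sample without replacement to exactly `depth` reads
#' (the depth-resampling conventionally applied to OTU tables before
#' diversity and network analysis). Taxa left with zero total count are
#' dropped.
#'
#' @param table taxa x samples count matrix.
#' @param depth target reads per sample.
#' @param seed integer seed.
#' @return rarefied count matrix; every column sums to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  check_count_table(table)
  tot <- colSums(table)
  if (any(tot < depth))
    mn_stop("depth_violation",
            paste0("sample(s) shallower than depth ", depth, ": ",
                   paste(colnames(table)[tot < depth], collapse = ", ")))
  set.seed(seed)
  n <- nrow(table)
  out <- vapply(seq_len(ncol(table)), function(j) {
    reads <- rep.int(seq_len(n), table[, j])
    drawn <- if (length(reads) == 1) reads else sample(reads, depth)
    tabulate(drawn, nbins = n)
  }, numeric(n))
  out <- matrix(out, nrow = n,
                dimnames = list(rownames(table), colnames(table)))
  storage.mode(out) <- "integer"
  out[rowSums(out) > 0, , drop = FALSE]
}
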