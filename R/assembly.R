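# Phylogenetic-bin null-model partitioning of community assembly processes:
# taxa are grouped into phylogenetic bins, each bin's turnover between two
# samples is scored by the abundance-weighted beta net relatedness index
# (betaNRI, phylogenetic null) and the modified Raup-Crick metric on
# Bray-Curtis (taxonomic null), the (betaNRI, RC) pair is mapped to one of
# five ecological processes, and per-group process fractions are aggregated
# with bin relative-abundance weights.

#' Phylogenetic bins
#'
#' Single-linkage grouping of taxa whose pairwise patristic distance is at
#' most `distance_threshold`; bins smaller than `min_bin_size` are merged
#' into their phylogenetically nearest bin (smallest mean patristic
#' distance). Deterministic: taxa are processed sorted by id.
#'
#' @param tree rooted tree covering the table's taxa.
#' @param table taxa x samples count matrix.
#' @param distance_threshold patristic radius for single linkage
#'   (default 0.2).
#' @param min_bin_size smallest allowed bin after merging (default 12).
#' @return list of class `phylo_bins`: `bins` (bin id -> taxon ids),
#'   `membership` (taxon -> bin id), `bin_abundance` (mean relative
#'   abundance per bin), plus the parameters used.
#' @export
phylo_bins <- function(tree, table, distance_threshold = 0.2,
                       min_bin_size = 12) {
  check_count_table(table)
  stopifnot(distance_threshold > 0, min_bin_size >= 1)
  taxa <- sort(rownames(table))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    mn_stop("missing_tip", paste0("taxa missing from tree: ",
                                  paste(missing, collapse = ", ")))
  pd <- stats::cophenetic(ape::keep.tip(tree, taxa))[taxa, taxa]
  hc <- stats::hclust(stats::as.dist(pd), method = "single")
  memb <- stats::cutree(hc, h = distance_threshold)
  # merge undersized bins into the nearest bin by mean patristic distance
  repeat {
    sizes <- base::table(memb)
    small <- names(sizes)[sizes < min_bin_size]
    if (length(small) == 0 || length(sizes) == 1) break
    b <- small[order(sizes[small], as.integer(small))][1]
    sel <- memb == as.integer(b)
    others <- setdiff(unique(memb), as.integer(b))
    d_to <- vapply(others, function(o)
      mean(pd[sel, memb == o, drop = FALSE]), numeric(1))
    memb[sel] <- others[which.min(d_to)]
  }
  ids <- match(memb, sort(unique(memb)))  # renumber 1..k
  names(ids) <- taxa
  bins <- split(taxa, ids)
  names(bins) <- paste0("bin", names(bins))
  rel <- relative_abundance(table)
  bin_ab <- vapply(bins, function(tx) mean(colSums(rel[tx, , drop = FALSE])),
                   numeric(1))
  structure(list(bins = bins,
                 membership = stats::setNames(paste0("bin", ids), taxa),
                 bin_abundance = bin_ab,
                 distance_threshold = distance_threshold,
                 min_bin_size = min_bin_size),
            class = "phylo_bins")
}

#' @export
print.phylo_bins <- function(x, ...) {
  cat(sprintf("phylo_bins: %d bins over %d taxa (radius %.3g, min size %d)\n",
              length(x$bins), length(x$membership), x$distance_threshold,
              x$min_bin_size))
  invisible(x)
}

# Abundance-weighted between-sample mean pairwise phylogenetic distance
# for one bin: f_a' D f_b with f the within-bin relative abundances.
beta_mpd <- function(fa, fb, d) as.numeric(fa %*% d %*% fb)

#' Beta net relatedness index (betaNRI) for one bin and sample pair
#'
#' Standardized effect size of the abundance-weighted between-sample mean
#' pairwise phylogenetic distance (betaMPD) against a null that shuffles
#' taxon identities across the bin's tips:
#' \eqn{\beta NRI = (obs - mean_{null}) / sd_{null}}.
#'
#' @param table taxa x samples count matrix.
#' @param pair character vector of two sample ids.
#' @param bin character vector of the bin's taxon ids (>= 2 present across
#'   the pair).
#' @param tree rooted tree covering the bin.
#' @param n_null null randomizations (>= 100 for real use).
#' @param seed integer seed.
#' @return a single betaNRI value.
#' @export
beta_nri <- function(table, pair, bin, tree, n_null = 1000, seed = 1L) {
  check_count_table(table)
  stopifnot(length(pair) == 2, all(pair %in% colnames(table)))
  bin <- intersect(bin, rownames(table))
  sub <- table[bin, pair, drop = FALSE]
  present <- rowSums(sub) > 0
  if (sum(present) < 2)
    mn_stop("empty_bin", "bin needs >= 2 taxa present across the pair")
  d <- stats::cophenetic(ape::keep.tip(tree, bin))[bin, bin]
  fa <- sub[, 1] / sum(sub[, 1]); fb <- sub[, 2] / sum(sub[, 2])
  if (any(!is.finite(fa)) || any(!is.finite(fb)))
    mn_stop("empty_bin", "a sample has no reads in this bin")
  obs <- beta_mpd(fa, fb, d)
  set.seed(seed)
  k <- length(bin)
  null <- vapply(seq_len(n_null), function(i) {
    p <- sample(k)
    beta_mpd(fa, fb, d[p, p, drop = FALSE])
  }, numeric(1))
  sdv <- stats::sd(null)
  if (is.na(sdv) || sdv < 1e-12)
    mn_stop("undefined_ses", "null betaMPD distribution has zero variance")
  (obs - mean(null)) / sdv
}

#' Modified Raup-Crick metric on Bray-Curtis (RC) for one bin and pair
#'
#' Observed Bray-Curtis dissimilarity within the bin, ranked against null
#' communities assembled by drawing each sample's observed within-bin
#' richness (taxa drawn with probability proportional to occupancy across
#' all samples) and observed within-bin read total (individuals drawn with
#' probability proportional to mean relative abundance). RC = 2 x (fraction
#' of null values below the observed, ties counted half) - 1, in [-1, 1].
#'
#' @inheritParams beta_nri
#' @param pool_samples sample ids over which taxon occupancy and mean
#'   relative abundance are estimated for the null draws; defaults to all
#'   samples. For grouped designs, pass the pair's group so the null
#'   represents stochastic assembly from the local species pool.
#' @return a single RC value in [-1, 1].
#' @export
rc_bray <- function(table, pair, bin, n_null = 1000, seed = 1L,
                    pool_samples = NULL) {
  check_count_table(table)
  stopifnot(length(pair) == 2, all(pair %in% colnames(table)))
  if (is.null(pool_samples)) pool_samples <- colnames(table)
  bin <- intersect(bin, rownames(table))
  sub_all <- table[bin, pool_samples, drop = FALSE]
  sub <- table[bin, pair, drop = FALSE]
  if (all(sub == 0)) mn_stop("empty_bin", "bin empty in both samples")
  obs <- as.numeric(vegan::vegdist(t(sub), method = "bray"))
  occupancy <- rowMeans(sub_all > 0)
  mean_rel <- rowMeans(sweep(sub_all, 2, pmax(colSums(sub_all), 1), "/"))
  k <- length(bin)
  set.seed(seed)
  draw_null <- function(richness, n_reads) {
    cnt <- numeric(k)
    if (richness == 0 || n_reads == 0) return(cnt)
    richness <- min(richness, sum(occupancy > 0))
    chosen <- sample(k, richness, prob = occupancy)
    cnt[chosen] <- 1  # each drawn taxon holds at least one individual
    extra <- n_reads - richness
    if (extra > 0) {
      p <- mean_rel[chosen]
      if (sum(p) == 0) p <- rep(1, richness)
      cnt[chosen] <- cnt[chosen] +
        as.vector(stats::rmultinom(1, extra, p))
    }
    cnt
  }
  rich <- colSums(sub > 0); reads <- colSums(sub)
  null <- vapply(seq_len(n_null), function(i) {
    a <- draw_null(rich[1], reads[1])
    b <- draw_null(rich[2], reads[2])
    if (sum(a) == 0 && sum(b) == 0) return(obs)  # degenerate null: tie
    as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
  }, numeric(1))
  2 * ((sum(null < obs) + 0.5 * sum(null == obs)) / n_null) - 1
}

#' Classify a turnover into an ecological process
#'
#' Decision rule on the (betaNRI, RC) pair: betaNRI above the SES threshold
#' is heterogeneous selection, below its negative is homogeneous selection;
#' otherwise RC above the RC threshold is dispersal limitation, below its
#' negative is homogenizing dispersal, and the remainder is drift.
#'
#' @param beta_nri betaNRI value.
#' @param rc RC value.
#' @param ses_threshold SES cut (default 1.96).
#' @param rc_threshold RC cut (default 0.95).
#' @return one of `"heterogeneous_selection"`, `"homogeneous_selection"`,
#'   `"dispersal_limitation"`, `"homogenizing_dispersal"`, `"drift"`.
#' @export
classify_turnover <- function(beta_nri, rc, ses_threshold = 1.96,
                              rc_threshold = 0.95) {
  stopifnot(is.finite(beta_nri), is.finite(rc))
  if (beta_nri > ses_threshold) "heterogeneous_selection"
  else if (beta_nri < -ses_threshold) "homogeneous_selection"
  else if (rc > rc_threshold) "dispersal_limitation"
  else if (rc < -rc_threshold) "homogenizing_dispersal"
  else "drift"
}

assembly_processes <- c("heterogeneous_selection", "homogeneous_selection",
                        "dispersal_limitation", "homogenizing_dispersal",
                        "drift")

#' Score every within-group sample pair and bin
#'
#' Runs [beta_nri()] and [rc_bray()] for each within-group sample pair and
#' each phylogenetic bin, then classifies the turnover. Bins with an
#' undefined SES (zero null variance) are recorded with `NA` and excluded
#' from aggregation.
#'
#' @param table taxa x samples count matrix.
#' @param tree rooted tree covering the table's taxa.
#' @param bins a `phylo_bins` object.
#' @param metadata data.frame with columns `sample`, `group`.
#' @param n_null null randomizations per score.
#' @param seed integer seed.
#' @param within_group_only score only within-group pairs (default TRUE).
#' @return data.frame: sample_a, sample_b, group, bin, beta_nri, rc,
#'   process (`NA` process marks excluded bins).
#' @export
score_turnovers <- function(table, tree, bins, metadata, n_null = 1000,
                            seed = 1L, within_group_only = TRUE) {
  stopifnot(inherits(bins, "phylo_bins"))
  groups <- stats::setNames(metadata$group, metadata$sample)
  samples <- intersect(colnames(table), metadata$sample)
  if (within_group_only &&
      any(base::table(groups[samples]) < 2))
    mn_stop("insufficient_pairs",
            "every group needs >= 2 samples for within-group turnover")
  pairs <- utils::combn(samples, 2)
  keep <- if (within_group_only)
    groups[pairs[1, ]] == groups[pairs[2, ]] else rep(TRUE, ncol(pairs))
  pairs <- pairs[, keep, drop = FALSE]
  res <- vector("list", ncol(pairs) * length(bins$bins))
  idx <- 0
  for (p in seq_len(ncol(pairs))) {
    pr <- pairs[, p]
    for (b in names(bins$bins)) {
      idx <- idx + 1
      # derive independent, reproducible sub-seeds per (pair, bin)
      sseed <- (seed * 7919L + p * 131L + idx) %% 2147483629L
      bn <- tryCatch(
        beta_nri(table, pr, bins$bins[[b]], tree, n_null, seed = sseed),
        undefined_ses = function(e) NA_real_,
        empty_bin = function(e) NA_real_)
      grp_samples <- samples[groups[samples] == groups[pr[1]]]
      rc <- tryCatch(
        rc_bray(table, pr, bins$bins[[b]], n_null, seed = sseed + 1L,
                pool_samples = if (within_group_only) grp_samples),
        empty_bin = function(e) NA_real_)
      proc <- if (is.na(bn) || is.na(rc)) NA_character_
              else classify_turnover(bn, rc)
      res[[idx]] <- data.frame(
        sample_a = pr[1], sample_b = pr[2],
        group = unname(groups[pr[1]]), bin = b,
        beta_nri = bn, rc = rc, process = proc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Aggregate turnover scores into per-group process fractions
#'
#' Per group, each process fraction is the bin-relative-abundance-weighted
#' share of (pair x bin) turnovers assigned to that process, normalized so
#' the five fractions sum to 1.
#'
#' @param scores data.frame from [score_turnovers()].
#' @param bins a `phylo_bins` object (provides the abundance weights).
#' @return data.frame: group plus one column per process, rows summing
#'   to 1.
#' @export
aggregate_processes <- function(scores, bins) {
  stopifnot(inherits(bins, "phylo_bins"))
  scores <- scores[!is.na(scores$process), , drop = FALSE]
  if (nrow(scores) == 0) stop("no classified turnover", call. = FALSE)
  w <- bins$bin_abundance[scores$bin]
  out <- lapply(split(seq_len(nrow(scores)), scores$group), function(ii) {
    sw <- tapply(w[ii], factor(scores$process[ii], levels = assembly_processes),
                 sum, default = 0)
    sw / sum(sw)
  })
  res <- data.frame(group = names(out), do.call(rbind, out),
                    row.names = NULL, stringsAsFactors = FALSE)
  names(res)[-1] <- assembly_processes
  res
}
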