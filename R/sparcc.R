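# SparCC: correlation inference for compositional count data.
#
# The log-ratio variance t_ij = var(log(x_i/x_j)) is invariant to the
# compositional closure. Writing t_ij = w_i^2 + w_j^2 - 2 r_ij w_i w_j with
# w_i the (unobservable) basis log-abundance standard deviations, the sparsity
# assumption sum_{j!=i} r_ij w_i w_j ~ 0 turns the row sums of T into a linear
# system for the basis variances, from which correlations follow. Strongly
# correlated pairs violate the sparsity assumption, so the single strongest
# pair above an exclusion threshold is removed from the system per iteration
# and the basis re-solved.

# Solve basis variances given the log-ratio variance matrix and a logical
# mask of included pairs. System: sum_{j in S_i} t_ij =
# |S_i| w_i^2 + sum_{j in S_i} w_j^2 (under the sparsity assumption).
solve_basis <- function(tmat, include) {
  d <- nrow(tmat)
  a <- include * 1
  diag(a) <- 0
  lhs <- diag(rowSums(a)) + a
  rhs <- rowSums(tmat * a)
  w2 <- try(solve(lhs, rhs), silent = TRUE)
  if (inherits(w2, "try-error"))
    w2 <- rep(mean(tmat[upper.tri(tmat)]) / 2, d)
  if (any(w2 <= 0)) {
    warning("SparCC: clamping non-positive basis variance estimate(s)")
    pos <- w2[w2 > 0]
    w2[w2 <= 0] <- if (length(pos)) min(pos) else 1e-6
  }
  w2
}

sparcc_from_fractions <- function(logx, n_iterations, exclusion_threshold,
                                  max_exclusions) {
  d <- nrow(logx)
  # log-ratio variance matrix
  vlog <- apply(logx, 1, stats::var)           # var(log x_i)
  cv <- stats::cov(t(logx))
  tmat <- outer(vlog, vlog, "+") - 2 * cv      # var(log x_i - log x_j)
  if (max(abs(tmat[upper.tri(tmat)])) < 1e-12)
    mn_stop("degenerate_input",
            "all samples share one composition; log-ratios are constant")
  include <- matrix(TRUE, d, d)
  n_excluded <- 0
  rmat <- NULL
  for (it in seq_len(max(1, n_iterations))) {
    w2 <- solve_basis(tmat, include)
    w <- sqrt(w2)
    rmat <- (outer(w2, w2, "+") - tmat) / (2 * outer(w, w))
    rmat[rmat > 1] <- 1; rmat[rmat < -1] <- -1
    diag(rmat) <- 1
    cand <- abs(rmat) * include
    diag(cand) <- 0
    if (n_excluded >= max_exclusions || max(cand) <= exclusion_threshold) break
    worst <- which(cand == max(cand), arr.ind = TRUE)[1, ]
    include[worst[1], worst[2]] <- include[worst[2], worst[1]] <- FALSE
    n_excluded <- n_excluded + 1
  }
  dimnames(rmat) <- dimnames(tmat)
  rmat
}

#' SparCC correlations for compositional data
#'
#' Estimates taxon-taxon correlations robust to the compositional closure of
#' sequencing counts, for one table or for the concatenation of two domain
#' tables (the inter-domain use case: bacterial and fungal counts over the
#' same samples). Pseudo-p-values come from permutation datasets in which
#' every taxon's counts are shuffled independently across samples.
#'
#' @param table_a taxa x samples count matrix (e.g. bacteria).
#' @param table_b optional second table over the same samples (e.g. fungi);
#'   when given, the returned matrix is joint and carries a domain map.
#' @param n_iterations maximum basis re-solve iterations (each may exclude
#'   one strongly correlated pair).
#' @param n_bootstrap number of permutation datasets for pseudo-p-values
#'   (0 skips them).
#' @param seed integer seed for the permutations.
#' @param exclusion_threshold pairs with |r| above this violate the sparsity
#'   assumption and are excluded one per iteration.
#' @param max_exclusions cap on excluded pairs.
#' @param pseudocount added to counts before log-ratios (zeros are otherwise
#'   undefined).
#' @return an `assoc_matrix` with `method = "sparcc"`, pseudo-p-values (when
#'   `n_bootstrap > 0`) and, for two tables, a `domains` map
#'   (`"bacteria"`/`"fungi"` by argument order).
#' @export
sparcc_correlations <- function(table_a, table_b = NULL, n_iterations = 20,
                                n_bootstrap = 100, seed = 1L,
                                exclusion_threshold = 0.8,
                                max_exclusions = 10, pseudocount = 1) {
  check_count_table(table_a, "table_a")
  stopifnot(n_iterations >= 1)
  domains <- NULL
  if (!is.null(table_b)) {
    check_count_table(table_b, "table_b")
    if (!identical(colnames(table_a), colnames(table_b)))
      mn_stop("sample_mismatch",
              "table_a and table_b must share an identical sample set/order")
    if (any(rownames(table_b) %in% rownames(table_a)))
      stop("taxon ids overlap between the two tables", call. = FALSE)
    domains <- c(stats::setNames(rep("bacteria", nrow(table_a)), rownames(table_a)),
                 stats::setNames(rep("fungi", nrow(table_b)), rownames(table_b)))
    table_a <- rbind(table_a, table_b)
  }
  counts <- table_a + pseudocount
  logx <- log(sweep(counts, 2, colSums(counts), "/"))
  r_obs <- sparcc_from_fractions(logx, n_iterations, exclusion_threshold,
                                 max_exclusions)
  pvals <- NULL
  if (n_bootstrap > 0) {
    set.seed(seed)
    d <- nrow(counts); n <- ncol(counts)
    exceed <- matrix(0, d, d)
    for (b in seq_len(n_bootstrap)) {
      perm <- t(apply(counts, 1, sample))
      plog <- log(sweep(perm, 2, colSums(perm), "/"))
      r_b <- suppressWarnings(
        sparcc_from_fractions(plog, n_iterations, exclusion_threshold,
                              max_exclusions))
      exceed <- exceed + (abs(r_b) >= abs(r_obs))
    }
    pvals <- (exceed + 1) / (n_bootstrap + 1)
    diag(pvals) <- 0
    dimnames(pvals) <- dimnames(r_obs)
  }
  new_assoc(r_obs, "sparcc", "log_ratio", pvalues = pvals, domains = domains)
}
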