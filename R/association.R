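#' Filter taxa by prevalence
#'
#' Keeps taxa detected (count > 0) in at least `min_fraction` of samples.
#' The sample set is never changed.
#'
#' @param table taxa x samples count matrix.
#' @param min_fraction required presence fraction in [0, 1].
#' @return filtered count matrix.
#' @export
prevalence_filter <- function(table, min_fraction) {
  check_count_table(table)
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  prev <- rowMeans(table > 0)
  out <- table[prev >= min_fraction, , drop = FALSE]
  if (nrow(out) == 0) mn_stop("empty_table", "no taxon passes the prevalence filter")
  out
}

#' Core OTUs of a community
#'
#' Core taxa are those present in at least `min_fraction` of all samples
#' (default 95\%, the conventional core-microbiome cut).
#'
#' @param table taxa x samples count matrix.
#' @param min_fraction presence fraction defining "core" (default 0.95).
#' @return character vector of core taxon ids (possibly empty).
#' @export
core_otus <- function(table, min_fraction = 0.95) {
  check_count_table(table)
  rownames(table)[rowMeans(table > 0) >= min_fraction]
}

# Constructor for association matrices; enforces symmetry/diagonal/bounds.
new_assoc <- function(r, method, transform, pvalues = NULL, domains = NULL) {
  stopifnot(isSymmetric(unname(r)))
  diag(r) <- 1
  r[r > 1] <- 1; r[r < -1] <- -1
  structure(list(r = r, method = method, transform = transform,
                 pvalues = pvalues, domains = domains),
            class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("assoc_matrix: %d taxa, method=%s, transform=%s, pvalues=%s\n",
              nrow(x$r), x$method, x$transform,
              if (is.null(x$pvalues)) "no" else "yes"))
  invisible(x)
}

#' Pearson association matrix
#'
#' Pairwise Pearson correlations across samples of transformed abundances,
#' the association measure used for intra-domain networks. Taxa with zero
#' variance after the transform are dropped with a warning (they carry no
#' correlation information).
#'
#' @param table taxa x samples count matrix.
#' @param transform `"relative"` (per-sample relative abundance) or
#'   `"log_relative"` (`log(relative + pseudocount)`, pseudocount = half the
#'   smallest nonzero relative abundance).
#' @return an `assoc_matrix` (fields `r`, `method`, `transform`).
#' @export
pearson_matrix <- function(table, transform = c("relative", "log_relative")) {
  check_count_table(table)
  transform <- match.arg(transform)
  if (ncol(table) < 3)
    mn_stop("insufficient_samples", "need >= 3 samples for correlations")
  x <- relative_abundance(table)
  if (transform == "log_relative") {
    pc <- min(x[x > 0]) / 2
    x <- log(x + pc)
  }
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance taxa: ",
            paste(rownames(x)[v == 0], collapse = ", "))
    x <- x[v > 0, , drop = FALSE]
  }
  if (nrow(x) < 2) mn_stop("empty_table", "fewer than 2 variable taxa")
  r <- stats::cor(t(x))
  new_assoc(r, "pearson", transform)
}

#' Build a co-occurrence network from an association matrix
#'
#' Retains edges with \eqn{|s_{ij}| \ge} `cutoff` (and \eqn{p \le}
#' `p_cutoff` when p-values are present). In bipartite mode only edges
#' joining the two domains are kept. Isolated nodes are dropped. Edges
#' carry the signed association strength as weight.
#'
#' @param assoc an `assoc_matrix`.
#' @param cutoff association-strength threshold in [0, 1].
#' @param p_cutoff optional significance level applied when the matrix has
#'   p-values.
#' @param mode `"intra"` or `"bipartite"`.
#' @param domains named character vector mapping taxon id to domain
#'   (e.g. `"bacteria"`/`"fungi"`); required for bipartite mode (defaults
#'   to the matrix's own domain map when present).
#' @param abundance optional named vector of node relative abundances,
#'   stored as a vertex attribute.
#' @return an [igraph::igraph] graph with vertex attributes `name`,
#'   `domain`, `abundance` and edge attributes `weight` (signed) and `sign`.
#' @export
build_network <- function(assoc, cutoff, p_cutoff = NULL,
                          mode = c("intra", "bipartite"),
                          domains = NULL, abundance = NULL) {
  stopifnot(inherits(assoc, "assoc_matrix"), cutoff >= 0, cutoff <= 1)
  mode <- match.arg(mode)
  r <- assoc$r
  keep <- abs(r) >= cutoff
  diag(keep) <- FALSE
  if (!is.null(p_cutoff)) {
    if (is.null(assoc$pvalues))
      stop("p_cutoff given but association matrix has no p-values", call. = FALSE)
    keep <- keep & (assoc$pvalues <= p_cutoff)
  }
  domains <- domains %||% assoc$domains
  if (mode == "bipartite") {
    if (is.null(domains)) stop("bipartite mode needs a domain map", call. = FALSE)
    dom <- domains[rownames(r)]
    cross <- outer(dom, dom, "!=")
    keep <- keep & cross
  }
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  if (nrow(idx) == 0) mn_stop("empty_network", "no edge survives the cutoff")
  edges <- data.frame(
    from = rownames(r)[idx[, 1]], to = rownames(r)[idx[, 2]],
    weight = r[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::E(g)$sign <- ifelse(igraph::E(g)$weight >= 0, "positive", "negative")
  if (!is.null(domains))
    igraph::V(g)$domain <- unname(domains[igraph::V(g)$name])
  if (!is.null(abundance))
    igraph::V(g)$abundance <- unname(abundance[igraph::V(g)$name])
  igraph::graph_attr(g, "mode") <- mode
  g
}
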