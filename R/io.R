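# Readers and writers for the plain-text interchange formats: TSV count
# tables, Newick trees, GraphML / edge-list networks, JSON reports.

#' Read an OTU count table from TSV
#'
#' First column holds ids, header row holds the other axis's ids. Cells
#' must be non-negative integers.
#'
#' @param path TSV file path.
#' @param orientation `"taxa_rows"` (default) or `"samples_rows"`; the
#'   returned matrix is always canonical taxa x samples.
#' @return integer count matrix, taxa as rows.
#' @export
read_count_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    mn_stop("duplicate_id", paste0("duplicate row id(s): ",
                                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (anyDuplicated(names(df)[-1]))
    mn_stop("duplicate_id", "duplicate column ids")
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(as.numeric(m))
  bad <- which(!is.finite(num) | num < 0 | num != floor(num))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(m))
    mn_stop("parse_error",
            sprintf("invalid cell at row '%s', column '%s': %s",
                    ids[rc[1]], colnames(m)[rc[2]], m[bad[1]]))
  }
  m <- matrix(as.integer(num), nrow(m), ncol(m),
              dimnames = list(ids, colnames(m)))
  if (orientation == "samples_rows") m <- t(m)
  check_count_table(m)
  m
}

#' Write a count table as TSV
#'
#' @param table taxa x samples count matrix.
#' @param path output path.
#' @param id_column header name of the taxon-id column.
#' @export
write_count_table <- function(table, path, id_column = "taxon") {
  check_count_table(table)
  df <- data.frame(taxon = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted tree from Newick
#'
#' Validates tip-label uniqueness and branch lengths; zero-length branches
#' are replaced by a small epsilon (patristic distances of 0 break
#' downstream clustering).
#'
#' @param path Newick file path.
#' @param zero_length_epsilon replacement for zero-length branches.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path, zero_length_epsilon = 1e-8) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    mn_stop("duplicate_tip",
            paste0("duplicate tip label(s): ",
                   paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                         collapse = ", ")))
  if (is.null(tree$edge.length))
    mn_stop("missing_length", "tree has no branch lengths")
  if (any(tree$edge.length == 0)) {
    warning("replacing zero-length branch(es) with epsilon")
    tree$edge.length[tree$edge.length == 0] <- zero_length_epsilon
  }
  tree
}

#' Write a network to GraphML or a signed edge list
#'
#' GraphML keeps every node attribute (taxonomy, abundance, module, role)
#' and edge attribute (weight, sign); the edge list is a 3-column TSV
#' (source, target, weight).
#'
#' @param network a non-empty igraph graph.
#' @param path output path.
#' @param format `"graphml"` or `"edgelist"`.
#' @export
write_network <- function(network, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (igraph::vcount(network) == 0)
    stop("refusing to write an empty network", call. = FALSE)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(network)
    df <- data.frame(source = el[, 1], target = el[, 2],
                     weight = igraph::E(network)$weight,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return an igraph graph.
#' @export
read_network <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") return(igraph::read_graph(path, format = "graphml"))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  g
}

#' Write an association matrix as a square TSV
#'
#' @param assoc an `assoc_matrix`.
#' @param path output path.
#' @export
write_assoc <- function(assoc, path) {
  df <- data.frame(taxon = rownames(assoc$r), assoc$r, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
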