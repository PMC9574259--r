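# End-to-end pipeline: simulate/load -> filter -> associations -> networks
# -> topology -> stability -> assembly, with a machine-readable run report.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every stage parameter at its
#' default. Override entries via `...` (unknown keys are rejected, so typos
#' fail loudly).
#'
#' @param ... named overrides of default entries.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    out_dir = NULL,
    seed = 1L,
    # input (either simulate, or paths to table/tree/metadata TSV/Newick)
    simulate = TRUE,
    sim = list(),                   # overrides for sim_config()
    table_path = NULL, tree_path = NULL, metadata_path = NULL,
    # stage toggles
    run_network = TRUE, run_topology = TRUE, run_stability = TRUE,
    run_assembly = TRUE,
    # filtering
    prevalence = 0.3,
    # association / threshold
    transform = "relative",
    rmt_grid = seq(0.30, 0.95, by = 0.01),
    fallback_cutoff = 0.6,          # used if the RMT scan fails
    # stability
    removal_fraction = 0.5, n_robustness = 100, n_null_connectedness = 200,
    # topology null
    n_random = 20,
    # assembly
    distance_threshold = 0.2, min_bin_size = 12, n_null_assembly = 200
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(utils::modifyList(cfg, over), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on simulated or file-based input,
#' writes every stage output under `out_dir` as plain text (TSV/JSON/
#' GraphML/Newick) and returns a run report sufficient to reproduce the
#' run. Identical configuration (including seeds) gives byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()] (or a named list of overrides).
#' @return the run report (named list), invisibly also written to
#'   `run_report.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- character(0)
  warn <- character(0)
  note <- function(f) manifest <<- c(manifest, f)

  # --- input stage -------------------------------------------------------
  if (isTRUE(config$simulate)) {
    sc <- do.call(sim_config, utils::modifyList(list(seed = config$seed),
                                                config$sim))
    tree <- simulate_tree(sc$n_taxa, seed = sc$seed)
    sim <- simulate_communities(sc, tree)
    table <- plant_correlation_blocks(sim$table, sim$truth, sc)
    metadata <- sim$metadata
    write_count_table(table, out("counts.tsv")); note("counts.tsv")
    ape::write.tree(tree, out("tree.nwk")); note("tree.nwk")
    utils::write.table(metadata, out("metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE); note("metadata.tsv")
    utils::write.table(sim$taxonomy, out("taxonomy.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE); note("taxonomy.tsv")
    jsonlite::write_json(
      list(block_membership = as.list(sim$truth$block_membership),
           regime_label = as.list(sim$truth$regime_label)),
      out("truth.json"), auto_unbox = TRUE, digits = NA, na = "null")
    note("truth.json")
  } else {
    table <- read_count_table(config$table_path)
    tree <- if (!is.null(config$tree_path)) read_tree(config$tree_path)
    metadata <- utils::read.delim(config$metadata_path,
                                  stringsAsFactors = FALSE)
  }

  # --- filter + associations --------------------------------------------
  filt <- withCallingHandlers(
    prevalence_filter(table, config$prevalence),
    warning = function(w) { warn <<- c(warn, conditionMessage(w))
                            invokeRestart("muffleWarning") })
  assoc <- withCallingHandlers(
    pearson_matrix(filt, transform = config$transform),
    warning = function(w) { warn <<- c(warn, conditionMessage(w))
                            invokeRestart("muffleWarning") })
  write_assoc(assoc, out("association.tsv")); note("association.tsv")

  report <- list(package = "micronet",
                 version = as.character(utils::packageVersion("micronet")),
                 # out_dir is run-specific; dropping it keeps reports from
                 # identical analyses byte-identical
                 config = config[setdiff(names(config),
                                         c("rmt_grid", "out_dir"))],
                 input = list(n_taxa = nrow(table), n_samples = ncol(table),
                              n_taxa_filtered = nrow(filt),
                              checksum = sum(table)))

  if (isTRUE(config$run_network)) {
    scan <- tryCatch(rmt_threshold_scan(assoc, grid = config$rmt_grid),
                     error = function(e) NULL)
    cutoff <- if (is.null(scan)) config$fallback_cutoff else scan$chosen
    if (!is.null(scan)) {
      utils::write.table(scan$scan, out("rmt_scan.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE); note("rmt_scan.tsv")
    } else warn <- c(warn, "RMT scan failed; fallback cutoff used")
    abund <- rowMeans(relative_abundance(filt))
    net <- build_network(assoc, cutoff, mode = "intra", abundance = abund)
    write_network(net, out("network.graphml"), "graphml"); note("network.graphml")
    write_network(net, out("network_edges.tsv"), "edgelist"); note("network_edges.tsv")
    report$network <- list(cutoff = cutoff, n_nodes = igraph::vcount(net),
                           n_edges = igraph::ecount(net))

    if (isTRUE(config$run_topology)) {
      mods <- detect_modules(net, seed = config$seed)
      roles <- suppressWarnings(zi_pi(net, mods$membership))
      utils::write.table(roles, out("node_roles.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE); note("node_roles.tsv")
      gd <- avg_path_length(net)
      pl <- tryCatch(powerlaw_fit(net), micronet_error = function(e) NULL)
      nulls <- random_network_null(net, n_random = config$n_random,
                                   seed = config$seed)
      report$topology <- list(
        n_nodes = igraph::vcount(net), n_edges = igraph::ecount(net),
        avg_degree = mean(igraph::degree(net)),
        powerlaw_r2 = pl$r_squared, powerlaw_exponent = pl$exponent,
        avg_path_length = gd$gd, modularity = mods$modularity,
        n_modules = mods$n_modules,
        role_census = as.list(base::table(roles$role)),
        null_gd = nulls$gd[c("null_mean", "null_sd", "t", "p_value")],
        null_modularity = nulls$modularity[c("null_mean", "null_sd", "t",
                                             "p_value")])
      jsonlite::write_json(report$topology, out("topology.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      note("topology.json")
    }

    if (isTRUE(config$run_stability)) {
      rob <- robustness_simulation(
        net, abund, removal_fraction = config$removal_fraction,
        n_replicates = config$n_robustness, seed = config$seed)
      utils::write.table(
        data.frame(replicate = seq_along(rob$per_replicate),
                   robustness = rob$per_replicate),
        out("robustness.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      note("robustness.tsv")
      conn <- suppressWarnings(
        connectedness(filt, n_null = config$n_null_connectedness,
                      seed = config$seed))
      coh <- cohesion(filt, conn)
      utils::write.table(conn, out("connectedness.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE); note("connectedness.tsv")
      utils::write.table(coh, out("cohesion.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE); note("cohesion.tsv")
      report$stability <- list(
        robustness_mean = rob$mean, robustness_sd = rob$sd,
        positive_cohesion_mean = mean(coh$positive),
        negative_cohesion_mean = mean(coh$negative))
    }
  }

  if (isTRUE(config$run_assembly) && !is.null(tree)) {
    bins <- phylo_bins(tree, filt,
                       distance_threshold = config$distance_threshold,
                       min_bin_size = config$min_bin_size)
    scores <- score_turnovers(filt, tree, bins, metadata,
                              n_null = config$n_null_assembly,
                              seed = config$seed)
    utils::write.table(scores, out("turnovers.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE); note("turnovers.tsv")
    part <- aggregate_processes(scores, bins)
    utils::write.table(part, out("assembly_partition.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("assembly_partition.tsv")
    report$assembly <- list(n_bins = length(bins$bins),
                            partition = part)
  }

  report$warnings <- warn
  report$manifest <- manifest
  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  invisible(report)
}
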