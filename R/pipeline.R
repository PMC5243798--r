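#' Run the end-to-end LGT workflow across a grid of k
#'
#' For every k in `config$k_grid` (with the gap threshold recomputed as
#' `G = 2k`): build the k-mer index, infer lateral segments (IDF + TF
#' filters), map them to genes, consolidate the calls into a directed
#' group-to-group network, reformulate it as an undirected graph, and
#' enumerate its maximal cliques (the genetic exchange communities). With at
#' least two grid points a core-node report across k is added; with a GO map
#' supplied, enrichment of the canonical maximum clique's lateral genes is
#' tested at each k. Reruns on identical inputs produce identical outputs.
#'
#' @param dataset An `lgt_dataset`.
#' @param config An `lgt_config`; `k_grid` drives the run.
#' @param go_map Optional data.frame (`gene_id`, `go_id`) enabling the
#'   enrichment stage.
#' @param out_dir Optional directory; when given, per-k TSV outputs
#'   (segments, lateral genes, network, cliques), the core-node report and a
#'   JSON run manifest are written there.
#' @param verbose Log per-stage counts to the console.
#' @return An `lgt_run`: list with `per_k` (one result list per k:
#'   `segments`, `lateral_genes`, `network`, `graph`, `cliques`,
#'   `clique_table`, optional `enrichment`), `core` (a `core_node_report`
#'   or NULL), `config` and `manifest`.
#' @export
run_pipeline <- function(dataset, config, go_map = NULL, out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(dataset, "lgt_dataset"), inherits(config, "lgt_config"))
  say <- function(...) if (verbose) message(...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  per_k <- list()
  outputs <- character(0)
  for (k in config$k_grid) {
    cfg_k <- lgt_config(
      k = k, G = 2L * k,
      idf_threshold_override = config$idf_threshold_override,
      min_segment_kmers = config$min_segment_kmers,
      min_overlap_kmers = config$min_overlap_kmers,
      fdr = config$fdr, k_grid = config$k_grid,
      min_clique_size = config$min_clique_size,
      min_edge_weight = config$min_edge_weight, seed = config$seed
    )
    say("k = ", k, ": inferring lateral segments")
    segments <- infer_lateral_segments(dataset, cfg_k)
    say("k = ", k, ": ", nrow(segments), " inferred segments")
    lateral_genes <- map_segments_to_genes(segments, dataset, cfg_k)
    say("k = ", k, ": ", nrow(lateral_genes), " lateral-gene calls")
    network <- consolidate(lateral_genes, genome_groups(dataset),
                           cfg_k$min_edge_weight)
    graph <- to_undirected(network)
    cliques <- enumerate_maximal_cliques(graph, cfg_k$min_clique_size)
    clique_table <- clique_gene_totals(cliques, network)
    say("k = ", k, ": ", length(cliques$cliques), " maximal cliques")

    enrichment <- NULL
    if (!is.null(go_map) && any(cliques$is_canonical_maximum) &&
        nrow(lateral_genes)) {
      members <- cliques$cliques[[which(cliques$is_canonical_maximum)]]
      rec_grp <- genome_groups(dataset)[lateral_genes$genome_id]
      in_clique <- lateral_genes$donor_group %in% members &
        rec_grp %in% members
      test <- unique(lateral_genes$gene_id[in_clique])
      if (length(test)) {
        enrichment <- enrich_clique(test, unique(dataset$genes$gene_id),
                                    go_map, cfg_k$fdr)
      }
    }

    res <- list(k = k, config = cfg_k, segments = segments,
                lateral_genes = lateral_genes, network = network,
                graph = graph, cliques = cliques,
                clique_table = clique_table, enrichment = enrichment)
    per_k[[as.character(k)]] <- res

    if (!is.null(out_dir)) {
      p <- function(stem) file.path(out_dir, sprintf("%s_k%d.tsv", stem, k))
      write_segments(segments, p("segments"))
      write_lateral_genes(lateral_genes, p("lateral_genes"))
      write_network(network, p("network"))
      write_clique_report(clique_table, p("cliques"))
      outputs <- c(outputs, p("segments"), p("lateral_genes"),
                   p("network"), p("cliques"))
      if (!is.null(enrichment)) {
        write_enrichment(enrichment, p("enrichment"))
        outputs <- c(outputs, p("enrichment"))
      }
    }
  }

  core <- NULL
  if (length(per_k) >= 2L) {
    core <- find_core_nodes(lapply(per_k, `[[`, "cliques"))
    if (!is.null(out_dir)) {
      core_path <- file.path(out_dir, "core_nodes.tsv")
      write_core_report(core, core_path)
      outputs <- c(outputs, core_path)
    }
  } else {
    warning("k grid has a single value; core-node stage skipped")
  }

  manifest <- list(
    tool = "lgtnet",
    version = as.character(utils::packageVersion("lgtnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    n_genomes = length(dataset$sequences),
    n_groups = length(unique(dataset$groups)),
    k_grid = config$k_grid,
    per_k_counts = lapply(per_k, function(r) {
      list(segments = nrow(r$segments),
           lateral_genes = nrow(r$lateral_genes),
           edges = nrow(r$network$edges),
           maximal_cliques = length(r$cliques$cliques))
    }),
    outputs = outputs
  )
  if (!is.null(out_dir)) {
    manifest$output_checksums <- as.list(tools::md5sum(outputs))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(per_k = per_k, core = core, config = config,
                 manifest = manifest),
            class = "lgt_run")
}

#' @export
print.lgt_run <- function(x, ...) {
  cat("LGT pipeline run over k in {",
      paste(names(x$per_k), collapse = ", "), "}\n")
  for (k in names(x$per_k)) {
    r <- x$per_k[[k]]
    cat(sprintf("  k=%s: %d segments, %d lateral genes, %d edges, %d cliques\n",
                k, nrow(r$segments), nrow(r$lateral_genes),
                nrow(r$network$edges), length(r$cliques$cliques)))
  }
  if (!is.null(x$core)) {
    cat("  core nodes:",
        if (length(x$core$core_nodes)) {
          paste(x$core$core_nodes, collapse = ", ")
        } else "none", "\n")
  }
  invisible(x)
}
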