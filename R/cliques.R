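#' Enumerate maximal and maximum cliques (genetic exchange communities)
#'
#' A genetic exchange community (GEC) is operationalised as a clique of the
#' undirected LGT graph: a set of groups each pair of which is directly
#' linked by inferred transfer. All maximal cliques with at least `min_size`
#' vertices are enumerated exactly (recursive pivoting of the Bron--Kerbosch
#' family, via igraph); those of greatest cardinality are flagged as maximum
#' cliques, and the lexicographically first maximum clique is additionally
#' marked canonical for reproducible reporting.
#'
#' @param graph An `undirected_lgt_graph` (see [to_undirected()]).
#' @param min_size Smallest clique reported (default 3).
#' @return A `clique_set`: list with `cliques` (list of sorted character
#'   vectors, ordered by size descending then lexicographically), `sizes`,
#'   `is_maximum`, `is_canonical_maximum`, `min_size` and `nodes`.
#' @export
enumerate_maximal_cliques <- function(graph, min_size = 3L) {
  stopifnot(inherits(graph, "undirected_lgt_graph"), min_size >= 1L)
  g <- as_igraph(graph)
  raw <- igraph::max_cliques(g, min = min_size)
  cliques <- lapply(raw, function(v) sort(names(v)))
  if (length(cliques)) {
    keystr <- vapply(cliques, paste, character(1), collapse = ";")
    sizes <- lengths(cliques)
    ord <- order(-sizes, keystr)
    cliques <- cliques[ord]
    sizes <- sizes[ord]
  } else {
    sizes <- integer(0)
  }
  max_size <- if (length(sizes)) max(sizes) else 0L
  is_maximum <- sizes == max_size & length(sizes) > 0L
  is_canonical <- rep(FALSE, length(sizes))
  if (any(is_maximum)) is_canonical[which(is_maximum)[1L]] <- TRUE
  structure(
    list(cliques = cliques, sizes = as.integer(sizes),
         is_maximum = is_maximum, is_canonical_maximum = is_canonical,
         min_size = as.integer(min_size), nodes = graph$nodes),
    class = "clique_set"
  )
}

#' @export
print.clique_set <- function(x, ...) {
  cat("Clique set:", length(x$cliques), "maximal cliques (>=",
      x$min_size, "vertices)")
  if (length(x$cliques)) {
    cat("; maximum size", max(x$sizes))
  }
  cat("\n")
  invisible(x)
}

#' Lateral-gene totals per clique
#'
#' For each clique, sums the weights of the directed edges of the LGT
#' network having both endpoints inside the clique — the number of lateral
#' genes exchanged within the community — and expresses it as a percentage
#' of the network-wide total (to 0.1%).
#'
#' @param clique_set A `clique_set`.
#' @param network The directed `lgt_network` the graph was derived from.
#' @return data.frame with one row per clique: `clique_id`, `size`,
#'   `is_maximum`, `members` (semicolon-joined), `lateral_gene_total`,
#'   `proportion_percent`; attribute `"network_total"` holds the
#'   network-wide weight sum.
#' @export
clique_gene_totals <- function(clique_set, network) {
  stopifnot(inherits(clique_set, "clique_set"),
            inherits(network, "lgt_network"))
  extra <- setdiff(unlist(clique_set$cliques), network$nodes)
  if (length(extra)) stop("clique node not in network: ", extra[1L])
  e <- network$edges
  network_total <- sum(e$weight)
  n <- length(clique_set$cliques)
  totals <- integer(n)
  for (i in seq_len(n)) {
    members <- clique_set$cliques[[i]]
    inside <- e$donor_group %in% members & e$recipient_group %in% members
    totals[i] <- sum(e$weight[inside])
  }
  out <- data.frame(
    clique_id = if (n) sprintf("clique_%03d", seq_len(n)) else character(),
    size = clique_set$sizes,
    is_maximum = clique_set$is_maximum,
    members = vapply(clique_set$cliques, paste, character(1),
                     collapse = ";"),
    lateral_gene_total = totals,
    proportion_percent = if (network_total > 0) {
      round(100 * totals / network_total, 1)
    } else {
      rep(NA_real_, n)
    },
    stringsAsFactors = FALSE
  )
  attr(out, "network_total") <- network_total
  out
}

#' Core nodes across a grid of word lengths k
#'
#' A group is a *core node* when it belongs to at least one reported maximal
#' clique at every examined value of k — i.e. its community membership is
#' robust to the choice of word length. The stricter variant requiring
#' membership in a maximum clique at every k is reported alongside.
#'
#' @param per_k_clique_sets Named list of `clique_set` objects, one per k
#'   (names are the k values); at least two entries.
#' @return A `core_node_report`: list with `table` (data.frame `node`,
#'   `k_values` present, `n_k`, `is_core`, `is_core_maximum`), `core_nodes`,
#'   `core_nodes_maximum` and `k_grid`.
#' @export
find_core_nodes <- function(per_k_clique_sets) {
  if (length(per_k_clique_sets) < 2L) {
    stop("core-node identification requires clique sets for >= 2 values of k")
  }
  stopifnot(all(vapply(per_k_clique_sets, inherits, logical(1),
                       "clique_set")))
  ks <- names(per_k_clique_sets)
  if (is.null(ks) || any(!nzchar(ks))) {
    stop("per-k clique sets must be named by their k value")
  }
  member_at_k <- lapply(per_k_clique_sets, function(cs) {
    unique(unlist(cs$cliques))
  })
  max_at_k <- lapply(per_k_clique_sets, function(cs) {
    unique(unlist(cs$cliques[cs$is_maximum]))
  })
  all_nodes <- sort(unique(unlist(member_at_k)))
  tab <- data.frame(
    node = all_nodes,
    k_values = vapply(all_nodes, function(nd) {
      paste(ks[vapply(member_at_k, function(m) nd %in% m, logical(1))],
            collapse = ",")
    }, character(1)),
    n_k = vapply(all_nodes, function(nd) {
      sum(vapply(member_at_k, function(m) nd %in% m, logical(1)))
    }, integer(1)),
    is_core = vapply(all_nodes, function(nd) {
      all(vapply(member_at_k, function(m) nd %in% m, logical(1)))
    }, logical(1)),
    is_core_maximum = vapply(all_nodes, function(nd) {
      all(vapply(max_at_k, function(m) nd %in% m, logical(1)))
    }, logical(1)),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(
    list(table = tab,
         core_nodes = tab$node[tab$is_core],
         core_nodes_maximum = tab$node[tab$is_core_maximum],
         k_grid = ks),
    class = "core_node_report"
  )
}

#' @export
print.core_node_report <- function(x, ...) {
  cat("Core-node report over k in {", paste(x$k_grid, collapse = ", "),
      "}\n")
  cat("  core nodes (any maximal clique at every k):",
      if (length(x$core_nodes)) paste(x$core_nodes, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Write clique and core-node reports
#'
#' @param clique_table data.frame from [clique_gene_totals()].
#' @param report A `core_node_report`.
#' @param path Output TSV path.
#' @export
write_clique_report <- function(clique_table, path) {
  utils::write.table(clique_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_clique_report
#' @export
write_core_report <- function(report, path) {
  stopifnot(inherits(report, "core_node_report"))
  utils::write.table(report$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
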