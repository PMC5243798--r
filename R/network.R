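new_lgt_network <- function(edges, nodes) {
  edges <- edges[order(edges$donor_group, edges$recipient_group), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(nodes)), edges = edges),
            class = "lgt_network")
}

#' Consolidate lateral-gene calls into a group-to-group LGT network
#'
#' Each recipient genome is subsumed into its group, and all lateral-gene
#' calls from a donor group into genomes of a recipient group are merged
#' into a single directed edge whose integer weight is the number of calls.
#' The sum of the edge weights therefore equals the number of lateral-gene
#' calls. Groups with no incident edges are retained as isolated nodes so
#' that the report can distinguish groups uninvolved in LGT.
#'
#' @param lateral_genes data.frame from [map_segments_to_genes()].
#' @param groups Named character vector genome id -> group id (see
#'   [genome_groups()]).
#' @param min_edge_weight Minimum weight an edge must reach to be kept
#'   (default 1, i.e. no pruning).
#' @return An `lgt_network`: list with `nodes` (all group ids) and `edges`
#'   (data.frame `donor_group`, `recipient_group`, `weight`, sorted by donor
#'   then recipient).
#' @export
consolidate <- function(lateral_genes, groups, min_edge_weight = 1L) {
  nodes <- sort(unique(unname(groups)))
  if (!nrow(lateral_genes)) {
    return(new_lgt_network(
      data.frame(donor_group = character(), recipient_group = character(),
                 weight = integer(), stringsAsFactors = FALSE),
      nodes))
  }
  unknown <- setdiff(lateral_genes$genome_id, names(groups))
  if (length(unknown)) {
    stop("lateral gene references unknown genome: ", unknown[1L])
  }
  recipient_group <- unname(groups[lateral_genes$genome_id])
  if (any(lateral_genes$donor_group == recipient_group)) {
    stop("lateral gene with donor group equal to its recipient's group")
  }
  agg <- stats::aggregate(
    list(weight = rep(1L, nrow(lateral_genes))),
    by = list(donor_group = lateral_genes$donor_group,
              recipient_group = recipient_group),
    FUN = sum
  )
  agg$weight <- as.integer(agg$weight)
  agg <- agg[agg$weight >= min_edge_weight, , drop = FALSE]
  new_lgt_network(agg, unique(c(nodes, agg$donor_group,
                                agg$recipient_group)))
}

#' Reformulate the directed LGT network as an undirected simple graph
#'
#' Drops weights and arrowheads: an undirected edge \{A, B\} is present iff
#' at least one of the directed edges A->B or B->A exists. The result is the
#' input to clique (genetic exchange community) analysis, which operates on
#' undirected, unweighted graphs.
#'
#' @param network An `lgt_network`.
#' @return An `undirected_lgt_graph`: list with `nodes` and `edges`
#'   (data.frame `node1`, `node2`, `node1 < node2`, unique rows).
#' @export
to_undirected <- function(network) {
  stopifnot(inherits(network, "lgt_network"))
  e <- network$edges
  if (nrow(e)) {
    n1 <- pmin(e$donor_group, e$recipient_group)
    n2 <- pmax(e$donor_group, e$recipient_group)
    und <- unique(data.frame(node1 = n1, node2 = n2,
                             stringsAsFactors = FALSE))
    und <- und[order(und$node1, und$node2), , drop = FALSE]
    rownames(und) <- NULL
  } else {
    und <- data.frame(node1 = character(), node2 = character(),
                      stringsAsFactors = FALSE)
  }
  structure(list(nodes = network$nodes, edges = und),
            class = "undirected_lgt_graph")
}

# igraph views of the two network classes
as_igraph <- function(x) {
  if (inherits(x, "lgt_network")) {
    g <- igraph::graph_from_data_frame(
      x$edges[, c("donor_group", "recipient_group", "weight")],
      directed = TRUE, vertices = data.frame(name = x$nodes))
  } else if (inherits(x, "undirected_lgt_graph")) {
    g <- igraph::graph_from_data_frame(
      x$edges, directed = FALSE, vertices = data.frame(name = x$nodes))
  } else {
    stop("not a network object")
  }
  g
}

#' @export
print.lgt_network <- function(x, ...) {
  cat("Directed LGT network:", length(x$nodes), "groups,",
      nrow(x$edges), "edges, total weight", sum(x$edges$weight), "\n")
  invisible(x)
}

#' @export
print.undirected_lgt_graph <- function(x, ...) {
  cat("Undirected LGT graph:", length(x$nodes), "groups,",
      nrow(x$edges), "edges\n")
  invisible(x)
}
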