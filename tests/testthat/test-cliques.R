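und_graph <- function(nodes, edges) {
  structure(list(
    nodes = nodes,
    edges = data.frame(node1 = edges[[1]], node2 = edges[[2]],
                       stringsAsFactors = FALSE)),
    class = "undirected_lgt_graph")
}

test_that("a triangle is one maximal clique and also the maximum", {
  g <- und_graph(c("a", "b", "c"),
                 list(c("a", "a", "b"), c("b", "c", "c")))
  cs <- enumerate_maximal_cliques(g)
  expect_identical(length(cs$cliques), 1L)
  expect_identical(cs$cliques[[1]], c("a", "b", "c"))
  expect_true(cs$is_maximum)
  expect_true(cs$is_canonical_maximum)
})

test_that("a complete graph K5 is a single maximal clique of size 5", {
  nodes <- letters[1:5]
  pairs <- utils::combn(nodes, 2)
  g <- und_graph(nodes, list(pairs[1, ], pairs[2, ]))
  cs <- enumerate_maximal_cliques(g)
  expect_identical(length(cs$cliques), 1L)
  expect_identical(cs$sizes, 5L)
})

test_that("an empty graph yields an empty clique set", {
  g <- und_graph(c("a", "b"), list(character(0), character(0)))
  cs <- enumerate_maximal_cliques(g)
  expect_identical(length(cs$cliques), 0L)
})

test_that("enumeration matches the exhaustive subset oracle on a fixed
           12-node random graph", {
  withr::local_seed(71)
  g <- random_graph(12L, 0.5)
  cs <- enumerate_maximal_cliques(g, min_size = 3L)
  expect_identical(clique_set_keys(cs),
                   brute_force_maximal_cliques(g$nodes, g$edges, 3L))
})

test_that("enumeration matches the oracle across random graphs and reported
           cliques are complete and maximal", {
  withr::local_seed(72)
  for (rep in 1:30) {
    n <- sample(4:15, 1)
    g <- random_graph(n, stats::runif(1, 0.2, 0.8))
    min_size <- sample(2:3, 1)
    cs <- enumerate_maximal_cliques(g, min_size = min_size)
    expect_identical(clique_set_keys(cs),
                     brute_force_maximal_cliques(g$nodes, g$edges, min_size))
    # completeness: every pair adjacent
    ekey <- paste(g$edges$node1, g$edges$node2)
    for (cl in cs$cliques) {
      if (length(cl) < 2) next
      pr <- utils::combn(cl, 2)
      expect_true(all(paste(pmin(pr[1, ], pr[2, ]),
                            pmax(pr[1, ], pr[2, ])) %in% ekey))
    }
    # maximum flags agree with the size maximum
    if (length(cs$cliques)) {
      expect_identical(cs$is_maximum, cs$sizes == max(cs$sizes))
      expect_identical(sum(cs$is_canonical_maximum), 1L)
    }
  }
})

test_that("clique gene totals and proportions follow the toy arithmetic", {
  edges <- data.frame(donor_group = c("A", "B", "A"),
                      recipient_group = c("B", "A", "C"),
                      weight = c(3L, 2L, 5L), stringsAsFactors = FALSE)
  net <- lgtnet:::new_lgt_network(edges, c("A", "B", "C"))
  cs <- structure(list(cliques = list(c("A", "B")), sizes = 2L,
                       is_maximum = TRUE, is_canonical_maximum = TRUE,
                       min_size = 2L, nodes = net$nodes),
                  class = "clique_set")
  tab <- clique_gene_totals(cs, net)
  expect_identical(tab$lateral_gene_total, 5L)
  expect_identical(attr(tab, "network_total"), 10L)
  expect_identical(tab$proportion_percent, 50.0)

  cs_all <- structure(list(cliques = list(c("A", "B", "C")), sizes = 3L,
                           is_maximum = TRUE, is_canonical_maximum = TRUE,
                           min_size = 3L, nodes = net$nodes),
                      class = "clique_set")
  expect_identical(clique_gene_totals(cs_all, net)$proportion_percent, 100.0)

  cs_none <- structure(list(cliques = list(), sizes = integer(0),
                            is_maximum = logical(0),
                            is_canonical_maximum = logical(0),
                            min_size = 3L, nodes = net$nodes),
                       class = "clique_set")
  tab0 <- clique_gene_totals(cs_none, net)
  expect_identical(nrow(tab0), 0L)
  expect_identical(attr(tab0, "network_total"), 10L)
})

test_that("clique totals never exceed the network total on simulated data", {
  sc <- small_scenario()
  net <- consolidate(sc$lateral_genes, genome_groups(sc$sim$dataset))
  cs <- enumerate_maximal_cliques(to_undirected(net), min_size = 2L)
  tab <- clique_gene_totals(cs, net)
  expect_true(all(tab$lateral_gene_total <= attr(tab, "network_total")))
  expect_true(all(tab$proportion_percent >= 0 &
                    tab$proportion_percent <= 100))
})

test_that("core nodes are the intersection of per-k clique membership", {
  mk <- function(cliques) {
    sizes <- lengths(cliques)
    structure(list(cliques = cliques, sizes = sizes,
                   is_maximum = sizes == max(sizes),
                   is_canonical_maximum = seq_along(sizes) ==
                     which.max(sizes),
                   min_size = 3L, nodes = letters[1:6]),
              class = "clique_set")
  }
  per_k <- list(
    "20" = mk(list(c("a", "b", "c"), c("c", "d", "e"))),
    "30" = mk(list(c("a", "b", "c", "d"))),
    "40" = mk(list(c("a", "c", "f")))
  )
  rep <- find_core_nodes(per_k)
  expect_identical(rep$core_nodes, c("a", "c"))
  tab <- rep$table
  expect_identical(tab$k_values[tab$node == "d"], "20,30")
  expect_false(tab$is_core[tab$node == "f"])
  # node in the maximum clique at every k is core under both variants
  expect_true(tab$is_core_maximum[tab$node == "a"])
  expect_error(find_core_nodes(per_k[1]), ">= 2")
})
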