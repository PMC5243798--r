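test_that("a minimal well-formed FASTA + group table round-trips", {
  paths <- write_fixture_files(c(g1 = "ACGT"), c(g1 = "A"))
  ds <- read_genomes(paths[["fasta"]], paths[["groups"]])
  expect_s3_class(ds, "lgt_dataset")
  expect_identical(genome_ids(ds), "g1")
  expect_identical(unname(genome_groups(ds)["g1"]), "A")
  expect_identical(length(unique(genome_groups(ds))), 1L)
})

test_that("lowercase bases are upcased and bad alphabets rejected", {
  paths <- write_fixture_files(c(g1 = "acgtn"), c(g1 = "A"))
  ds <- read_genomes(paths[["fasta"]], paths[["groups"]])
  expect_identical(unname(ds$sequences["g1"]), "ACGTN")
  expect_error(make_dataset(c(g1 = "ACGU"), c(g1 = "A")), "A,C,G,T,N")
})

test_that("referential integrity between FASTA and group table is enforced", {
  paths <- write_fixture_files(c(g1 = "ACGT"), c(g1 = "A", ghost = "B"))
  expect_error(read_genomes(paths[["fasta"]], paths[["groups"]]), "ghost")

  paths2 <- write_fixture_files(c(g1 = "ACGT", g2 = "ACGT"), c(g1 = "A"))
  expect_error(read_genomes(paths2[["fasta"]], paths2[["groups"]]), "g2")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tgroup_id", "g1\tA", "g1\tB"), dup)
  expect_error(read_group_table(dup), "more than one group")
})

test_that("gene coordinates outside the genome are rejected on read", {
  genes <- data.frame(genome_id = "g1", gene_id = "gene1",
                      start = 10L, end = 50L, strand = "+",
                      stringsAsFactors = FALSE)
  paths <- write_fixture_files(c(g1 = strrep("ACGT", 10)), c(g1 = "A"),
                               genes = genes)
  expect_error(
    read_genomes(paths[["fasta"]], paths[["groups"]], paths[["gff3"]]),
    "coordinates")
})

test_that("GFF3 1-based coordinates convert to 0-based half-open", {
  genes <- data.frame(genome_id = "g1", gene_id = "gene1",
                      start = 4L, end = 12L, strand = "+",
                      stringsAsFactors = FALSE)
  paths <- write_fixture_files(c(g1 = strrep("ACGT", 10)), c(g1 = "A"),
                               genes = genes)
  ds <- read_genomes(paths[["fasta"]], paths[["groups"]], paths[["gff3"]])
  expect_identical(ds$genes$start, 4L)
  expect_identical(ds$genes$end, 12L)
})

test_that("group table write/read is an identity on its content", {
  groups <- c(g1 = "A", g2 = "B", g3 = "A")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_group_table(groups, path)
  expect_identical(read_group_table(path), groups)
})

test_that("network TSV serialisation is deterministic and round-trips", {
  lg <- data.frame(genome_id = "b1", gene_id = "x", donor_group = "A",
                   overlap_kmers = 5L, segment_start = 0L,
                   segment_end = 100L, stringsAsFactors = FALSE)
  net1 <- consolidate(lg[rep(1, 5), ], c(b1 = "B", a1 = "A"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net1, path)
  expect_identical(readLines(path),
                   c("donor_group\trecipient_group\tweight", "A\tB\t5"))

  empty <- consolidate(lg[0, ], c(b1 = "B", a1 = "A"))
  write_network(empty, path)
  expect_identical(readLines(path),
                   "donor_group\trecipient_group\tweight")

  edges <- data.frame(
    donor_group = c("A", "B", "C"), recipient_group = c("B", "C", "A"),
    weight = c(3L, 1L, 7L), stringsAsFactors = FALSE)
  net3 <- lgtnet:::new_lgt_network(edges, c("A", "B", "C"))
  write_network(net3, path)
  back <- read_network(path)
  expect_identical(back$edges, net3$edges)
  expect_identical(back$nodes, net3$nodes)
})

test_that("GraphML export preserves direction and weight", {
  edges <- data.frame(donor_group = c("A", "B"), recipient_group = c("B", "A"),
                      weight = c(2L, 7L), stringsAsFactors = FALSE)
  net <- lgtnet:::new_lgt_network(edges, c("A", "B", "C"))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, path, format = "graphml")
  g <- igraph::read_graph(path, format = "graphml")
  expect_true(igraph::is_directed(g))
  expect_equal(igraph::vcount(g), 3)
  el <- igraph::as_data_frame(g)
  el <- el[order(el$from), ]
  expect_identical(el$from, c("A", "B"))
  expect_identical(el$to, c("B", "A"))
  expect_identical(as.integer(el$weight), c(2L, 7L))
})

test_that("GO map reader validates term identifiers", {
  ok <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tgo_id", "g1\tGO:0006414", "g1\tGO:0032196"), ok)
  gm <- read_go_map(ok)
  expect_identical(nrow(gm), 2L)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tgo_id", "g1\tGO:xyz"), bad)
  expect_error(read_go_map(bad), "GO:xyz")
})

test_that("randomly generated valid annotations always satisfy the
           coordinate invariant after a file round trip", {
  withr::local_seed(42)
  for (rep in 1:5) {
    L <- sample(200:400, 1)
    seqs <- c(g1 = random_dna(L))
    n_genes <- sample(1:6, 1)
    starts <- sort(sample(0:(L - 20L), n_genes))
    ends <- pmin(L, starts + sample(10:50, n_genes, replace = TRUE))
    genes <- data.frame(genome_id = "g1",
                        gene_id = sprintf("gene%02d", seq_len(n_genes)),
                        start = starts, end = ends, strand = "+",
                        stringsAsFactors = FALSE)
    paths <- write_fixture_files(seqs, c(g1 = "A"), genes = genes)
    ds <- read_genomes(paths[["fasta"]], paths[["groups"]], paths[["gff3"]])
    g <- ds$genes
    expect_true(all(g$start >= 0L & g$start < g$end &
                      g$end <= nchar(seqs[["g1"]])))
  }
})
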