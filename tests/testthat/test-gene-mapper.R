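seg_row <- function(genome, donor, start, end, k) {
  data.frame(genome_id = genome, donor_group = donor,
             start = start, end = end,
             kmer_span = end - start - k + 1L, status = "inferred",
             segment_mean = 0, background_mean = 1,
             stringsAsFactors = FALSE)
}

mapper_dataset <- function(L, genes) {
  withr::with_seed(51, make_dataset(
    stats::setNames(c(random_dna(L), random_dna(L)), c("r", "d")),
    c(r = "O", d = "D"), genes))
}

test_that("a segment wholly inside a gene calls it with the full span as
           overlap (containment case)", {
  k <- 25L
  genes <- data.frame(genome_id = "r", gene_id = "geneA",
                      start = 100L, end = 1000L, strand = "+",
                      stringsAsFactors = FALSE)
  ds <- mapper_dataset(2000L, genes)
  seg <- seg_row("r", "D", 200L, 824L, k)   # kmer_span 600
  cfg <- lgt_config(k = k, min_segment_kmers = 500, min_overlap_kmers = 100)
  lg <- map_segments_to_genes(seg, ds, cfg)
  expect_identical(nrow(lg), 1L)
  expect_identical(lg$gene_id, "geneA")
  expect_identical(lg$overlap_kmers, 600L)
  expect_identical(lg$donor_group, "D")
})

test_that("a long segment with too few in-gene k-mer starts is not called", {
  k <- 25L
  genes <- data.frame(genome_id = "r", gene_id = "geneB",
                      start = 750L, end = 900L, strand = "+",
                      stringsAsFactors = FALSE)
  ds <- mapper_dataset(2000L, genes)
  seg <- seg_row("r", "D", 200L, 824L, k)   # span 600
  # in-gene starts: p in [750, 875] intersect [200, 799] -> 750..799 = 50
  cfg <- lgt_config(k = k, min_segment_kmers = 500, min_overlap_kmers = 100)
  expect_identical(nrow(map_segments_to_genes(seg, ds, cfg)), 0L)
  cfg50 <- lgt_config(k = k, min_segment_kmers = 500, min_overlap_kmers = 50)
  expect_identical(map_segments_to_genes(seg, ds, cfg50)$overlap_kmers, 50L)
})

test_that("one segment straddling two adjacent genes calls both", {
  k <- 10L
  genes <- data.frame(genome_id = "r", gene_id = c("geneA", "geneB"),
                      start = c(0L, 160L), end = c(160L, 320L),
                      strand = "+", stringsAsFactors = FALSE)
  ds <- mapper_dataset(400L, genes)
  seg <- seg_row("r", "D", 0L, 309L, k)     # span 300, starts 0..299
  cfg <- lgt_config(k = k, min_segment_kmers = 10, min_overlap_kmers = 10)
  lg <- map_segments_to_genes(seg, ds, cfg)
  expect_identical(lg$gene_id, c("geneA", "geneB"))
  # geneA: p in [0, 150] -> 151; geneB: p in [160, 299] -> 140
  expect_identical(lg$overlap_kmers, c(151L, 140L))
  expect_identical(lg$segment_start, c(0L, 0L))
})

test_that("segments below the segment-span threshold never call genes", {
  k <- 10L
  genes <- data.frame(genome_id = "r", gene_id = "geneA",
                      start = 0L, end = 300L, strand = "+",
                      stringsAsFactors = FALSE)
  ds <- mapper_dataset(400L, genes)
  seg <- seg_row("r", "D", 0L, 59L, k)      # span 50
  cfg <- lgt_config(k = k, min_segment_kmers = 100, min_overlap_kmers = 1)
  expect_identical(nrow(map_segments_to_genes(seg, ds, cfg)), 0L)
})

test_that("calls are non-increasing in both thresholds and (1,1) calls every
           gene intersected by a full k-mer", {
  sc <- small_scenario()
  counts <- sapply(c(1, 5, 20, 100, 1000), function(thr) {
    cfg <- lgt_config(k = sc$cfg$k, min_segment_kmers = thr,
                      min_overlap_kmers = 5)
    nrow(map_segments_to_genes(sc$segments, sc$sim$dataset, cfg))
  })
  expect_true(all(diff(counts) <= 0))
  counts2 <- sapply(c(1, 5, 20, 100, 1000), function(thr) {
    cfg <- lgt_config(k = sc$cfg$k, min_segment_kmers = 5,
                      min_overlap_kmers = thr)
    nrow(map_segments_to_genes(sc$segments, sc$sim$dataset, cfg))
  })
  expect_true(all(diff(counts2) <= 0))

  cfg11 <- lgt_config(k = sc$cfg$k, min_segment_kmers = 1,
                      min_overlap_kmers = 1)
  lg <- map_segments_to_genes(sc$segments, sc$sim$dataset, cfg11)
  # expected: every (gene, donor) pair with >= 1 k-mer start fully inside
  seg <- sc$segments
  genes <- sc$sim$dataset$genes
  k <- sc$cfg$k
  expected <- 0L
  for (gi in seq_len(nrow(genes))) {
    for (don in unique(seg$donor_group)) {
      hit <- any(seg$genome_id == genes$genome_id[gi] &
                   seg$donor_group == don &
                   pmin(seg$end - k, genes$end[gi] - k) >=
                     pmax(seg$start, genes$start[gi]))
      expected <- expected + hit
    }
  }
  expect_identical(nrow(lg), as.integer(expected))
})

test_that("every call's supporting segment satisfies both thresholds", {
  sc <- small_scenario()
  lg <- sc$lateral_genes
  expect_true(all(lg$overlap_kmers >= sc$cfg$min_overlap_kmers))
  span <- lg$segment_end - lg$segment_start - sc$cfg$k + 1L
  expect_true(all(span >= sc$cfg$min_segment_kmers))
})

test_that("a segment on an unknown genome is an error", {
  genes <- data.frame(genome_id = "r", gene_id = "geneA", start = 0L,
                      end = 100L, strand = "+", stringsAsFactors = FALSE)
  ds <- mapper_dataset(400L, genes)
  seg <- seg_row("ghost", "D", 0L, 59L, 10L)
  expect_error(map_segments_to_genes(seg, ds, lgt_config(k = 10)),
               "ghost")
})
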