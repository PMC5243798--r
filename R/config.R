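#' Pipeline configuration
#'
#' Bundles the tunable parameters of the LGT inference workflow: the word
#' length `k`, the gap-merging threshold `G` (default `2 * k`), an optional
#' override of the relationship-matrix mean threshold, the two minimum-length
#' thresholds used when mapping segments to genes, the FDR for enrichment
#' tests, and the grid of `k` values examined for core-node stability.
#'
#' @param k Word length in nucleotides. Shared k-mers of this exact length are
#'   the atomic unit of matching.
#' @param G Gap threshold in nucleotides; segments separated by a gap strictly
#'   less than `G` are merged. Defaults to `2 * k`.
#' @param idf_threshold_override Optional numeric. When supplied it replaces
#'   the mean-element threshold of the relationship matrix.
#' @param min_segment_kmers Minimum k-mer span (gaps included) an inferred
#'   segment must have before it can call a gene lateral.
#' @param min_overlap_kmers Minimum number of the segment's k-mer start
#'   positions whose full window lies inside the gene interval.
#' @param fdr False discovery rate for Gene Ontology enrichment (default 0.05).
#' @param k_grid Ordered integer vector of k values for the multi-k run; `G`
#'   is recomputed as `2 * k` at each grid point unless `fixed_G` is TRUE.
#' @param min_clique_size Smallest maximal clique reported (default 3).
#' @param min_edge_weight Minimum directed edge weight retained in the network
#'   (default 1, i.e. no pruning).
#' @param seed Integer seed used by any stochastic step.
#' @return An object of class `lgt_config` (a validated list).
#' @examples
#' cfg <- lgt_config(k = 25)
#' cfg$G  # 50
#' @export
lgt_config <- function(k = 25L,
                       G = 2L * k,
                       idf_threshold_override = NULL,
                       min_segment_kmers = 10L,
                       min_overlap_kmers = 10L,
                       fdr = 0.05,
                       k_grid = k,
                       min_clique_size = 3L,
                       min_edge_weight = 1L,
                       seed = 1L) {
  k <- as.integer(k)
  G <- as.integer(G)
  k_grid <- as.integer(k_grid)
  stopifnot(
    length(k) == 1L, k >= 1L,
    length(G) == 1L, G >= 0L,
    min_segment_kmers >= 1L,
    min_overlap_kmers >= 1L,
    fdr > 0, fdr < 1,
    length(k_grid) >= 1L, all(k_grid >= 1L),
    min_clique_size >= 1L, min_edge_weight >= 1L
  )
  if (!is.null(idf_threshold_override)) {
    stopifnot(is.numeric(idf_threshold_override),
              idf_threshold_override >= 0)
  }
  structure(
    list(
      k = k, G = G,
      idf_threshold_override = idf_threshold_override,
      min_segment_kmers = as.integer(min_segment_kmers),
      min_overlap_kmers = as.integer(min_overlap_kmers),
      fdr = fdr,
      k_grid = sort(unique(k_grid)),
      min_clique_size = as.integer(min_clique_size),
      min_edge_weight = as.integer(min_edge_weight),
      seed = as.integer(seed)
    ),
    class = "lgt_config"
  )
}

#' Dataset-specific mapping-threshold presets
#'
#' Named profiles for the dual minimum-length thresholds used in
#' segment-to-gene mapping. The profiles correspond to datasets of different
#' sequence diversity: closely related genomes support long shared segments
#' (high thresholds), while phyletically broad datasets only retain short
#' ones.
#'
#' @param name One of `"ECS"`, `"EB"`, `"BA"`, `"BAC"`.
#' @return A list with `min_segment_kmers` and `min_overlap_kmers`.
#' @export
threshold_profile <- function(name = c("ECS", "EB", "BA", "BAC")) {
  name <- match.arg(name)
  switch(name,
    ECS = list(min_segment_kmers = 500L, min_overlap_kmers = 100L),
    EB  = list(min_segment_kmers = 100L, min_overlap_kmers = 100L),
    BA  = list(min_segment_kmers = 10L,  min_overlap_kmers = 10L),
    BAC = list(min_segment_kmers = 10L,  min_overlap_kmers = 10L)
  )
}

#' @export
print.lgt_config <- function(x, ...) {
  cat("LGT pipeline configuration\n")
  cat("  k =", x$k, " G =", x$G, "\n")
  cat("  k grid:", paste(x$k_grid, collapse = ", "), "\n")
  cat("  min segment k-mers:", x$min_segment_kmers,
      " min overlap k-mers:", x$min_overlap_kmers, "\n")
  cat("  IDF threshold:",
      if (is.null(x$idf_threshold_override)) "matrix mean" else
        x$idf_threshold_override, "\n")
  cat("  enrichment FDR:", x$fdr, "\n")
  invisible(x)
}
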