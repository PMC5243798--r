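empty_lateral_gene_table <- function() {
  data.frame(genome_id = character(), gene_id = character(),
             donor_group = character(), overlap_kmers = integer(),
             segment_start = integer(), segment_end = integer(),
             stringsAsFactors = FALSE)
}

#' Map inferred lateral segments onto annotated genes
#'
#' A gene is called lateral when it contains, or is overlapped by, at least
#' one inferred lateral segment meeting two distinct minimum-length
#' thresholds: the segment itself must span at least `min_segment_kmers`
#' k-mer start positions (gaps included), and at least `min_overlap_kmers`
#' of the segment's k-mer start positions must have their full k-length
#' window inside the gene interval. Gap positions within a merged segment
#' count toward the overlap. A gene hit by segments from several donor
#' groups yields one call per donor group (direction matters for the
#' network); multiple qualifying segments from the same donor are collapsed
#' to the one with the largest overlap (ties broken by smaller start).
#'
#' @param segments Inferred-segment data.frame
#'   (from [infer_lateral_segments()]).
#' @param dataset The `lgt_dataset` carrying the gene annotations.
#' @param config An `lgt_config` supplying `k`, `min_segment_kmers` and
#'   `min_overlap_kmers`.
#' @return data.frame with one row per (genome, gene, donor group):
#'   `genome_id`, `gene_id`, `donor_group`, `overlap_kmers`,
#'   `segment_start`, `segment_end`; sorted by genome, gene, donor group.
#' @export
map_segments_to_genes <- function(segments, dataset, config) {
  stopifnot(inherits(dataset, "lgt_dataset"), inherits(config, "lgt_config"))
  if (!nrow(segments) || !nrow(dataset$genes)) {
    return(empty_lateral_gene_table())
  }
  unknown <- setdiff(segments$genome_id, genome_ids(dataset))
  if (length(unknown)) {
    stop("segment references unknown genome: ", unknown[1L])
  }
  k <- config$k
  seg <- segments[segments$kmer_span >= config$min_segment_kmers, ,
                  drop = FALSE]
  if (!nrow(seg)) return(empty_lateral_gene_table())

  # all (segment, gene) pairs on the same genome
  pairs <- merge(
    cbind(seg, seg_row = seq_len(nrow(seg))),
    dataset$genes,
    by = "genome_id", suffixes = c("", ".gene")
  )
  if (!nrow(pairs)) return(empty_lateral_gene_table())
  # k-mer start positions p of the segment extent with
  # gene.start <= p and p + k <= gene.end
  lo <- pmax(pairs$start, pairs$start.gene)
  hi <- pmin(pairs$end - k, pairs$end.gene - k)
  overlap <- pmax(0L, hi - lo + 1L)
  pairs$overlap_kmers <- overlap
  pairs <- pairs[overlap >= config$min_overlap_kmers, , drop = FALSE]
  if (!nrow(pairs)) return(empty_lateral_gene_table())

  # one call per (genome, gene, donor group): largest overlap, then smallest
  # segment start
  pairs <- pairs[order(pairs$genome_id, pairs$gene_id, pairs$donor_group,
                       -pairs$overlap_kmers, pairs$start), , drop = FALSE]
  key <- paste(pairs$genome_id, pairs$gene_id, pairs$donor_group, sep = "\r")
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  out <- data.frame(
    genome_id = pairs$genome_id,
    gene_id = pairs$gene_id,
    donor_group = pairs$donor_group,
    overlap_kmers = as.integer(pairs$overlap_kmers),
    segment_start = pairs$start,
    segment_end = pairs$end,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$genome_id, out$gene_id, out$donor_group), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
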