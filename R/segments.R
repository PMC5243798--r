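empty_segment_table <- function() {
  data.frame(genome_id = character(), donor_group = character(),
             start = integer(), end = integer(), kmer_span = integer(),
             status = character(), segment_mean = numeric(),
             background_mean = numeric(), stringsAsFactors = FALSE)[0, ]
}

# Marked k-mer start positions (0-based) of `genome_id` whose canonical k-mer
# occurs in the donor group's presence set.
marked_positions <- function(index, genome_id, donor_group) {
  pk <- index$pos_kmers[[genome_id]]
  if (is.null(pk)) stop("unknown genome: ", genome_id)
  pres <- index$group_presence[[donor_group]]
  if (is.null(pres)) stop("unknown group: ", donor_group)
  hit <- !is.na(pk) & (pk %in% pres)
  which(hit) - 1L
}

#' Call potential lateral segments for one genome / donor group
#'
#' Step C of the TF-IDF procedure. Every k-mer start position of the genome
#' whose canonical k-mer occurs in the donor group's presence set is marked;
#' maximal runs of consecutive marked positions form primitive segments, and
#' two neighbouring segments are merged when the gap between the last marked
#' start of one and the first marked start of the next is strictly less than
#' `G` nucleotides. A segment spans from its first marked k-mer start to the
#' end of its last k-mer; its `kmer_span` counts all k-mer start positions in
#' that extent, intervening gaps included
#' (`kmer_span = end - start - k + 1`).
#'
#' @param index A `kmer_index`.
#' @param genome_id Recipient genome identifier.
#' @param donor_group Donor group identifier (should be IDF-eligible for the
#'   genome; this function does not re-check eligibility).
#' @param G Gap-merging threshold in nucleotides.
#' @return data.frame of segments with `status = "potential"`, sorted by
#'   `start`, pairwise disjoint. Zero rows when no position is marked.
#' @export
call_potential_segments <- function(index, genome_id, donor_group, G) {
  stopifnot(inherits(index, "kmer_index"), G >= 0L)
  pos <- marked_positions(index, genome_id, donor_group)
  if (!length(pos)) return(empty_segment_table())
  k <- index$k
  # runs of consecutive marked starts
  run_start_idx <- which(c(TRUE, diff(pos) > 1L))
  first <- pos[run_start_idx]
  last <- pos[c(run_start_idx[-1L] - 1L, length(pos))]
  # merge runs whose inter-run gap (next first - previous last) < G; runs
  # closer than k overlap in nucleotide space and always coalesce, so the
  # emitted intervals stay pairwise disjoint even for G < k
  if (length(first) > 1L) {
    thr <- max(G, k)
    gap <- first[-1L] - last[-length(last)]
    seg_start_idx <- which(c(TRUE, gap >= thr))  # strict: merge when gap < thr
    merged_first <- first[seg_start_idx]
    merged_last <- last[c(seg_start_idx[-1L] - 1L, length(last))]
    first <- merged_first
    last <- merged_last
  }
  start <- as.integer(first)
  end <- as.integer(last) + k
  data.frame(
    genome_id = genome_id, donor_group = donor_group,
    start = start, end = end,
    kmer_span = end - start - k + 1L,
    status = "potential",
    segment_mean = NA_real_, background_mean = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Apply the TF (own-group rarity) filter to potential segments
#'
#' Step D of the TF-IDF procedure. For each potential segment, the frequency
#' of a k-mer is the number of genomes of the recipient's *own* group that
#' contain it. A segment is accepted as an inferred lateral segment when the
#' mean frequency over the k-mers at its marked start positions is strictly
#' less than the mean frequency over all distinct k-mers of the own group's
#' presence set: ubiquitous (vertically inherited) sequence is thereby
#' rejected, while material present in only one or a few group members
#' passes.
#'
#' @param segments data.frame of potential segments
#'   (from [call_potential_segments()]).
#' @param index The `kmer_index` the segments were called from.
#' @return The accepted rows with `status = "inferred"` and the two means
#'   recorded in `segment_mean` / `background_mean`.
#' @export
apply_tf_filter <- function(segments, index) {
  stopifnot(inherits(index, "kmer_index"))
  if (!nrow(segments)) return(empty_segment_table())
  stopifnot(all(segments$status == "potential"))
  keep <- logical(nrow(segments))
  seg_mean <- bg_mean <- numeric(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    gid <- segments$genome_id[i]
    own <- index$groups[[gid]]
    pk <- index$pos_kmers[[gid]]
    pres <- index$group_presence[[segments$donor_group[i]]]
    # marked positions restricted to the segment extent
    lo <- segments$start[i] + 1L                    # 1-based index into pk
    hi <- segments$end[i] - index$k + 1L
    win <- pk[lo:hi]
    marked <- win[!is.na(win) & (win %in% pres)]
    freq <- index$group_counts[[own]][marked]
    freq[is.na(freq)] <- 0L
    seg_mean[i] <- mean(freq)
    bg_mean[i] <- index$group_bg_mean[[own]]
    keep[i] <- seg_mean[i] < bg_mean[i]
  }
  out <- segments
  out$segment_mean <- seg_mean
  out$background_mean <- bg_mean
  out <- out[keep, , drop = FALSE]
  out$status <- rep("inferred", nrow(out))
  rownames(out) <- NULL
  out
}

#' Infer lateral segments for a whole dataset
#'
#' Composes the four TF-IDF steps: build the k-mer index (step A), the
#' relationship matrix and its mean IDF threshold (step B), call gap-merged
#' potential segments for every (recipient genome, eligible donor group)
#' pair (step C), and keep those passing the TF own-group rarity filter
#' (step D). Deterministic for fixed inputs.
#'
#' @param dataset An `lgt_dataset`.
#' @param config An `lgt_config`; uses `k`, `G` and
#'   `idf_threshold_override`.
#' @param index Optionally a precomputed `kmer_index` for `config$k`.
#' @return data.frame of inferred segments, sorted by genome, donor group,
#'   start, with attribute `"relationship_matrix"` carrying the step-B
#'   matrix.
#' @export
infer_lateral_segments <- function(dataset, config, index = NULL) {
  stopifnot(inherits(dataset, "lgt_dataset"), inherits(config, "lgt_config"))
  if (is.null(index)) index <- build_kmer_index(dataset, config$k)
  stopifnot(index$k == config$k)
  R <- build_relationship_matrix(index, config$idf_threshold_override)
  out <- list()
  for (g in genome_ids(dataset)) {
    for (don in eligible_donor_groups(R, g)) {
      pot <- call_potential_segments(index, g, don, config$G)
      inf <- apply_tf_filter(pot, index)
      if (nrow(inf)) out[[length(out) + 1L]] <- inf
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty_segment_table()
  res <- res[order(res$genome_id, res$donor_group, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "relationship_matrix") <- R
  res
}
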