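#' @importFrom stringi stri_sub stri_reverse stri_detect_fixed
NULL

#' Canonical k-mers of a sequence, by start position
#'
#' Slides a window of length `k` over the sequence and returns, for every
#' start position, the canonical form of the window: the lexicographically
#' smaller of the window and its reverse complement. Matching is thereby
#' strand-insensitive, as genome records are deposited on arbitrary strands.
#' Windows containing an `N` yield `NA` (ambiguity codes cannot match
#' exactly).
#'
#' @param sequence Single upper-case DNA string over \{A,C,G,T,N\}.
#' @param k Word length (>= 1).
#' @return Character vector of length `max(0, nchar(sequence) - k + 1)`;
#'   element `i` is the canonical k-mer starting at 0-based position `i - 1`,
#'   or `NA` if that window contains `N`.
#' @examples
#' canonical_kmers("ACGTACGT", 4)
#' @export
canonical_kmers <- function(sequence, k) {
  L <- nchar(sequence)
  n <- L - k + 1L
  if (n < 1L) return(character(0))
  fwd <- stringi::stri_sub(sequence, from = seq_len(n), length = k)
  rev <- chartr("ACGT", "TGCA", stringi::stri_reverse(fwd))
  out <- ifelse(fwd <= rev, fwd, rev)
  out[stringi::stri_detect_fixed(fwd, "N")] <- NA_character_
  out
}

#' Build the per-genome / per-group k-mer index
#'
#' Step A of the TF-IDF procedure: a dictionary of the distinct canonical
#' k-mers of every genome, together with per-group presence sets (the union
#' over member genomes) and per-group genome-occurrence counts (for each
#' k-mer, the number of member genomes containing it). The occurrence counts
#' drive the TF filter; the presence sets drive segment calling and the
#' relationship matrix.
#'
#' @param dataset An `lgt_dataset` (see [read_genomes()]).
#' @param k Word length in nucleotides.
#' @return A `kmer_index` object: list with elements `k`, `pos_kmers`
#'   (per-genome positional canonical k-mer vector, `NA` at N-containing
#'   windows), `genome_sets` (per-genome distinct k-mers), `group_presence`
#'   (per-group distinct k-mers), `group_counts` (per-group named integer
#'   vector of genome-occurrence counts) and `group_bg_mean` (mean
#'   occurrence count over each group's presence set).
#' @export
build_kmer_index <- function(dataset, k) {
  stopifnot(inherits(dataset, "lgt_dataset"), k >= 1L)
  k <- as.integer(k)
  pos_kmers <- lapply(dataset$sequences, canonical_kmers, k = k)
  genome_sets <- lapply(pos_kmers, function(v) unique(v[!is.na(v)]))

  groups <- dataset$groups
  group_ids <- sort(unique(groups))
  group_presence <- vector("list", length(group_ids))
  group_counts <- vector("list", length(group_ids))
  names(group_presence) <- names(group_counts) <- group_ids
  for (g in group_ids) {
    members <- names(groups)[groups == g]
    all_kmers <- unlist(genome_sets[members], use.names = FALSE)
    if (length(all_kmers)) {
      cnt <- table(all_kmers)
      group_counts[[g]] <- stats::setNames(as.integer(cnt), names(cnt))
      group_presence[[g]] <- names(cnt)
    } else {
      group_counts[[g]] <- stats::setNames(integer(0), character(0))
      group_presence[[g]] <- character(0)
    }
  }
  structure(
    list(
      k = k,
      pos_kmers = pos_kmers,
      genome_sets = genome_sets,
      group_presence = group_presence,
      group_counts = group_counts,
      group_bg_mean = vapply(group_counts, function(x) {
        if (length(x)) mean(x) else NA_real_
      }, numeric(1)),
      groups = groups
    ),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("k-mer index (k =", x$k, "):", length(x$genome_sets), "genomes,",
      length(x$group_presence), "groups\n")
  invisible(x)
}
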