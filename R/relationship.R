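#' Build the genome-by-donor-group relationship matrix
#'
#' Step B of the TF-IDF procedure (the IDF component). For genome *i* and
#' every group *j* other than its own, the raw element counts the distinct
#' canonical k-mers shared between the genome and the group's presence set.
#' Raw counts are normalised by the genome's own distinct-k-mer count, giving
#' entries in \[0, 1\] that are comparable across genomes of different
#' lengths. Own-group cells are undefined (`NA`) and excluded from the mean;
#' the mean of the defined entries is the threshold above which a genome is
#' recognised as possibly carrying k-mers donated by a group.
#'
#' @param index A `kmer_index` from [build_kmer_index()].
#' @param threshold_override Optional numeric replacing the mean threshold.
#' @return A `relationship_matrix` object: list with `r` (numeric matrix,
#'   genomes x groups, `NA` on own-group cells), `threshold`, and `groups`.
#' @export
build_relationship_matrix <- function(index, threshold_override = NULL) {
  stopifnot(inherits(index, "kmer_index"))
  groups <- index$groups
  group_ids <- names(index$group_presence)
  if (length(group_ids) < 2L) {
    stop("LGT inference requires at least two groups")
  }
  genome_ids <- names(index$genome_sets)
  r <- matrix(NA_real_, nrow = length(genome_ids), ncol = length(group_ids),
              dimnames = list(genome_ids, group_ids))
  for (g in genome_ids) {
    own <- groups[[g]]
    set_i <- index$genome_sets[[g]]
    denom <- length(set_i)
    for (grp in group_ids) {
      if (grp == own) next
      r[g, grp] <- if (denom == 0L) 0 else
        sum(set_i %in% index$group_presence[[grp]]) / denom
    }
  }
  threshold <- if (!is.null(threshold_override)) {
    as.numeric(threshold_override)
  } else {
    mean(r, na.rm = TRUE)
  }
  structure(
    list(r = r, threshold = threshold, groups = groups,
         overridden = !is.null(threshold_override)),
    class = "relationship_matrix"
  )
}

#' Donor groups passing the IDF threshold for a genome
#'
#' Returns the groups (other than the genome's own) whose relationship-matrix
#' entry strictly exceeds the threshold, i.e. the groups from which the
#' genome shares unexpectedly many k-mers and may therefore have received
#' lateral material.
#'
#' @param R A `relationship_matrix`.
#' @param genome_id Genome identifier (a row of the matrix).
#' @return Character vector of eligible donor group ids (possibly empty).
#' @export
eligible_donor_groups <- function(R, genome_id) {
  stopifnot(inherits(R, "relationship_matrix"))
  if (!genome_id %in% rownames(R$r)) {
    stop("unknown genome: ", genome_id)
  }
  row <- R$r[genome_id, ]
  names(row)[!is.na(row) & row > R$threshold]
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat("Relationship matrix:", nrow(x$r), "genomes x", ncol(x$r), "groups\n")
  cat("  IDF threshold:", format(x$threshold, digits = 6),
      if (x$overridden) "(override)" else "(matrix mean)", "\n")
  invisible(x)
}
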