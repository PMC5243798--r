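#' @importFrom Biostrings readDNAStringSet writeDNAStringSet DNAStringSet
#' @importFrom utils read.delim write.table
NULL

# Internal container: an lgt_dataset is a list with
#   sequences : named character vector (upper-case, alphabet ACGTN)
#   genes     : data.frame(genome_id, gene_id, start, end, strand)
#               0-based half-open coordinates
#   groups    : named character vector genome_id -> group_id
new_lgt_dataset <- function(sequences, genes, groups) {
  obj <- structure(
    list(sequences = sequences, genes = genes, groups = groups),
    class = "lgt_dataset"
  )
  validate_lgt_dataset(obj)
}

validate_lgt_dataset <- function(x) {
  ids <- names(x$sequences)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every genome must have a non-empty identifier")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate genome identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(nchar(x$sequences) < 1L)) {
    stop("zero-length genome sequence")
  }
  bad <- grepl("[^ACGTN]", x$sequences)
  if (any(bad)) {
    stop("sequence of genome ", ids[which(bad)[1L]],
         " contains characters outside {A,C,G,T,N}")
  }
  missing_grp <- setdiff(ids, names(x$groups))
  if (length(missing_grp)) {
    stop("genomes absent from the group table: ",
         paste(missing_grp, collapse = ", "))
  }
  extra <- setdiff(names(x$groups), ids)
  if (length(extra)) {
    stop("group table references unknown genome(s): ",
         paste(extra, collapse = ", "))
  }
  g <- x$genes
  if (nrow(g)) {
    unknown <- setdiff(g$genome_id, ids)
    if (length(unknown)) {
      stop("gene annotations reference unknown genome(s): ",
           paste(unknown, collapse = ", "))
    }
    len <- nchar(x$sequences)[g$genome_id]
    if (any(g$start < 0L) || any(g$start >= g$end) || any(g$end > len)) {
      i <- which(g$start < 0L | g$start >= g$end | g$end > len)[1L]
      stop("gene ", g$gene_id[i], " on genome ", g$genome_id[i],
           " has coordinates outside [0, genome length)")
    }
    key <- paste(g$genome_id, g$gene_id)
    if (anyDuplicated(key)) {
      stop("duplicate gene identifier within a genome: ",
           key[duplicated(key)][1L])
    }
  }
  x
}

#' Genomes and group labels of a dataset
#'
#' @param x An `lgt_dataset`.
#' @return `genome_ids()`: character vector of genome identifiers.
#'   `genome_groups()`: named character vector mapping genome id to group id.
#' @export
genome_ids <- function(x) names(x$sequences)

#' @rdname genome_ids
#' @export
genome_groups <- function(x) x$groups

#' @export
print.lgt_dataset <- function(x, ...) {
  cat("LGT dataset:", length(x$sequences), "genomes in",
      length(unique(x$groups)), "groups;",
      nrow(x$genes), "annotated genes\n")
  invisible(x)
}

#' Read genomes, gene annotations and group assignments
#'
#' Builds the validated dataset object consumed by the inference pipeline.
#' Sequences are read from a multi-record FASTA file (lower-case bases are
#' upcased; only A, C, G, T and N are accepted), gene intervals from a GFF3
#' file, and the genome-to-group partition from a two-column headered TSV
#' (`genome_id`, `group_id`). GFF3 1-based inclusive coordinates are
#' converted to the 0-based half-open convention used internally.
#'
#' @param fasta_path Path to a (multi-record) FASTA file. Record identifiers
#'   are taken as the first whitespace-delimited token of each header.
#' @param group_table_path Path to the group table TSV.
#' @param annotation_path Optional path to a GFF3 file; records with type
#'   `gene` (or `CDS` when no `gene` records exist) become gene annotations.
#'   `NULL` means no annotations.
#' @return An `lgt_dataset` object.
#' @export
read_genomes <- function(fasta_path, group_table_path,
                         annotation_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  sequences <- toupper(as.character(seqs))
  names(sequences) <- ids

  groups <- read_group_table(group_table_path)

  genes <- if (is.null(annotation_path)) {
    empty_gene_table()
  } else {
    read_gene_annotations(annotation_path)
  }
  new_lgt_dataset(sequences, genes, groups)
}

empty_gene_table <- function() {
  data.frame(genome_id = character(), gene_id = character(),
             start = integer(), end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Read a genome-to-group assignment table
#'
#' @param path Two-column headered TSV with columns `genome_id`, `group_id`.
#' @return Named character vector mapping genome id to group id.
#' @export
read_group_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("genome_id", "group_id") %in% names(tab))) {
    stop("group table must have columns genome_id and group_id")
  }
  if (anyDuplicated(tab$genome_id)) {
    stop("genome assigned to more than one group: ",
         tab$genome_id[duplicated(tab$genome_id)][1L])
  }
  stats::setNames(tab$group_id, tab$genome_id)
}

#' Write a genome-to-group assignment table
#'
#' @param groups Named character vector genome id -> group id.
#' @param path Output TSV path.
#' @export
write_group_table <- function(groups, path) {
  tab <- data.frame(genome_id = names(groups), group_id = unname(groups),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_gene_annotations <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  types <- as.character(gr$type)
  keep <- types == "gene"
  if (!any(keep)) keep <- types == "CDS"
  gr <- gr[keep]
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    alt <- gr$Name
    ids <- ifelse(is.na(ids) | !nzchar(ids),
                  ifelse(is.null(alt) | is.na(alt), NA_character_, alt), ids)
  }
  if (is.null(ids) || anyNA(ids)) {
    stop("GFF3 gene records must carry an ID (or Name) attribute")
  }
  data.frame(
    genome_id = as.character(GenomicRanges::seqnames(gr)),
    gene_id = as.character(ids),
    start = GenomicRanges::start(gr) - 1L,  # 1-based incl -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = sub("\\*", "+", as.character(GenomicRanges::strand(gr))),
    stringsAsFactors = FALSE
  )
}

#' Read a gene-to-GO annotation map
#'
#' @param path Headered TSV with columns `gene_id` and `go_id`; one row per
#'   (gene, term) pair. Term identifiers must look like `GO:0006414`.
#' @return data.frame with columns `gene_id`, `go_id`.
#' @export
read_go_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("gene_id", "go_id") %in% names(tab))) {
    stop("GO map must have columns gene_id and go_id")
  }
  bad <- !grepl("^GO:\\d{7}$", tab$go_id)
  if (any(bad)) {
    stop("malformed GO term identifier: ", tab$go_id[which(bad)[1L]])
  }
  unique(tab[, c("gene_id", "go_id")])
}

#' Write / read an LGT network
#'
#' The directed, integer-weighted group-to-group network is serialised either
#' as an edge-list TSV (columns `donor_group`, `recipient_group`, `weight`,
#' rows sorted by donor then recipient) or as GraphML with direction and a
#' `weight` edge attribute preserved.
#'
#' @param network An `lgt_network` object (see [consolidate()]).
#' @param path Output path.
#' @param format `"tsv"` (edge list) or `"graphml"`.
#' @return `path`, invisibly; `read_network()` returns an `lgt_network`.
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "lgt_network"))
  if (format == "tsv") {
    e <- network$edges
    e <- e[order(e$donor_group, e$recipient_group), , drop = FALSE]
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  e <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "character", "integer"))
  if (!all(c("donor_group", "recipient_group", "weight") %in% names(e))) {
    stop("network TSV must have columns donor_group, recipient_group, weight")
  }
  new_lgt_network(e, nodes = sort(unique(c(e$donor_group,
                                           e$recipient_group))))
}

#' Write inferred lateral segments as a BED-like TSV
#'
#' Columns: `genome_id`, `start`, `end`, `donor_group`, `kmer_span`,
#' `status` (0-based half-open coordinates).
#'
#' @param segments Segment data.frame from [infer_lateral_segments()].
#' @param path Output path.
#' @export
write_segments <- function(segments, path) {
  cols <- c("genome_id", "start", "end", "donor_group", "kmer_span", "status")
  utils::write.table(segments[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the lateral-gene call table
#'
#' @param lateral_genes data.frame from [map_segments_to_genes()].
#' @param path Output path.
#' @export
write_lateral_genes <- function(lateral_genes, path) {
  cols <- c("genome_id", "gene_id", "donor_group", "overlap_kmers",
            "segment_start", "segment_end")
  utils::write.table(lateral_genes[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
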