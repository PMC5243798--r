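#' Simulation parameters for group-structured genomes with planted transfers
#'
#' The generator emulates the group structure the inference method assumes: a
#' random root sequence, group ancestors derived from it by inter-group
#' substitution, member genomes derived from their ancestor by intra-group
#' substitution, and lateral transfers planted by copying a donor-genome
#' interval over the homologous recipient interval (replacement, so gene
#' coordinates stay fixed). Defaults define the package's standard benchmark
#' scenario: 4 groups of 4 genomes of 200 kb, inter-group divergence 0.25,
#' intra-group divergence 0.005, and 10 planted transfers of 5 kb.
#'
#' @param n_groups Number of groups (>= 2).
#' @param genomes_per_group Genomes per group.
#' @param genome_length Genome length in nucleotides.
#' @param intra_group_divergence Per-site substitution probability from the
#'   group ancestor to each member genome.
#' @param inter_group_divergence Per-site substitution probability from the
#'   root to each group ancestor.
#' @param n_transfers Number of planted transfers.
#' @param transfer_length Transfer length in nucleotides; a single value or
#'   a length-2 range sampled uniformly.
#' @param gene_length,gene_spacer Gene tiling: non-overlapping genes of
#'   `gene_length` nt separated by `gene_spacer` nt across each genome.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_groups = 4L,
                       genomes_per_group = 4L,
                       genome_length = 200000L,
                       intra_group_divergence = 0.005,
                       inter_group_divergence = 0.25,
                       n_transfers = 10L,
                       transfer_length = 5000L,
                       gene_length = 900L,
                       gene_spacer = 100L,
                       seed = 1L) {
  stopifnot(
    n_groups >= 2L, genomes_per_group >= 1L, genome_length >= 1L,
    intra_group_divergence >= 0, intra_group_divergence <= 1,
    inter_group_divergence >= 0, inter_group_divergence <= 1,
    n_transfers >= 0L,
    length(transfer_length) %in% c(1L, 2L),
    all(transfer_length >= 1L), all(transfer_length < genome_length),
    gene_length >= 1L, gene_spacer >= 0L
  )
  structure(
    list(n_groups = as.integer(n_groups),
         genomes_per_group = as.integer(genomes_per_group),
         genome_length = as.integer(genome_length),
         intra_group_divergence = intra_group_divergence,
         inter_group_divergence = inter_group_divergence,
         n_transfers = as.integer(n_transfers),
         transfer_length = as.integer(transfer_length),
         gene_length = as.integer(gene_length),
         gene_spacer = as.integer(gene_spacer),
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

DNA_BASES <- c("A", "C", "G", "T")

# substitute each site independently with probability p, always to a
# different base
mutate_sites <- function(x, p) {
  if (p <= 0) return(x)
  idx <- which(stats::runif(length(x)) < p)
  if (!length(idx)) return(x)
  cur <- match(x[idx], DNA_BASES)
  shift <- sample.int(3L, length(idx), replace = TRUE)
  x[idx] <- DNA_BASES[(cur - 1L + shift) %% 4L + 1L]
  x
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a group-structured dataset with planted lateral transfers
#'
#' See [sim_params()] for the generative model. Each planted transfer picks
#' a recipient genome, a donor group other than the recipient's, a donor
#' genome within it and an interval, and copies the donor interval over the
#' same coordinates of the recipient (replacement). Planted intervals within
#' one recipient never overlap. Genes are tiled deterministically across
#' every genome. Byte-identical output for a fixed seed.
#'
#' @param params A `sim_params` object.
#' @return An `lgt_simulation`: list with `dataset` (an `lgt_dataset`),
#'   `truth` (data.frame `event_id`, `donor_group`, `donor_genome`,
#'   `recipient_genome`, `recipient_start`, `length`, `mode`) and `params`.
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_local_seed(params$seed, {
    L <- params$genome_length
    group_ids <- sprintf("G%02d", seq_len(params$n_groups))
    root <- sample(DNA_BASES, L, replace = TRUE)
    genomes <- list()
    groups <- character(0)
    for (g in group_ids) {
      ancestor <- mutate_sites(root, params$inter_group_divergence)
      for (m in seq_len(params$genomes_per_group)) {
        gid <- sprintf("%s_s%02d", g, m)
        genomes[[gid]] <- mutate_sites(ancestor,
                                       params$intra_group_divergence)
        groups[gid] <- g
      }
    }
    genome_ids <- names(genomes)

    truth <- data.frame(
      event_id = character(), donor_group = character(),
      donor_genome = character(), recipient_genome = character(),
      recipient_start = integer(), length = integer(), mode = character(),
      stringsAsFactors = FALSE
    )
    planted <- lapply(genome_ids, function(x) integer(0))  # used starts/ends
    names(planted) <- genome_ids
    for (t in seq_len(params$n_transfers)) {
      len <- if (length(params$transfer_length) == 2L) {
        sample(params$transfer_length[1L]:params$transfer_length[2L], 1L)
      } else {
        params$transfer_length
      }
      placed <- FALSE
      for (attempt in 1:200) {
        recipient <- sample(genome_ids, 1L)
        donor_group <- sample(setdiff(group_ids, groups[recipient]), 1L)
        donor <- sample(genome_ids[groups[genome_ids] == donor_group], 1L)
        offset <- sample.int(L - len + 1L, 1L) - 1L
        prev <- planted[[recipient]]
        overlaps <- FALSE
        if (length(prev)) {
          starts <- prev[c(TRUE, FALSE)]
          ends <- prev[c(FALSE, TRUE)]
          overlaps <- any(offset < ends & starts < offset + len)
        }
        if (!overlaps) {
          genomes[[recipient]][(offset + 1L):(offset + len)] <-
            genomes[[donor]][(offset + 1L):(offset + len)]
          planted[[recipient]] <- c(prev, offset, offset + len)
          truth <- rbind(truth, data.frame(
            event_id = sprintf("t%03d", t),
            donor_group = donor_group, donor_genome = donor,
            recipient_genome = recipient,
            recipient_start = offset, length = len, mode = "replace",
            stringsAsFactors = FALSE
          ))
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place transfer ", t,
                        " without overlap; lower n_transfers or length")
    }

    sequences <- vapply(genomes, paste, character(1), collapse = "")
    genes <- tile_genes(genome_ids, L, params$gene_length,
                        params$gene_spacer)
    structure(
      list(dataset = new_lgt_dataset(sequences, genes, groups),
           truth = truth, params = params),
      class = "lgt_simulation"
    )
  })
}

tile_genes <- function(genome_ids, L, gene_length, gene_spacer) {
  pitch <- gene_length + gene_spacer
  n_genes <- max(0L, (L - gene_length) %/% pitch + 1L)
  if (n_genes == 0L) return(empty_gene_table())
  starts <- (seq_len(n_genes) - 1L) * pitch
  do.call(rbind, lapply(genome_ids, function(gid) {
    data.frame(
      genome_id = gid,
      gene_id = sprintf("%s_g%04d", gid, seq_len(n_genes)),
      start = starts, end = starts + gene_length, strand = "+",
      stringsAsFactors = FALSE
    )
  }))
}

#' @export
print.lgt_simulation <- function(x, ...) {
  cat("Simulated dataset:", length(x$dataset$sequences), "genomes,",
      nrow(x$truth), "planted transfers (seed", x$params$seed, ")\n")
  invisible(x)
}

#' Write a simulated dataset to standard formats
#'
#' Emits `genomes.fasta`, `genes.gff3`, `groups.tsv` and (for simulations)
#' `truth.tsv` into `dir`, ready for [read_genomes()] or the command-line
#' pipeline.
#'
#' @param x An `lgt_simulation` or `lgt_dataset`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(x, dir) {
  sim <- NULL
  if (inherits(x, "lgt_simulation")) {
    sim <- x
    x <- x$dataset
  }
  stopifnot(inherits(x, "lgt_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "genomes.fasta"),
    gff3 = file.path(dir, "genes.gff3"),
    groups = file.path(dir, "groups.tsv")
  )
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x$sequences),
                              paths[["fasta"]])
  write_gff3(x$genes, paths[["gff3"]])
  write_group_table(x$groups, paths[["groups"]])
  if (!is.null(sim)) {
    paths["truth"] <- file.path(dir, "truth.tsv")
    utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

write_gff3 <- function(genes, path) {
  if (!nrow(genes)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$genome_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Score inferred segments against the planted truth
#'
#' Per-nucleotide precision and recall are computed over the union of
#' intervals per (recipient genome, donor group) pairing: a nucleotide of an
#' inferred segment is a true positive only if it lies inside a planted
#' interval of the same recipient from the same donor group. Per-event
#' recall counts a planted transfer as recovered when at least 50% of its
#' length is covered by inferred segments with the correct donor group.
#' With no inferred segments at all, precision is vacuously 1.0 and the
#' `zero_call` flag is set.
#'
#' @param segments Inferred-segment data.frame.
#' @param truth Truth data.frame from [simulate_dataset()].
#' @return A list of class `recovery_score`: `precision_nt`, `recall_nt`,
#'   `f1_nt`, `recall_event`, `n_events`, `n_segments`, `zero_call`.
#' @export
score_recovery <- function(segments, truth) {
  seg_key <- if (nrow(segments)) {
    paste(segments$genome_id, segments$donor_group, sep = "\r")
  } else {
    character(0)
  }
  tru_key <- if (nrow(truth)) {
    paste(truth$recipient_genome, truth$donor_group, sep = "\r")
  } else {
    character(0)
  }
  seg_by_key <- split(seq_len(nrow(segments)), seg_key)
  reduce_ranges <- function(starts0, ends0) {
    IRanges::reduce(IRanges::IRanges(start = starts0 + 1L, end = ends0))
  }
  inferred_r <- lapply(seg_by_key, function(i) {
    reduce_ranges(segments$start[i], segments$end[i])
  })
  tru_by_key <- split(seq_len(nrow(truth)), tru_key)
  truth_r <- lapply(tru_by_key, function(i) {
    reduce_ranges(truth$recipient_start[i],
                  truth$recipient_start[i] + truth$length[i])
  })
  total_inferred <- sum(vapply(inferred_r, function(r) sum(IRanges::width(r)),
                               numeric(1)))
  total_truth <- sum(vapply(truth_r, function(r) sum(IRanges::width(r)),
                            numeric(1)))
  tp <- 0
  for (key in intersect(names(inferred_r), names(truth_r))) {
    tp <- tp + sum(IRanges::width(
      IRanges::intersect(inferred_r[[key]], truth_r[[key]])))
  }
  zero_call <- total_inferred == 0
  precision <- if (zero_call) 1.0 else tp / total_inferred
  recall <- if (total_truth == 0) 1.0 else tp / total_truth
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)

  recall_event <- NA_real_
  if (nrow(truth)) {
    recovered <- logical(nrow(truth))
    for (i in seq_len(nrow(truth))) {
      key <- tru_key[i]
      if (!key %in% names(inferred_r)) next
      ev <- IRanges::IRanges(start = truth$recipient_start[i] + 1L,
                             end = truth$recipient_start[i] +
                               truth$length[i])
      cov <- sum(IRanges::width(IRanges::intersect(inferred_r[[key]], ev)))
      recovered[i] <- cov / truth$length[i] >= 0.5
    }
    recall_event <- mean(recovered)
  }
  structure(
    list(precision_nt = precision, recall_nt = recall, f1_nt = f1,
         recall_event = recall_event, n_events = nrow(truth),
         n_segments = nrow(segments), zero_call = zero_call),
    class = "recovery_score"
  )
}

#' @export
print.recovery_score <- function(x, ...) {
  cat(sprintf(
    "Recovery: precision %.4f, recall %.4f (per-nt); per-event recall %s over %d events%s\n",
    x$precision_nt, x$recall_nt,
    ifelse(is.na(x$recall_event), "NA", sprintf("%.4f", x$recall_event)),
    x$n_events, if (x$zero_call) " [no calls]" else ""))
  invisible(x)
}
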