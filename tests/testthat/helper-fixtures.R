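# Construct an in-memory dataset without touching the filesystem.
make_dataset <- function(sequences, groups, genes = NULL) {
  if (is.null(genes)) genes <- lgtnet:::empty_gene_table()
  lgtnet:::new_lgt_dataset(sequences, genes, groups)
}

# Write a dataset out as FASTA + groups TSV (+ optional GFF3) and return paths.
write_fixture_files <- function(sequences, groups, genes = NULL,
                                dir = withr::local_tempdir(.local_envir =
                                                             parent.frame())) {
  fasta <- file.path(dir, "genomes.fasta")
  writeLines(paste0(">", names(sequences), "\n", unname(sequences)), fasta)
  grp <- file.path(dir, "groups.tsv")
  writeLines(c("genome_id\tgroup_id",
               paste(names(groups), unname(groups), sep = "\t")), grp)
  out <- c(fasta = fasta, groups = grp)
  if (!is.null(genes)) {
    gff <- file.path(dir, "genes.gff3")
    lgtnet:::write_gff3(genes, gff)
    out["gff3"] <- gff
  }
  out
}

# Independent canonicalisation oracle: Biostrings reverse complement, done
# window by window (never the package's own vectorised path).
oracle_canonical_windows <- function(sequence, k) {
  L <- nchar(sequence)
  if (L < k) return(character(0))
  vapply(seq_len(L - k + 1L), function(i) {
    w <- substr(sequence, i, i + k - 1L)
    if (grepl("N", w, fixed = TRUE)) return(NA_character_)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
    if (w <= rc) w else rc
  }, character(1))
}

# A fabricated k-mer index whose donor presence hits exactly `marked`
# (0-based) k-mer start positions of a single genome; exercises the
# run/merge geometry of segment calling in isolation.
fake_marked_index <- function(marked, L, k, genome = "r", donor = "D",
                              own = "O") {
  pk <- rep("bg", L - k + 1L)
  pk[marked + 1L] <- "hit"
  structure(
    list(
      k = as.integer(k),
      pos_kmers = stats::setNames(list(pk), genome),
      genome_sets = stats::setNames(list(unique(pk)), genome),
      group_presence = stats::setNames(list("hit", c("bg", "hit")),
                                       c(donor, own)),
      group_counts = stats::setNames(
        list(c(hit = 1L), c(bg = 1L, hit = 1L)), c(donor, own)),
      group_bg_mean = stats::setNames(c(1, 1), c(donor, own)),
      groups = stats::setNames(own, genome)
    ),
    class = "kmer_index"
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Exhaustive bitmask clique oracle for graphs with <= 15 nodes. Returns the
# maximal cliques with >= min_size vertices as a sorted character vector of
# semicolon-joined sorted member lists.
brute_force_maximal_cliques <- function(nodes, edges, min_size = 3L) {
  n <- length(nodes)
  stopifnot(n <= 15L)
  adj <- integer(n)  # bitmask of neighbours per node
  if (nrow(edges)) {
    i1 <- match(edges$node1, nodes)
    i2 <- match(edges$node2, nodes)
    for (e in seq_along(i1)) {
      adj[i1[e]] <- bitwOr(adj[i1[e]], bitwShiftL(1L, i2[e] - 1L))
      adj[i2[e]] <- bitwOr(adj[i2[e]], bitwShiftL(1L, i1[e] - 1L))
    }
  }
  S <- 0:(2^n - 1L)
  is_clique <- rep(TRUE, length(S))
  for (v in seq_len(n)) {
    bit <- bitwShiftL(1L, v - 1L)
    allowed <- bitwOr(adj[v], bit)
    in_s <- bitwAnd(S, bit) > 0L
    ok <- bitwAnd(S, bitwNot(allowed)) == 0L
    is_clique <- is_clique & (!in_s | ok)
  }
  is_clique[1L] <- FALSE  # empty set
  extendable <- rep(FALSE, length(S))
  for (u in seq_len(n)) {
    bit <- bitwShiftL(1L, u - 1L)
    not_in <- bitwAnd(S, bit) == 0L
    covers <- bitwAnd(S, bitwNot(adj[u])) == 0L
    extendable <- extendable | (not_in & covers)
  }
  popcount <- vapply(S, function(s) sum(bitwAnd(s, bitwShiftL(1L, 0:(n - 1L))) > 0L),
                     numeric(1))
  keep <- S[is_clique & !extendable & popcount >= min_size]
  sort(vapply(keep, function(s) {
    members <- nodes[bitwAnd(s, bitwShiftL(1L, 0:(n - 1L))) > 0L]
    paste(sort(members), collapse = ";")
  }, character(1)))
}

clique_set_keys <- function(cs) {
  sort(vapply(cs$cliques, paste, character(1), collapse = ";"))
}

random_graph <- function(n, p) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2L)
  keep <- stats::runif(ncol(pairs)) < p
  edges <- data.frame(node1 = pairs[1L, keep], node2 = pairs[2L, keep],
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges),
            class = "undirected_lgt_graph")
}

# Closed-form hypergeometric tails from binomial coefficients only (oracle
# for the Fisher tests).
oracle_tails <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c
  n <- a + b
  xs <- max(0L, n - (N - K)):min(n, K)
  pmf <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  list(p_over = sum(pmf[xs >= a]), p_under = sum(pmf[xs <= a]))
}
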