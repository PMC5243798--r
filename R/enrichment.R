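#' One-sided Fisher's exact probabilities for a 2x2 table
#'
#' Exact hypergeometric tail probabilities for the table
#' \tabular{lcc}{
#'   \tab annotated \tab not annotated \cr
#'   test set \tab a \tab b \cr
#'   rest of reference \tab c \tab d \cr
#' }
#' With the margins fixed, the annotated count in the test set follows a
#' hypergeometric distribution; `p_over = P(X >= a)` tests
#' over-representation and `p_under = P(X <= a)` under-representation. Both
#' tails include the observed table, so `p_over + p_under >= 1`. All four
#' arguments are vectorised.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return data.frame with columns `p_over`, `p_under`.
#' @examples
#' fisher_term_test(3, 1, 1, 3)  # p_over = 17/70
#' @export
fisher_term_test <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative cell count")
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(a + b + c + d < 1)) stop("empty table")
  # X ~ Hypergeometric(m = a + c annotated, n = b + d unannotated,
  #                    k = a + b draws)
  p_over <- stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  p_under <- stats::phyper(a, a + c, b + d, a + b, lower.tail = TRUE)
  data.frame(p_over = pmin(p_over, 1), p_under = pmin(p_under, 1))
}

#' GO-term enrichment among a clique's lateral genes
#'
#' Tests every Gene Ontology term annotating at least one reference gene for
#' over- and under-representation in the test set (the lateral genes of a
#' clique) against the reference set (all genes of the dataset, test genes
#' included). Genes without any GO annotation are excluded from both sets.
#' Benjamini--Hochberg adjustment is applied separately to the two one-sided
#' p-value families, and a direction is assigned where the adjusted value
#' falls at or below `fdr`.
#'
#' @param test_genes Character vector of gene identifiers in the test set
#'   (must be a subset of `reference_genes`).
#' @param reference_genes Character vector of all gene identifiers in the
#'   dataset.
#' @param go_map data.frame with columns `gene_id`, `go_id` (see
#'   [read_go_map()]).
#' @param fdr False discovery rate threshold (default 0.05).
#' @return data.frame with one row per tested term: `term_id`, `a`, `b`,
#'   `c`, `d`, `p_over`, `p_under`, `q_over`, `q_under`, `direction`
#'   (`"over"`, `"under"` or `"none"`), sorted by the smaller adjusted
#'   value.
#' @export
enrich_clique <- function(test_genes, reference_genes, go_map, fdr = 0.05) {
  stopifnot(is.data.frame(go_map),
            all(c("gene_id", "go_id") %in% names(go_map)),
            fdr > 0, fdr < 1)
  test_genes <- unique(test_genes)
  reference_genes <- unique(reference_genes)
  if (!length(test_genes)) stop("empty test set")
  if (length(setdiff(test_genes, reference_genes))) {
    stop("test set must be a subset of the reference set")
  }
  annotated <- unique(go_map$gene_id)
  ref <- intersect(reference_genes, annotated)
  test <- intersect(test_genes, annotated)
  gm <- go_map[go_map$gene_id %in% ref, , drop = FALSE]
  terms <- sort(unique(gm$go_id))
  if (!length(terms)) {
    return(data.frame(term_id = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), p_over = numeric(),
                      p_under = numeric(), q_over = numeric(),
                      q_under = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  genes_by_term <- split(gm$gene_id, gm$go_id)
  n_test <- length(test)
  n_ref <- length(ref)
  a <- vapply(terms, function(t) sum(genes_by_term[[t]] %in% test),
              integer(1))
  term_total <- lengths(genes_by_term)[terms]
  b <- n_test - a
  c <- as.integer(term_total) - a
  d <- (n_ref - n_test) - c
  p <- fisher_term_test(a, b, c, d)
  q_over <- stats::p.adjust(p$p_over, method = "BH")
  q_under <- stats::p.adjust(p$p_under, method = "BH")
  direction <- rep("none", length(terms))
  direction[q_over <= fdr] <- "over"
  direction[q_under <= fdr & q_under < q_over] <- "under"
  out <- data.frame(
    term_id = terms, a = as.integer(a), b = as.integer(b),
    c = as.integer(c), d = as.integer(d),
    p_over = p$p_over, p_under = p$p_under,
    q_over = q_over, q_under = q_under,
    direction = direction, stringsAsFactors = FALSE
  )
  out <- out[order(pmin(out$q_over, out$q_under), out$term_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment result table
#'
#' @param results data.frame from [enrich_clique()].
#' @param path Output TSV path.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
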