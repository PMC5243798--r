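---
title: "Inferring LGT networks and genetic exchange communities with lgtnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring LGT networks and genetic exchange communities with lgtnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgtnet)
```

# The model

`lgtnet` treats a genome as a bag of words: its distinct k-mers. Lateral
genetic transfer (LGT) leaves a recipient genome carrying stretches of
sequence that are (a) shared with a *donor group* of genomes to an extent
unexplained by background similarity, and (b) rare within the recipient's
*own group*, because a recent transfer has not yet spread to the group's
other members. The two conditions are tested in sequence:

* the **IDF step** asks whether genome *i* shares unexpectedly many distinct
  k-mers with group *j*: the relationship-matrix entry
  `r[i][j] = |K(i) ∩ K(j)| / |K(i)|` (where `K(·)` is a distinct-canonical-
  k-mer set) must strictly exceed the mean over all defined entries;
* the **TF step** asks whether the candidate segment's k-mers are rare in the
  recipient's own group: the mean number of own-group genomes containing the
  segment's marked k-mers must be strictly below the same mean taken over the
  own group's entire presence set.

Between the two filters, marked k-mer start positions (those whose word
occurs in the donor group's presence set) are assembled into segments: runs
of consecutive marked positions, merged across gaps shorter than the
threshold *G*. A segment spans from its first marked start to the end of its
last k-mer, and its length in k-mers (`kmer_span = end − start − k + 1`)
counts every start position in that extent, gaps included.

The method is intentionally asymmetric in time: transfers older than the
most recent common ancestor of the recipient's group have usually spread to
most group members, push the segment's own-group frequency up to the
background level, and are rejected by the TF step. What survives is recent
lateral signal, which is exactly what makes the resulting network edges
interpretable as LGT rather than shared ancestry.

## Assumptions

* Groups are given, not estimated; at least two are required. Inference
  quality depends on the partition reflecting real lineage structure.
* Matching is exact. Sequence divergence *within* a transferred segment
  (post-transfer mutation) fragments the run of marked positions; the gap
  threshold *G* re-joins fragments separated by fewer than *G* nucleotides.
* Matching is strand-insensitive: every window is canonicalised to the
  lexicographic minimum of itself and its reverse complement, because genome
  records are deposited on arbitrary strands.
* `N` bases are retained in coordinates but any window containing `N` is
  excluded from catalogs — ambiguity codes cannot match exactly.

# Parameters

| parameter | unit | default | role |
|---|---|---|---|
| `k` | nt | 25 | word length; the atomic matching unit |
| `G` | nt | `2k` | maximal gap merged between marked runs |
| `idf_threshold_override` | – | `NULL` | replaces the matrix-mean IDF threshold when set |
| `min_segment_kmers` | k-mers | 10 | minimal segment span for gene mapping |
| `min_overlap_kmers` | k-mers | 10 | minimal in-gene overlap for gene mapping |
| `min_clique_size` | nodes | 3 | smallest reported maximal clique |
| `fdr` | – | 0.05 | Benjamini–Hochberg threshold for GO enrichment |
| `k_grid` | nt | `k` | word lengths examined for core-node stability |

Small *k* (≤ 20) produces chance matches between unrelated sequences and
hence false positives; large *k* (≥ 40) makes shared words too rare and
detections sparse. The default grid for empirical data is 20–40, with step
10 for closely related datasets and step 5 for phyletically broad ones. The
two gene-mapping thresholds approximate the typical detection length in a
dataset: presets are provided (`threshold_profile()`) at 500/100 for
sequence-type-level datasets, 100/100 at genus level, and 10/10 for
class-, phylum- or order-level collections, where shared segments are short.

# Numerical choices

* **Normalisation of the relationship matrix.** Raw shared-k-mer counts are
  divided by the recipient genome's distinct-k-mer count, giving entries in
  [0, 1] comparable across genomes of different length. Own-group cells are
  undefined and excluded from the mean threshold.
* **Strict inequalities at both thresholds.** Eligibility requires
  `r > mean`; TF acceptance requires `segment mean < background mean`. Ties
  therefore reject, so a dataset of identical genomes yields no calls.
* **Frequency = genome presence.** The TF step counts the number of
  own-group genomes *containing* a k-mer, not its total occurrences;
  presence counting matches the per-group dictionary semantics of the index
  and is insensitive to within-genome repeats.
* **Gap merging threshold.** Two runs are merged when the gap between
  marked start positions is strictly less than `max(G, k)`. For all
  `G ≥ k` — in particular the default `G = 2k` — this is exactly the
  "gap < G" rule; the `max(·, k)` floor only acts for degenerate small `G`,
  where runs closer than `k` overlap in nucleotide space and must coalesce
  for emitted segments to stay pairwise disjoint.
* **Gene overlap.** A k-mer start position counts toward a gene only when
  its full k-length window lies inside the gene interval (a window either
  is or is not inside the gene); gap positions within a merged segment do
  count. A gene hit from several donor groups yields one call per donor
  group, since the network weights are per donor–recipient pair.
* **Clique reporting.** Maximal cliques are enumerated exactly with
  recursive pivoting (Bron–Kerbosch family, via igraph); the group-level
  graphs here have at most a few dozen nodes, so worst-case exponential
  behaviour is immaterial. Ties for maximum size are all flagged, and the
  lexicographically first is marked canonical for reproducible reports.
* **Enrichment.** One-sided hypergeometric tails are computed in closed
  form; both tails include the observed table. The reference set is all
  annotated genes of the dataset *including* the test set (the test column
  of the 2×2 table is subtracted from the margins, not from the input
  sets); unannotated genes are excluded from both sets; annotations are
  used as given, with no propagation through the GO hierarchy.
  Benjamini–Hochberg adjustment is applied separately to the over- and
  under-represented families, since the two directions are reported
  separately.
* **Degenerate inputs.** Genomes shorter than `k` contribute empty
  catalogs (and relationship entries of 0); empty networks produce empty
  clique sets; a single-element `k_grid` skips the core-node stage with a
  warning; a clique covering no lateral genes reports a total of 0.

# Design decisions taken where the design was open

* Core nodes are defined as groups present in *at least one maximal clique*
  at every examined `k`; the stricter variant (membership in a maximum
  clique at every `k`) is computed alongside and reported in the same
  table.
* The command-line interface is a thin `Rscript` wrapper
  (`inst/scripts/lgt-pipeline.R`) over exported functions; all behaviour is
  available and tested at the R level.
* GenBank flat files are not parsed directly; gene annotations are read
  from GFF3, to which GenBank records are routinely converted.

# The simulator: what it emulates and what it does not

`simulate_dataset()` draws a root sequence, derives one ancestor per group
by independent per-site substitution (`inter_group_divergence`), derives
member genomes from their ancestor the same way (`intra_group_divergence`),
and plants transfers by copying a donor-genome interval over the same
coordinates of a recipient genome (replacement). Genes are tiled
deterministically (900 nt genes, 100 nt spacers by default). Everything is
reproducible from a single seed.

The default scenario — 4 groups × 4 genomes of 200 kb, inter-group
divergence 0.25, intra-group 0.005, ten 5 kb transfers — was chosen to
mimic the regime the method targets: groups distinct enough that background
k-mer sharing is negligible at `k = 25`, members similar enough that the
own-group background frequency is high, and transfers long enough to clear
the mapping thresholds. On this scenario the pipeline recovers every
planted event with per-nucleotide precision above 0.99.

Deliberately **not** modelled: insertions/deletions and rearrangements
(exact matching would fragment across indels; coordinates would no longer
be shared between donor and recipient), coalescent population structure,
codon or compositional bias, plasmids/phage as separate replicons, and
within-genome rate variation. Passing the simulated benchmarks therefore
demonstrates correctness of the inference machinery under the model's own
assumptions — not performance on real genomes, where divergence within
transferred segments, repeats and mobile elements make both thresholds and
`k` genuinely consequential.

Two further caveats follow from the replacement design. First, transfer
detection is symmetric in principle: once a fragment has been copied into a
recipient, the *donor* genome also shares that fragment with the
recipient's group. The TF filter usually rejects the back-direction
(the fragment is ancestral, hence frequent, in the donor's own group), but
when two planted transfers happen to overlap reciprocally at the same
coordinates the groups exchange flanking homology and per-nucleotide
precision drops below 1 even though every reported segment reflects real
shared material. Second, per-event recall uses a ≥ 50% coverage rule, so a
transfer recovered as two half-segments still counts.

# Problem sizes used by the test suite

Unit tests run on strings of tens to hundreds of nucleotides where expected
values are hand-derivable or brute-force enumerable (window-by-window
canonicalisation, exhaustive bitmask clique search on ≤ 15 nodes, closed-
form hypergeometric tails on all 2×2 tables with total ≤ 30). End-to-end
benchmarks use the default 3.2 Mb scenario above plus a 6 × 20 kb pipeline
fixture; these sizes exercise every stage while keeping a full test run in
the low minutes on one CPU.

# Limitations

* Exact k-mer matching is not robust to sequence loss, truncation or
  heavy post-transfer divergence; such events are missed or fragmented.
* The IDF threshold is global: a pair of extremely similar groups (e.g.
  sister genera) inflates the matrix mean and can mask weaker lateral
  signal elsewhere in the dataset. Removing or merging the dominant groups,
  or overriding the threshold, exposes it again.
* Cliques are a strict community definition; missing data can break a true
  community into overlapping cliques. Noise-tolerant structures
  (paracliques) are out of scope here.
* Directionality and edge weights are discarded before clique extraction;
  the communities describe connectivity, not flux.
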