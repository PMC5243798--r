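# Heavy benchmark scenarios are computed once per test run and memoised so
# several test files can assert on the same objects.
.scenario_cache <- new.env(parent = emptyenv())

# Standard benchmark: 4 groups x 4 genomes of 200 kb, inter-group divergence
# 0.25, intra 0.005, 10 planted 5 kb transfers, seed 1; k = 25, G = 2k.
standard_scenario <- function() {
  if (is.null(.scenario_cache$standard)) {
    sim <- simulate_dataset(sim_params())
    cfg <- lgt_config(k = 25)
    segments <- infer_lateral_segments(sim$dataset, cfg)
    .scenario_cache$standard <- list(sim = sim, cfg = cfg,
                                     segments = segments)
  }
  .scenario_cache$standard
}

# Same generative conditions with no planted transfers (false-positive
# control).
null_scenario <- function(k) {
  key <- paste0("null_k", k)
  if (is.null(.scenario_cache[[key]])) {
    if (is.null(.scenario_cache$null_sim)) {
      .scenario_cache$null_sim <- simulate_dataset(sim_params(n_transfers = 0))
    }
    sim <- .scenario_cache$null_sim
    cfg <- lgt_config(k = k)
    segments <- infer_lateral_segments(sim$dataset, cfg)
    .scenario_cache[[key]] <- list(
      sim = sim, cfg = cfg, segments = segments,
      lateral_genes = map_segments_to_genes(segments, sim$dataset, cfg))
  }
  .scenario_cache[[key]]
}

# Desk-scale simulation for invariant and monotonicity checks.
small_scenario <- function() {
  if (is.null(.scenario_cache$small)) {
    sim <- simulate_dataset(sim_params(
      n_groups = 3L, genomes_per_group = 2L, genome_length = 20000L,
      n_transfers = 4L, transfer_length = 1500L, seed = 7L))
    cfg <- lgt_config(k = 15, min_segment_kmers = 5, min_overlap_kmers = 5)
    segments <- infer_lateral_segments(sim$dataset, cfg)
    .scenario_cache$small <- list(
      sim = sim, cfg = cfg, segments = segments,
      lateral_genes = map_segments_to_genes(segments, sim$dataset, cfg))
  }
  .scenario_cache$small
}
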