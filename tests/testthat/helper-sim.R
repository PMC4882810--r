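# Small configurations used across tests. The full-size defaults (5700
# autosomal genes) are exercised in the acceptance suite; unit tests use
# scaled-down universes with the same structure.

small_cfg <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(n_autosomal_genes = 60, n_z_genes = 30,
                   mean_depth = 200, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# deterministic toy read-assignment table
toy_assignment <- function(counts_by_tx, sample_id = "s1") {
  data.frame(transcript_id = names(counts_by_tx),
             sample_id = sample_id,
             read_pair_count = as.numeric(counts_by_tx),
             stringsAsFactors = FALSE)
}
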