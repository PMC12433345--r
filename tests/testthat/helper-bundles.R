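# Shared simulated fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

# Down-scaled design for unit tests: same 6 x 8 structure, fewer loci.
small_cfg <- function(seed = 7L) {
  sim_config(seed = seed, n_shared = 120L, n_specific = 15L,
             chrom_len = 300000L, n_genes = 60L)
}

small_bundle <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- simulate_bundle(small_cfg())
  .fixtures$small
}

small_result <- function() {
  if (is.null(.fixtures$small_res))
    .fixtures$small_res <- suppressMessages(
      run_pipeline(small_bundle(), out_dir = NULL,
                   config = pipeline_config(seed = 7L)))
  .fixtures$small_res
}

# The full study-design bundle (6 tissues x 8 replicates, 3000 shared +
# 600 specific loci) used by the end-to-end recovery checks.
default_bundle <- function() {
  if (is.null(.fixtures$default))
    .fixtures$default <- simulate_bundle(sim_config(seed = 7L))
  .fixtures$default
}

default_result <- function() {
  if (is.null(.fixtures$default_res))
    .fixtures$default_res <- suppressMessages(
      run_pipeline(default_bundle(), out_dir = NULL,
                   config = pipeline_config(seed = 7L)))
  .fixtures$default_res
}

# Match recovered consensus regions to truth loci one-to-one by summit
# identity (the generator places every sample's summit at the locus
# summit, so an exact-summit match is the strictest 1:1 check).
match_truth <- function(regions, truth) {
  match(paste0(regions$chrom, ":", regions$consensus_summit),
        paste0(truth$chrom, ":", truth$summit))
}
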