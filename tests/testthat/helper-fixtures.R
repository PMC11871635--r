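# Shared expensive fixtures, built once per test run: a default planted
# epigenome (seed fixed) and the pipeline run over it.

.fixture_cache <- new.env(parent = emptyenv())

fixture_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    dir <- file.path(tempdir(), "crcscan-sim-fixture")
    unlink(dir, recursive = TRUE)
    .fixture_cache$sim <- plant_epigenome(synthetic_config(seed = 101), dir)
  }
  .fixture_cache$sim
}

fixture_run <- function() {
  if (is.null(.fixture_cache$run)) {
    sim <- fixture_sim()
    .fixture_cache$run <- run_crc_pipeline(
      peaks = sim$files$peaks, genes = sim$files$genes,
      genome = sim$files$genome, motifs = sim$files$motifs,
      signal = sim$files$signal,
      tf_list = readLines(sim$files$tf_list),
      out_dir = file.path(sim$dir, "out"))
  }
  .fixture_cache$run
}

# Small quantified-region set for table-level tests.
small_enhancer_table <- function() {
  set.seed(7)
  peaks <- random_peaks(40, max_pos = 2e5)
  regions <- stitch(peaks, 5000)
  regions <- quantify(regions)
  call_superenhancers(regions)
}
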