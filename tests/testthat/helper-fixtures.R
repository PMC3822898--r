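# Fixtures are generated in code: a small synthetic dataset written to a
# temporary file, plus plugin / filter source files used across tests.

fixture_blocks <- function(seed = 42L, n_segments = 3L, n_units = 2L,
                           n_channels = 2L, waveforms = TRUE) {
  build_dataset(generator_spec(
    seed = seed, n_segments = n_segments, n_units = n_units,
    n_channels = n_channels, waveforms = waveforms,
    signal_components = list(c(50, 10)), signal_noise_sd = 2,
    signal_fs_hz = 500))
}

# write a fixture dataset to .h5 and return its parts
fixture_on_disk <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                            seed = 42L, ...) {
  blocks <- fixture_blocks(seed = seed, ...)
  path <- file.path(dir, sprintf("fixture_%d.h5", seed))
  write_file(path, blocks)
  sel <- from_current(selection_state(blocks, select_all = TRUE))
  list(path = path, blocks = blocks, selection = sel)
}

# the spike-count example plugin: per-unit spike counts over segments,
# optionally as rates in Hz
spike_count_plugin_source <- function() {
  c("spike_counts <- analysis_plugin(",
    "  name = \"Spike counts\",",
    "  parameters = list(",
    "    plugin_param(\"as_rate\", \"boolean\", FALSE, \"Rate in Hz\"),",
    "    plugin_param(\"legend\", \"boolean\", TRUE, \"Show legend\")",
    "  ),",
    "  start = function(provider, selections, config) {",
    "    by_unit <- provider$spike_trains_by_unit_by_segment()",
    "    lapply(by_unit, function(per_seg)",
    "      spike_counts_per_segment(per_seg, as_rate = config$as_rate))",
    "  })")
}

write_spike_count_plugin <- function(dir) {
  path <- file.path(dir, "spike_counts.R")
  writeLines(spike_count_plugin_source(), path)
  path
}

expect_no_violations <- function(obj) {
  expect_identical(validate(obj), character(0))
}
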