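test_that("plugin discovery mirrors the directory tree and refreshes on edit", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "rates"))
  dir.create(file.path(dir, "misc"))
  write_spike_count_plugin(file.path(dir, "rates"))
  writeLines(c("p2 <- analysis_plugin('ISI summary',",
               "  start = function(provider, selections, config)",
               "    lengths(provider$spike_trains_by_unit()))"),
             file.path(dir, "rates", "isi.R"))
  writeLines(c("p3 <- analysis_plugin('Counter',",
               "  start = function(provider, selections, config)",
               "    length(provider$spike_trains()))"),
             file.path(dir, "misc", "count.R"))
  tree <- discover_plugins(dir)
  expect_length(plugin_tree_leaves(tree), 3)
  expect_setequal(names(tree$children), c("misc", "rates"))
  expect_length(tree$children$rates$plugins, 2)
  # editing a file is visible on re-discovery
  writeLines(c("p3 <- analysis_plugin('Counter v2',",
               "  start = function(provider, selections, config) 0)"),
             file.path(dir, "misc", "count.R"))
  tree2 <- discover_plugins(dir)
  expect_false(is.null(find_plugin(tree2, "Counter v2")))
  expect_null(find_plugin(tree2, "Counter"))
  # a broken file warns and is skipped, others are unaffected
  writeLines("syntax error here (", file.path(dir, "misc", "broken.R"))
  expect_warning(tree3 <- discover_plugins(dir), "failed to load")
  expect_length(plugin_tree_leaves(tree3), 3)
  # discovery is idempotent without disk changes
  suppressWarnings({
    a <- discover_plugins(dir); b <- discover_plugins(dir)
  })
  expect_equal(vapply(plugin_tree_leaves(a), plugin_name, character(1)),
               vapply(plugin_tree_leaves(b), plugin_name, character(1)))
})

test_that("parameter declarations validate types, defaults and choices", {
  p <- analysis_plugin("t", start = function(pr, s, cfg) cfg,
                       parameters = list(
                         plugin_param("as_rate", "boolean", FALSE),
                         plugin_param("bins", "integer", 10L),
                         plugin_param("width", "real", 0.5),
                         plugin_param("label", "text", "x"),
                         plugin_param("taper", "choice", "hann",
                                      choices = c("hann", "rectangular"))))
  got <- validate_params(p, list(bins = 20))
  expect_identical(got$bins, 20L)
  expect_identical(got$as_rate, FALSE) # default filled in
  expect_error(validate_params(p, list(nope = 1)), "unknown parameter")
  expect_error(validate_params(p, list(bins = 2.5)), "kind 'integer'")
  expect_error(validate_params(p, list(taper = "welch")), "kind 'choice'")
  expect_error(plugin_param("x", "choice", "a"), "does not satisfy")
  expect_error(analysis_plugin("d", start = function(a, b, c) 1,
                               parameters = list(plugin_param("k", "real", 1),
                                                 plugin_param("k", "real", 2))),
               "unique")
})

test_that("in-process execution runs the plugin and wraps its errors", {
  fx <- fixture_on_disk(seed = 33L, n_segments = 3L)
  dir <- withr::local_tempdir()
  path <- write_spike_count_plugin(dir)
  plugin <- find_plugin(discover_plugins(dir), "Spike counts")
  prov <- provider_from_selection(fx$selection)
  res <- run_in_process(plugin, prov, list(as_rate = FALSE))
  expect_equal(names(res), c("Unit 0", "Unit 1"))
  expect_equal(res[["Unit 0"]]$segment, sprintf("Segment %d", 0:2))
  rate <- run_in_process(plugin, prov, list(as_rate = TRUE))
  # count and rate modes differ exactly by each segment's duration (2 s)
  expect_equal(rate[["Unit 1"]]$value, res[["Unit 1"]]$value / 2)
  bad <- analysis_plugin("exploder", start = function(pr, s, cfg) stop("kapow"))
  expect_error(run_in_process(bad, prov), "plugin 'exploder' failed: kapow")
})

test_that("subprocess execution equals in-process execution", {
  skip_if_not_installed("ephyskit")
  fx <- fixture_on_disk(seed = 34L, n_segments = 3L)
  dir <- withr::local_tempdir()
  path <- write_spike_count_plugin(dir)
  plugin <- .load_plugin_file(path)
  prov <- provider_from_selection(fx$selection)
  inproc <- run_in_process(plugin, prov, list(as_rate = TRUE))
  sub <- run_subprocess(path, snapshot(prov), list(as_rate = TRUE))
  expect_equal(sub, inproc)
})

test_that("subprocess failures surface the child error to the parent", {
  fx <- fixture_on_disk(seed = 35L, n_segments = 2L)
  dir <- withr::local_tempdir()
  path <- write_spike_count_plugin(dir)
  prov <- provider_from_selection(fx$selection)
  snap <- snapshot(prov)
  snap$selection_json <- gsub(basename(fx$path), "gone.h5", snap$selection_json,
                              fixed = TRUE)
  expect_error(run_subprocess(path, snap, list()), "gone.h5|resolution")
})

test_that("exported bundles reproduce the direct result and list their inputs", {
  fx <- fixture_on_disk(seed = 36L, n_segments = 3L)
  dir <- withr::local_tempdir()
  path <- write_spike_count_plugin(dir)
  plugin <- .load_plugin_file(path)
  prov <- provider_from_selection(fx$selection)
  direct <- run_in_process(plugin, prov, list(as_rate = FALSE))
  bundle <- file.path(dir, "bundle")
  export_standalone(path, list(fx$selection), list(as_rate = FALSE), bundle,
                    plugin_name = "Spike counts")
  mf <- jsonlite::fromJSON(file.path(bundle, "manifest.json"))
  expect_equal(mf$plugin_file, "plugin.R")
  expect_equal(mf$selections, "selections/sel_001.sel.json")
  expect_true(file.exists(file.path(bundle, "run")))
  res <- run_bundle(bundle)
  expect_equal(res, direct)
  stored <- read_result(file.path(bundle, "result.h5"))
  expect_equal(stored, direct)
  # missing selection file -> clear error
  unlink(file.path(bundle, "selections", "sel_001.sel.json"))
  expect_error(run_bundle(bundle), "selection file .* missing")
})

test_that("startup scripts adjust configuration and fail safely", {
  dir <- withr::local_tempdir()
  script <- file.path(dir, "startup.R")
  writeLines("config$autoload <- FALSE; config$plot_color <- 'steelblue'",
             script)
  cfg <- run_startup_script(script, list(autoload = TRUE))
  expect_false(cfg$autoload)
  expect_equal(cfg$plot_color, "steelblue")
  expect_equal(run_startup_script(file.path(dir, "absent.R"),
                                  list(autoload = TRUE)),
               list(autoload = TRUE))
  writeLines("stop('bad script')", script)
  expect_warning(cfg2 <- run_startup_script(script, list(autoload = TRUE)),
                 "continuing with defaults")
  expect_true(cfg2$autoload)
})
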