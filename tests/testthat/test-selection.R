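test_that("selection JSON is canonical and round trips byte-identically", {
  expect_equal(to_json(selection()), '{"blocks":[],"version":1}')
  s <- selection(list(selection_block(
    "f.h5", "native-h5", 0L, segments = c(2L, 0L),
    channel_groups = list(selection_group(1L, units = c(1L, 0L)),
                          selection_group(0L, channels = 0L)))))
  j <- to_json(s)
  expect_identical(to_json(from_json(j)), j)
  # order of indices and groups does not matter: canonicalization
  s2 <- selection(list(selection_block(
    "f.h5", "native-h5", 0L, segments = c(0L, 2L),
    channel_groups = list(selection_group(0L, channels = 0L),
                          selection_group(1L, units = c(0L, 1L))))))
  expect_identical(to_json(s2), j)
})

test_that("from_json normalizes duplicates and rejects malformed documents", {
  expect_warning(
    s <- from_json('{"blocks":[{"path":"f","io":"native-h5","index":0,"segments":[1,1,0]}],"version":1}'),
    "duplicate")
  expect_equal(s$blocks[[1]]$segments, c(0L, 1L))
  expect_error(from_json('{"blocks":[]}'), "version")
  expect_error(from_json('{"version":99,"blocks":[]}'), "unknown schema version")
  expect_error(from_json('{"version":1,"blocks":[{"io":"x","index":0}]}'),
               "missing required key 'path'")
  expect_error(from_json("{nonsense"), "parse error")
})

test_that("resolve marks exactly the selected containers", {
  fx <- fixture_on_disk(seed = 9L, n_segments = 3L)
  sel <- selection(list(selection_block(
    fx$path, "native-h5", 0L, segments = 2L,
    channel_groups = list(selection_group(0L, units = 1L)))))
  res <- resolve(sel, lazy = TRUE)
  blk <- res[[1]]
  expect_true(blk$selected)
  expect_equal(vapply(blk$segments, function(s) s$selected, logical(1)),
               c(FALSE, FALSE, TRUE))
  cg <- blk$channel_groups[[1]]
  expect_true(cg$selected)
  expect_equal(vapply(cg$units, function(u) u$selected, logical(1)),
               c(FALSE, TRUE))
  expect_equal(vapply(cg$channels, function(ch) ch$selected, logical(1)),
               c(FALSE, FALSE))
})

test_that("resolve reports missing files and out-of-range indices", {
  fx <- fixture_on_disk(seed = 10L)
  expect_error(resolve(selection(list(selection_block("gone.h5", "native-h5", 0L)))),
               "resolution error")
  expect_error(resolve(selection(list(selection_block(fx$path, "native-h5", 3L)))),
               "index 3")
  expect_error(resolve(selection(list(selection_block(fx$path, "native-h5", 0L,
                                                      segments = 99L)))),
               "99")
})

test_that("lazy resolve materializes no data objects", {
  fx <- fixture_on_disk(seed = 11L)
  reset_materialization_count()
  resolve(fx$selection, lazy = TRUE)
  expect_identical(materialization_count(), 0L)
})

test_that("from_current snapshots are immune to later state changes", {
  fx <- fixture_on_disk(seed = 12L, n_segments = 3L)
  blocks <- read_file(fx$path)
  st <- selection_state(blocks, select_all = TRUE)
  snap <- from_current(st)
  expect_equal(snap$blocks[[1]]$segments, 0:2)
  st$set_selected(blocks[[1]]$segments[[1]], FALSE)
  expect_equal(snap$blocks[[1]]$segments, 0:2) # unchanged
  snap2 <- from_current(st)
  expect_equal(snap2$blocks[[1]]$segments, 1:2)
})

test_that("empty state and unsaved blocks behave as specified", {
  expect_equal(from_current(selection_state(list())), selection())
  mem <- new_block("in memory only")
  st <- selection_state(list(mem), select_all = TRUE)
  expect_error(from_current(st), "source locator")
})

test_that("selection size depends on container counts, not data volume", {
  dir <- withr::local_tempdir()
  small <- build_dataset(generator_spec(seed = 1L, n_segments = 2L,
                                        n_channels = 0L,
                                        baseline_hz = 2, peak_hz = 2,
                                        waveforms = FALSE))
  big <- build_dataset(generator_spec(seed = 1L, n_segments = 2L,
                                      n_channels = 0L,
                                      baseline_hz = 2000, peak_hz = 2000,
                                      waveforms = FALSE))
  fs <- file.path(dir, "data_a.h5"); fb <- file.path(dir, "data_b.h5")
  write_file(fs, small); write_file(fb, big)
  js <- to_json(from_current(selection_state(small)))
  jb <- to_json(from_current(selection_state(big)))
  expect_gt(file.size(fb), file.size(fs)) # ~1000x the spikes on disk
  expect_identical(nchar(jb), nchar(js))  # same-size selection text
})

test_that("randomized selections round trip and resolve to exactly their marks", {
  fx <- fixture_on_disk(seed = 13L, n_segments = 4L, n_units = 2L,
                        waveforms = FALSE)
  set.seed(99)
  for (i in 1:25) {
    segs <- sort(sample(0:3, sample(0:4, 1)))
    units <- sort(sample(0:1, sample(0:2, 1)))
    chans <- sort(sample(0:1, sample(0:2, 1)))
    sel <- selection(list(selection_block(
      fx$path, "native-h5", 0L, segments = segs,
      channel_groups = list(selection_group(0L, units = units,
                                            channels = chans)))))
    j <- to_json(sel)
    expect_identical(to_json(from_json(j)), j)
    blk <- resolve(sel, lazy = TRUE)[[1]]
    expect_equal(which(vapply(blk$segments, function(s) s$selected, logical(1))) - 1L,
                 segs)
    cg <- blk$channel_groups[[1]]
    expect_equal(which(vapply(cg$units, function(u) u$selected, logical(1))) - 1L,
                 units)
    expect_equal(which(vapply(cg$channels, function(c) c$selected, logical(1))) - 1L,
                 chans)
  }
})

test_that("named selection lists auto-suffix colliding names", {
  lst <- selections_add(list(), "stim A", selection())
  lst <- selections_add(lst, "stim A", selection())
  expect_equal(names(lst), c("stim A", "stim A_2"))
})
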