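# fixture: 1 block, 3 segments, 1 channel group with 2 units and 2 channels

test_that("container queries return only selected members in traversal order", {
  fx <- fixture_on_disk(seed = 21L, n_segments = 3L)
  prov <- provider_from_selection(fx$selection)
  expect_length(prov$blocks(), 1)
  expect_length(prov$segments(), 3)
  expect_length(prov$units(), 2)
  expect_length(prov$channels(), 2)
  sel <- selection(list(selection_block(
    fx$path, "native-h5", 0L, segments = c(0L, 2L),
    channel_groups = list(selection_group(0L, units = 0:1, channels = 0:1)))))
  p2 <- provider_from_selection(sel)
  expect_equal(vapply(p2$segments(), function(s) s$name, character(1)),
               c("Segment 0", "Segment 2"))
  empty <- provider_from_selection(selection())
  expect_length(empty$blocks(), 0)
  expect_length(empty$spike_trains(), 0)
  expect_length(empty$segments(), 0)
})

test_that("blocks from several files come back in file order", {
  dir <- withr::local_tempdir()
  fx1 <- fixture_on_disk(dir = dir, seed = 22L, n_segments = 2L)
  fx2 <- fixture_on_disk(dir = dir, seed = 23L, n_segments = 2L)
  sel <- selection(c(fx1$selection$blocks, fx2$selection$blocks))
  prov <- provider_from_selection(sel)
  expect_length(prov$blocks(), 2)
  expect_equal(prov$blocks()[[1]]$source$path, normalizePath(fx1$path))
  expect_equal(prov$blocks()[[2]]$source$path, normalizePath(fx2$path))
})

test_that("spike train queries respect the unit AND segment inclusion rule", {
  fx <- fixture_on_disk(seed = 24L, n_segments = 3L)
  prov <- provider_from_selection(fx$selection)
  expect_length(prov$spike_trains(), 6) # 2 units x 3 segments
  by_unit <- prov$spike_trains_by_unit()
  expect_equal(names(by_unit), c("Unit 0", "Unit 1"))
  expect_equal(lengths(by_unit), c("Unit 0" = 3L, "Unit 1" = 3L))
  nested <- prov$spike_trains_by_unit_by_segment()
  expect_length(nested, 2)
  expect_equal(names(nested[["Unit 0"]]),
               c("Segment 0", "Segment 1", "Segment 2"))
  # deselect one segment: 2x2 remain
  sel <- selection(list(selection_block(
    fx$path, "native-h5", 0L, segments = c(0L, 2L),
    channel_groups = list(selection_group(0L, units = 0:1, channels = 0:1)))))
  expect_length(provider_from_selection(sel)$spike_trains(), 4)
  # deselect one unit: 1x3 remain
  sel2 <- selection(list(selection_block(
    fx$path, "native-h5", 0L, segments = 0:2,
    channel_groups = list(selection_group(0L, units = 1L, channels = 0:1)))))
  p3 <- provider_from_selection(sel2)
  expect_length(p3$spike_trains(), 3)
  expect_equal(names(p3$spike_trains_by_unit()), "Unit 1")
})

test_that("query results are mutually consistent", {
  fx <- fixture_on_disk(seed = 25L, n_segments = 3L)
  prov <- provider_from_selection(fx$selection)
  expect_equal(length(prov$spike_trains()),
               sum(lengths(prov$spike_trains_by_segment())))
  expect_equal(length(prov$spike_trains()),
               sum(lengths(prov$spike_trains_by_unit())))
})

test_that("trains without a unit appear under the sentinel key", {
  blk <- new_block("b")
  seg <- new_segment("s0"); attach_child(blk, seg)
  attach_child(seg, new_spike_train(qty(0.5, "s"), qty(0, "s"), qty(1, "s")))
  f <- withr::local_tempfile(fileext = ".h5")
  write_file(f, list(blk))
  st <- selection_state(read_file(f), select_all = TRUE)
  prov <- provider_from_state(st)
  expect_length(prov$spike_trains(), 1)
  expect_equal(names(prov$spike_trains_by_unit()), "<unassigned>")
})

test_that("analog signals group by channel, ordered by channel index", {
  fx <- fixture_on_disk(seed = 26L, n_segments = 2L)
  prov <- provider_from_selection(fx$selection)
  by_ch <- prov$analog_signals_by_channel()
  expect_equal(names(by_ch), c("Channel 0", "Channel 1"))
  expect_equal(lengths(by_ch), c("Channel 0" = 2L, "Channel 1" = 2L))
  sel <- selection(list(selection_block(
    fx$path, "native-h5", 0L, segments = 0:1,
    channel_groups = list(selection_group(0L, units = 0:1, channels = 1L)))))
  by_ch2 <- provider_from_selection(sel)$analog_signals_by_channel()
  expect_equal(names(by_ch2), "Channel 1")
})

test_that("events filter by label; empty segments are absent", {
  fx <- fixture_on_disk(seed = 27L, n_segments = 3L)
  prov <- provider_from_selection(fx$selection)
  evs <- prov$events_by_segment("stim")
  expect_length(evs, 3)
  expect_length(prov$events_by_segment("no such label"), 0)
  expect_length(prov$epochs_by_segment(), 0)
})

test_that("laziness: nothing is read until queried, and only once", {
  fx <- fixture_on_disk(seed = 28L, n_segments = 3L)
  reset_materialization_count()
  prov <- provider_from_selection(fx$selection, lazy = TRUE)
  expect_identical(materialization_count(), 0L)
  expect_identical(prov$materialized_count(), 0L)
  n <- length(prov$spike_trains())
  expect_identical(materialization_count(), n)
  prov$spike_trains()
  expect_identical(materialization_count(), n)
  expect_identical(prov$materialized_count(), n)
})

test_that("snapshot and live providers answer queries identically", {
  fx <- fixture_on_disk(seed = 29L, n_segments = 3L)
  blocks <- read_file(fx$path)
  st <- selection_state(blocks, select_all = TRUE)
  st$set_selected(blocks[[1]]$segments[[2]], FALSE)
  live <- provider_from_state(st)
  snap_prov <- provider_from_selection(from_current(st))
  expect_equal(vapply(live$segments(), function(s) s$name, character(1)),
               vapply(snap_prov$segments(), function(s) s$name, character(1)))
  lt <- live$spike_trains(); st_ <- snap_prov$spike_trains()
  expect_length(lt, length(st_))
  for (i in seq_along(lt)) expect_true(model_equal(lt[[i]], st_[[i]]))
  # live provider tracks subsequent changes, the snapshot does not
  st$set_selected(blocks[[1]]$segments[[2]], TRUE)
  expect_length(live$segments(), 3)
  expect_length(snap_prov$segments(), 2)
})

test_that("provider snapshots restore to an equivalent provider", {
  fx <- fixture_on_disk(seed = 30L, n_segments = 2L)
  prov <- provider_from_selection(fx$selection)
  snap <- snapshot(prov)
  js <- snapshot_to_json(snap)
  prov2 <- restore(js)
  a <- prov$spike_trains(); b <- prov2$spike_trains()
  expect_length(b, length(a))
  for (i in seq_along(a)) expect_true(model_equal(a[[i]], b[[i]]))
  ev_a <- prov$events_by_segment(); ev_b <- prov2$events_by_segment()
  expect_equal(names(ev_a), names(ev_b))
  # restore on a machine without the file names the path
  bad <- snap
  bad$selection_json <- gsub(basename(fx$path), "missing.h5",
                             bad$selection_json, fixed = TRUE)
  expect_error(restore(bad), "missing.h5")
})
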