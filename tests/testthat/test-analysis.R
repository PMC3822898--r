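strain <- function(times, t0 = 0, t1 = max(times, 1) + 0.1, unit = "s") {
  new_spike_train(qty(times, unit), qty(t0, unit), qty(t1, unit))
}

test_that("interspike intervals: differences, singletons, ties", {
  expect_equal(q_mag(isi(strain(c(0.1, 0.3, 0.6)))), c(0.2, 0.3))
  expect_length(q_mag(isi(strain(0.5))), 0)
  expect_equal(q_mag(isi(strain(c(0.2, 0.2, 0.5)))), c(0, 0.3))
})

test_that("isi histogram pools within-train intervals into half-open bins", {
  tr <- strain((0:10) * 10, t1 = 200, unit = "ms") # 11 spikes, 10 ms apart
  h <- isi_histogram(list(tr), qty(5, "ms"), qty(50, "ms"))
  expect_s3_class(h, "binned_histogram")
  expect_equal(length(h$counts), 10)
  expect_equal(h$counts[3], 10) # all ten intervals in [10, 15) ms
  expect_equal(sum(h$counts), 10)
  # empty input: all-zero histogram
  h0 <- isi_histogram(list(), qty(5, "ms"), qty(50, "ms"))
  expect_true(all(h0$counts == 0))
  expect_error(isi_histogram(list(tr), qty(0, "ms"), qty(50, "ms")), "positive")
})

test_that("isi counts are conserved including overflow", {
  trains <- lapply(1:4, function(i) gen_poisson_train(15, qty(0, "s"),
                                                      qty(2, "s"), seed = i))
  h <- isi_histogram(trains, qty(10, "ms"), qty(80, "ms"))
  n_int <- sum(vapply(trains, function(tr) max(length(tr$times) - 1L, 0L),
                      integer(1)))
  expect_equal(sum(h$counts) + h$overflow, n_int)
})

test_that("poisson isi mean matches 1/rate within 3 standard errors", {
  tr <- gen_poisson_train(20, qty(0, "s"), qty(100, "s"), seed = 1234L)
  iv <- q_mag(isi(tr))
  se <- sd(iv) / sqrt(length(iv))
  expect_lt(abs(mean(iv) - 1 / 20), 3 * se)
})

test_that("cross-correlogram counts single coincidences into the right lag bin", {
  res <- correlogram(list(a = list(strain(0.0, 0, 1)),
                          b = list(strain(0.05, 0, 1))),
                     bin_size = qty(0.1, "s"), max_lag = qty(0.1, "s"))
  centers <- q_mag(res$lag_bin_centers)
  expect_equal(centers, c(-0.1, 0, 0.1))
  # +0.05 falls in the bin centered at 0.1 ([0.05, 0.15))
  expect_equal(res$counts[["a"]][["b"]], c(0, 0, 1))
  # -0.05 is the (included) left edge of the center bin [-0.05, 0.05)
  expect_equal(res$counts[["b"]][["a"]], c(0, 1, 0))
})

test_that("autocorrelogram satisfies symmetry and the n(n-1) pair identity", {
  tr <- gen_poisson_train(10, qty(0, "s"), qty(10, "s"), seed = 77L)
  n <- length(tr$times)
  res <- correlogram(list(u = list(tr)), bin_size = qty(50, "ms"),
                     max_lag = qty(11, "s"))
  cc <- res$counts[["u"]][["u"]]
  expect_equal(sum(cc), n * (n - 1))
  expect_equal(cc, rev(cc))
})

test_that("correlograms match the brute-force oracle exactly", {
  for (seed in c(101L, 202L)) {
    ta <- gen_poisson_train(10, qty(0, "s"), qty(10, "s"), seed = seed)
    tb <- gen_poisson_train(10, qty(0, "s"), qty(10, "s"), seed = seed + 1L)
    res <- correlogram(list(a = list(ta), b = list(tb)),
                       bin_size = qty(20, "ms"), max_lag = qty(0.3, "s"))
    oracle <- oracle_correlogram_pair(q_mag(ta$times), q_mag(tb$times),
                                      0.02, 0.3)
    expect_equal(q_mag(res$lag_bin_centers), oracle$centers, tolerance = 1e-12)
    expect_identical(res$counts[["a"]][["b"]], oracle$counts)
    auto <- oracle_correlogram_pair(q_mag(ta$times), q_mag(ta$times),
                                    0.02, 0.3, auto = TRUE)
    expect_identical(res$counts[["a"]][["a"]], auto$counts)
  }
})

test_that("correlogram rate normalization divides by reference spikes x bin width", {
  ta <- strain(c(0.1, 0.2), 0, 1); tb <- strain(0.15, 0, 1)
  cnt <- correlogram(list(a = list(ta), b = list(tb)), qty(0.1, "s"),
                     qty(0.2, "s"), normalization = "count")
  rate <- correlogram(list(a = list(ta), b = list(tb)), qty(0.1, "s"),
                      qty(0.2, "s"), normalization = "rate")
  expect_equal(rate$counts[["a"]][["b"]], cnt$counts[["a"]][["b"]] / (2 * 0.1))
  expect_error(correlogram(list(a = list(ta), b = list(tb, tb)),
                           qty(0.1, "s"), qty(0.2, "s")), "pairing error")
})

test_that("alignment shifts spikes, drops segments lacking the event", {
  blk <- new_block("b")
  for (i in 0:2) {
    seg <- new_segment(sprintf("s%d", i)); attach_child(blk, seg)
    attach_child(seg, strain(1.2 + i / 10, 0, 2))
    if (i < 2) attach_child(seg, new_event(qty(1.0, "s"), "stim"))
  }
  # a second, later event with the same label: the first is used
  attach_child(blk$segments[[1]], new_event(qty(1.8, "s"), "stim"))
  tbs <- list(s0 = blk$segments[[1]]$spike_trains,
              s1 = blk$segments[[2]]$spike_trains,
              s2 = blk$segments[[3]]$spike_trains)
  expect_warning(out <- align_trains(tbs, "stim"), "s2")
  expect_equal(names(out), c("s0", "s1"))
  expect_equal(q_mag(out$s0[[1]]$times), 0.2, tolerance = 1e-12)
  expect_equal(q_mag(out$s0[[1]]$t_start), -1)
})

test_that("psth recovers a homogeneous rate within 3 SE per bin", {
  rate <- 20; nseg <- 100; bin <- 0.1
  tbs <- lapply(1:nseg, function(i)
    gen_poisson_train(rate, qty(0, "s"), qty(2, "s"), seed = 5000L + i))
  names(tbs) <- sprintf("t%03d", 1:nseg)
  h <- psth(tbs, qty(bin, "s"))
  expect_equal(h$normalization, "rate")
  r <- q_in(h$counts, "Hz")
  se <- sqrt(rate / (nseg * bin)) # Poisson SE of the rate estimate
  expect_true(all(abs(r - rate) < 3 * se))
})

test_that("psth degenerate cases: single spike, empty intersection, alignment", {
  h <- psth(list(s = strain(0.5, 0, 1)), qty(1, "s"))
  expect_equal(q_in(h$counts, "Hz"), 1) # 1 spike / (1 trial x 1 s)
  expect_error(psth(list(a = strain(0.5, 0, 1), b = strain(3, 2.5, 4)),
                    qty(0.1, "s")), "empty intersection")
  blk <- new_block()
  seg <- new_segment("s"); attach_child(blk, seg)
  tr <- strain(1.5, 0, 2); attach_child(seg, tr)
  attach_child(seg, new_event(qty(1, "s"), "stim"))
  ha <- psth(list(s = list(tr)), qty(0.5, "s"), align = "stim")
  expect_equal(q_mag(ha$bin_edges)[1], -1) # support is event-relative
})

test_that("psth is invariant under time unit conversion of its input", {
  tr_s <- strain(c(0.2, 0.7, 1.4), 0, 2, unit = "s")
  tr_ms <- strain(c(200, 700, 1400), 0, 2000, unit = "ms")
  h1 <- psth(list(s = tr_s), qty(0.5, "s"))
  h2 <- psth(list(s = tr_ms), qty(500, "ms"))
  expect_equal(q_in(h1$counts, "Hz"), q_in(h2$counts, "Hz"))
})

test_that("raster rows follow the display mode and alignment drops rows", {
  blocks <- fixture_blocks(seed = 31L, n_segments = 4L)
  prov <- provider_from_state(selection_state(blocks))
  seg1 <- blocks[[1]]$segments[[1]]
  r1 <- raster(seg1$spike_trains, mode = "units_in_one_segment")
  expect_equal(vapply(r1$rows, `[[`, character(1), "label"),
               c("Unit 0", "Unit 1"))
  u0 <- blocks[[1]]$channel_groups[[1]]$units[[1]]
  r2 <- raster(u0$spike_trains, mode = "segments_for_one_unit")
  expect_equal(vapply(r2$rows, `[[`, character(1), "label"),
               sprintf("Segment %d", 0:3))
  expect_error(raster(prov$spike_trains(), mode = "units_in_one_segment"),
               "usage error")
  r3 <- raster(u0$spike_trains, mode = "segments_for_one_unit", align = "stim")
  expect_length(r3$rows, 4)
  # all fixture events sit at 1 s, so aligned times are shifted by -1
  expect_equal(q_mag(r3$rows[[1]]$times), q_mag(r2$rows[[1]]$times) - 1)
})

test_that("spike counts per segment: count vs rate differ by duration", {
  tbs <- list("Seg A" = strain(seq(0.1, 0.9, length.out = 5), 0, 2),
              "Seg B" = strain(numeric(0), 0, 2),
              "Seg C" = strain(seq(0.1, 1.9, length.out = 12), 0, 2))
  cnt <- spike_counts_per_segment(tbs, as_rate = FALSE)
  expect_equal(cnt$value, c(5, 0, 12))
  rt <- spike_counts_per_segment(tbs, as_rate = TRUE)
  expect_equal(rt$value, c(2.5, 0, 6))
  zero <- list(z = strain(numeric(0), 1, 1 + 1e-12))
  zero$z$t_stop <- qty(1, "s") # force zero duration
  expect_warning(out <- spike_counts_per_segment(zero, as_rate = TRUE),
                 "zero duration")
  expect_equal(nrow(out), 0)
})

test_that("waveform stacking preserves order and the mean recovers the template", {
  tmpl <- matrix(sin(seq(0, 2 * pi, length.out = 16)), nrow = 1)
  mk <- function(n, noise, seed) {
    set.seed(seed)
    w <- array(rep(tmpl, each = n), dim = c(n, 1, 16)) +
      array(rnorm(n * 16, 0, noise), dim = c(n, 1, 16))
    tr <- strain(sort(runif(n)), 0, 1.1)
    tr$waveforms <- qty(w, "uV")
    tr
  }
  exact <- mk(10, 0, 1)
  out <- waveforms_by_unit(list(exact))
  expect_equal(as.vector(q_mag(out[["<unassigned>"]]$mean)), as.vector(tmpl))
  noisy <- mk(500, 2, 2)
  res <- waveforms_by_unit(list(noisy))
  se <- 2 / sqrt(500)
  # per-sample bound, Bonferroni-adjusted across the 16 samples tested
  zmax <- qnorm(1 - 0.001 / (2 * 16))
  expect_true(all(abs(q_mag(res[["<unassigned>"]]$mean) - tmpl) < zmax * se))
  expect_warning(empty <- waveforms_by_unit(list(strain(0.5))), "skipped")
  expect_length(empty, 0)
})
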