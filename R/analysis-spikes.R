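# Spike-train statistics: interspike intervals, correlograms, event
# alignment, PSTH, raster data, per-segment counts, waveform averages.
# All binning is half-open [a, b); results carry physical units.

# count x into half-open bins defined by edges (length m+1, increasing)
.bin_count <- function(x, edges) {
  m <- length(edges) - 1L
  if (!length(x)) return(integer(m))
  idx <- findInterval(x, edges) # edges[i] <= x < edges[i+1]
  idx <- idx[x < edges[m + 1L] & idx >= 1L]
  tabulate(idx, nbins = m)
}

#' Binned histogram result
#'
#' @param bin_edges `qty` vector of m+1 strictly increasing edges (time).
#' @param counts length-m vector: spike counts, or rates when
#'   `normalization = "rate"` (then a `qty` in Hz).
#' @param normalization `"count"` or `"rate"`.
#' @param overflow count of values beyond the last edge (ISI histograms).
#' @export
binned_histogram <- function(bin_edges, counts, normalization = "count",
                             overflow = 0L) {
  stopifnot(is_qty(bin_edges))
  if (is.unsorted(q_mag(bin_edges), strictly = TRUE))
    stop("histogram bin edges must be strictly increasing", call. = FALSE)
  structure(list(bin_edges = bin_edges, counts = counts,
                 normalization = normalization, overflow = overflow),
            class = "binned_histogram")
}

#' Interspike intervals of one spike train
#'
#' Successive differences of the (sorted) spike times; duplicate timestamps
#' yield zero intervals. A train with fewer than two spikes gives an empty
#' result.
#'
#' @param train a spike train.
#' @return `qty` vector of intervals, length `max(n - 1, 0)`.
#' @export
isi <- function(train) {
  stopifnot(inherits(train, "SpikeTrain"))
  if (length(train$times) < 2L) return(qty(numeric(0), q_unit(train$times)))
  diff(train$times)
}

#' Interspike interval histogram
#'
#' Intervals are computed within each train and pooled, then counted into
#' half-open bins over `[0, max_interval)`. Intervals at or beyond
#' `max_interval` are reported in the `overflow` field, so total counted plus
#' overflow equals the number of intervals.
#'
#' @param trains list of spike trains (typically one unit across segments).
#' @param bin_size bin width (time `qty`, > 0).
#' @param max_interval upper edge of the histogram (time `qty`).
#' @return A [binned_histogram()] (count normalization).
#' @export
isi_histogram <- function(trains, bin_size, max_interval) {
  # bin in the unit of bin_size so integral-valued intervals (e.g. whole
  # milliseconds) hit their bins without floating-point edge jitter
  unit <- q_unit(bin_size)
  bs <- q_mag(bin_size)
  if (bs <= 0) stop("isi_histogram: bin_size must be positive", call. = FALSE)
  mx <- q_in(max_interval, unit)
  m <- max(1L, floor(round(mx / bs, 9)))
  edges <- seq(0, by = bs, length.out = m + 1L)
  ivals <- unlist(lapply(trains, function(tr) q_in(isi(tr), unit)))
  counts <- .bin_count(ivals, edges)
  binned_histogram(qty(edges, unit), counts, "count",
                   overflow = sum(ivals >= edges[m + 1L]))
}

#' Auto- and cross-correlograms for a set of units
#'
#' For each ordered unit pair (a, b) and each segment, the differences
#' `t_b - t_a` over all spike pairs with `|diff| <= max_lag` are counted into
#' bins centered on zero lag (center bin `[-bin/2, +bin/2)`), then summed
#' over segments. The auto case (a == b) excludes self-pairs, so with
#' `max_lag` covering the whole train the total count is `n (n - 1)`. Rate
#' normalization divides by (number of reference spikes of unit a) x (bin
#' width).
#'
#' @param trains_by_unit named list: unit name -> list of trains, paired
#'   across units by position (one per segment).
#' @param bin_size lag bin width (time `qty`, > 0).
#' @param max_lag largest lag retained (`>= bin_size`).
#' @param normalization `"count"` or `"rate"`.
#' @return A `correlogram_result`: `lag_bin_centers` (`qty`), `counts`
#'   (nested list `counts[[a]][[b]]`), `normalization`, `bin_size`,
#'   `max_lag`.
#' @export
correlogram <- function(trains_by_unit, bin_size, max_lag,
                        normalization = c("count", "rate")) {
  normalization <- match.arg(normalization)
  bs <- .secs(bin_size); ml <- .secs(max_lag)
  if (bs <= 0) stop("correlogram: bin_size must be positive", call. = FALSE)
  if (ml < bs) stop("correlogram: max_lag must be >= bin_size", call. = FALSE)
  nseg <- unique(lengths(trains_by_unit))
  if (length(nseg) != 1L)
    stop("correlogram: pairing error: units have different numbers of trains",
         call. = FALSE)
  K <- ceiling(round(ml / bs - 0.5, 9))
  centers <- seq(-K, K) * bs
  nbin <- 2L * K + 1L
  units <- names(trains_by_unit)
  counts <- list()
  nref <- stats::setNames(numeric(length(units)), units)
  for (a in units) {
    nref[a] <- sum(vapply(trains_by_unit[[a]], function(tr) length(tr$times),
                          integer(1)))
    counts[[a]] <- list()
    for (b in units) {
      acc <- numeric(nbin)
      for (s in seq_len(nseg)) {
        ta <- .secs(trains_by_unit[[a]][[s]]$times)
        tb <- .secs(trains_by_unit[[b]][[s]]$times)
        if (!length(ta) || !length(tb)) next
        d <- as.vector(outer(tb, ta, "-"))
        if (identical(a, b)) {
          # drop self-pairs (same spike index), not distinct coincident spikes
          n <- length(ta)
          d <- d[-(seq_len(n) + (seq_len(n) - 1L) * n)]
        }
        d <- d[abs(d) <= ml]
        k <- floor(d / bs + 0.5)
        k <- k[abs(k) <= K]
        acc <- acc + tabulate(k + K + 1L, nbins = nbin)
      }
      counts[[a]][[b]] <- acc
    }
  }
  if (normalization == "rate")
    for (a in units)
      for (b in units)
        counts[[a]][[b]] <- counts[[a]][[b]] / (nref[a] * bs)
  structure(list(lag_bin_centers = qty(centers, "s"), counts = counts,
                 normalization = normalization,
                 bin_size = qty(bs, "s"), max_lag = qty(ml, "s")),
            class = "correlogram_result")
}

.as_train_list <- function(x) if (inherits(x, "SpikeTrain")) list(x) else x

.first_event_time <- function(events, label) {
  tt <- vapply(events, function(ev)
    if (identical(ev$label, label)) .secs(ev$time) else NA_real_, numeric(1))
  tt <- tt[!is.na(tt)]
  if (!length(tt)) return(NULL)
  min(tt) # two same-label events: the first in time wins
}

.shift_train <- function(tr, t0) {
  out <- new_spike_train(times = qty(.secs(tr$times) - t0, "s"),
                         t_start = qty(.secs(tr$t_start) - t0, "s"),
                         t_stop = qty(.secs(tr$t_stop) - t0, "s"),
                         waveforms = tr$waveforms,
                         sampling_rate = tr$sampling_rate)
  out$unit_ref <- tr$unit_ref
  out
}

#' Align spike trains on a labeled event
#'
#' Shifts every train of each segment so that the segment's event with the
#' given label sits at time 0; `t_start`/`t_stop` shift consistently.
#' Segments lacking the event are dropped with a warning. When a segment has
#' several events with the label, the earliest is used.
#'
#' @param trains_by_segment named list: segment name -> train or list of
#'   trains.
#' @param event_label event label to align on.
#' @param events_by_segment optional named list segment name -> list of
#'   events; when omitted the events are taken from each train's segment
#'   back reference.
#' @return Named list of the same shape with shifted trains.
#' @export
align_trains <- function(trains_by_segment, event_label,
                         events_by_segment = NULL) {
  out <- list()
  for (key in names(trains_by_segment)) {
    trs <- .as_train_list(trains_by_segment[[key]])
    evs <- if (!is.null(events_by_segment)) events_by_segment[[key]]
           else if (length(trs) && !is.null(trs[[1]]$segment_ref))
             lapply(trs[[1]]$segment_ref$events, materialize)
    t0 <- if (length(evs)) .first_event_time(evs, event_label)
    if (is.null(t0)) {
      warning(sprintf("align_trains: segment '%s' has no event labeled '%s'; dropped",
                      key, event_label), call. = FALSE)
      next
    }
    out[[key]] <- lapply(trs, .shift_train, t0 = t0)
  }
  out
}

#' Peristimulus time histogram
#'
#' Pools spikes over segments (trials) within the intersection of the trial
#' windows and returns a trial-averaged rate: pooled count per bin divided by
#' (number of segments x bin width). With `align` given, trains are first
#' aligned on that event ([align_trains()]), so the histogram support is in
#' event-relative time.
#'
#' @param trains_by_segment named list: segment name -> train(s).
#' @param bin_size bin width (time `qty`, > 0).
#' @param align optional event label to align on before binning.
#' @param events_by_segment optional events (see [align_trains()]).
#' @return A [binned_histogram()] with `normalization = "rate"`; `counts` is
#'   a `qty` in Hz, and the raw pooled counts are kept in `$pooled_counts`.
#' @export
psth <- function(trains_by_segment, bin_size, align = NULL,
                 events_by_segment = NULL) {
  bs <- .secs(bin_size)
  if (bs <= 0) stop("psth: bin_size must be positive", call. = FALSE)
  if (!is.null(align))
    trains_by_segment <- align_trains(trains_by_segment, align,
                                      events_by_segment)
  if (!length(trains_by_segment))
    stop("psth: no segments survive alignment", call. = FALSE)
  all_trains <- unlist(lapply(trains_by_segment, .as_train_list),
                       recursive = FALSE)
  w0 <- max(vapply(all_trains, function(tr) .secs(tr$t_start), numeric(1)))
  w1 <- min(vapply(all_trains, function(tr) .secs(tr$t_stop), numeric(1)))
  m <- floor(round((w1 - w0) / bs, 9))
  if (w1 <= w0 || m < 1L)
    stop("psth: trial windows have empty intersection", call. = FALSE)
  edges <- w0 + seq(0, m) * bs
  pooled <- unlist(lapply(all_trains, function(tr) .secs(tr$times)))
  counts <- .bin_count(pooled, edges)
  nseg <- length(trains_by_segment)
  h <- binned_histogram(qty(edges, "s"), qty(counts / (nseg * bs), "Hz"),
                        normalization = "rate")
  h$pooled_counts <- counts
  h$n_trials <- nseg
  h
}

#' Raster data: spike times row by row
#'
#' Two display modes: several units within one segment (rows labeled by
#' unit), or one unit across several segments (rows labeled by segment).
#' With `align` given, times are event-relative and segments lacking the
#' event are dropped as in [align_trains()].
#'
#' @param trains list of spike trains, mode-consistent.
#' @param mode `"units_in_one_segment"` or `"segments_for_one_unit"`.
#' @param align optional event label.
#' @return A `raster_data`: `rows` (list of `list(label, times)`) and
#'   `alignment`.
#' @export
raster <- function(trains, mode = c("units_in_one_segment",
                                    "segments_for_one_unit"),
                   align = NULL) {
  mode <- match.arg(mode)
  if (!length(trains)) return(structure(list(rows = list(), alignment = align),
                                        class = "raster_data"))
  segs <- lapply(trains, function(tr) tr$segment_ref)
  units <- lapply(trains, function(tr) tr$unit_ref)
  if (mode == "units_in_one_segment") {
    for (s in segs) if (!identical(s, segs[[1]]))
      stop("raster: usage error: mode 'units_in_one_segment' requires trains from a single segment",
           call. = FALSE)
    labels <- vapply(units, function(u) if (is.null(u)) UNASSIGNED_KEY else u$name,
                     character(1))
  } else {
    for (u in units) if (!identical(u, units[[1]]))
      stop("raster: usage error: mode 'segments_for_one_unit' requires trains of a single unit",
           call. = FALSE)
    labels <- vapply(segs, function(s) if (is.null(s)) UNASSIGNED_KEY else s$name,
                     character(1))
  }
  rows <- list()
  for (i in seq_along(trains)) {
    tr <- trains[[i]]
    t0 <- 0
    if (!is.null(align)) {
      evs <- if (!is.null(tr$segment_ref)) lapply(tr$segment_ref$events, materialize)
      t0 <- if (length(evs)) .first_event_time(evs, align)
      if (is.null(t0)) {
        warning(sprintf("raster: row '%s' has no event labeled '%s'; dropped",
                        labels[i], align), call. = FALSE)
        next
      }
    }
    rows <- c(rows, list(list(label = labels[i],
                              times = qty(.secs(tr$times) - t0, "s"))))
  }
  structure(list(rows = rows, alignment = align), class = "raster_data")
}

#' Spike counts (or rates) of one unit over segments
#'
#' @param unit_trains_by_segment named list: segment name -> train (one
#'   unit's train in that segment).
#' @param as_rate divide each count by its segment duration (Hz). Segments
#'   with zero duration are excluded with a warning in rate mode.
#' @return `data.frame(segment, value)` in segment order.
#' @export
spike_counts_per_segment <- function(unit_trains_by_segment, as_rate = FALSE) {
  labels <- character(0); values <- numeric(0)
  for (key in names(unit_trains_by_segment)) {
    trs <- .as_train_list(unit_trains_by_segment[[key]])
    n <- sum(vapply(trs, function(tr) length(tr$times), integer(1)))
    if (as_rate) {
      dur <- .secs(trs[[1]]$t_stop) - .secs(trs[[1]]$t_start)
      if (dur <= 0) {
        warning(sprintf("spike_counts_per_segment: segment '%s' has zero duration; excluded",
                        key), call. = FALSE)
        next
      }
      values <- c(values, n / dur)
    } else {
      values <- c(values, n)
    }
    labels <- c(labels, key)
  }
  data.frame(segment = labels, value = values, stringsAsFactors = FALSE)
}

#' Stacked and mean spike waveforms per unit
#'
#' Waveform arrays (spike x channel x sample) are stacked across each unit's
#' trains, preserving spike order; the mean is taken over spikes per channel
#' and sample. Trains without waveforms are skipped with a warning.
#'
#' @param trains list of spike trains with unit references.
#' @return Named list: unit name -> `list(waveforms, mean)`, both `qty`.
#' @export
waveforms_by_unit <- function(trains) {
  groups <- list()
  for (tr in trains) {
    if (is.null(tr$waveforms)) {
      warning("waveforms_by_unit: train without waveforms skipped", call. = FALSE)
      next
    }
    key <- if (is.null(tr$unit_ref)) UNASSIGNED_KEY else tr$unit_ref$name
    groups[[key]] <- c(groups[[key]], list(tr$waveforms))
  }
  out <- list()
  for (key in names(groups)) {
    ws <- groups[[key]]
    unit <- q_unit(ws[[1]])
    mats <- lapply(ws, function(w) q_in(w, unit))
    d <- dim(mats[[1]])[2:3]
    total <- sum(vapply(mats, function(m) dim(m)[1], integer(1)))
    stacked <- array(0, dim = c(total, d[1], d[2]))
    at <- 0L
    for (m in mats) {
      n <- dim(m)[1]
      if (n) stacked[at + seq_len(n), , ] <- m
      at <- at + n
    }
    out[[key]] <- list(waveforms = qty(stacked, unit),
                       mean = qty(apply(stacked, c(2, 3), mean), unit))
  }
  out
}
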