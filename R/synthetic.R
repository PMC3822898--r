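# Deterministic synthetic data with known ground truth: homogeneous and
# stimulus-modulated Poisson spike trains, sinusoid-plus-noise analog
# signals, and full annotated hierarchies. Each object draws from its own
# seed derived from the dataset seed and the object's structural path, so any
# single object can be regenerated in isolation and equal generator specs
# give equal datasets.

.derive_seed <- function(base_seed, path) {
  s <- digest::digest2int(sprintf("%d|%s", as.integer(base_seed), path))
  s <- abs(s) %% .Machine$integer.max
  if (s == 0L) 1L else s
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Homogeneous Poisson spike train
#'
#' Spike count drawn Poisson with mean `rate x duration`, times uniform over
#' `[t_start, t_stop)`, sorted. Identical seeds give identical trains.
#'
#' @param rate firing rate in Hz (number or `qty`), `>= 0`.
#' @param t_start,t_stop window bounds (time `qty`).
#' @param seed integer seed.
#' @return A spike train.
#' @export
gen_poisson_train <- function(rate, t_start = qty(0, "s"), t_stop = qty(1, "s"),
                              seed = 1L) {
  r <- if (is_qty(rate)) .hz(rate) else rate
  stopifnot(r >= 0)
  t0 <- .secs(t_start); t1 <- .secs(t_stop)
  stopifnot(t0 < t1)
  times <- .with_seed(seed, {
    n <- stats::rpois(1, r * (t1 - t0))
    sort(stats::runif(n, t0, t1))
  })
  new_spike_train(qty(times, "s"), qty(t0, "s"), qty(t1, "s"))
}

#' Gaussian-bump rate profile used by the modulated generator
#' @param t times in seconds.
#' @param baseline,peak rates in Hz.
#' @param center,width bump center and width in seconds.
#' @export
bump_rate <- function(t, baseline, peak, center, width) {
  baseline + (peak - baseline) * exp(-(t - center)^2 / (2 * width^2))
}

#' Stimulus-modulated (inhomogeneous Poisson) spike train
#'
#' Rate profile `rate(t) = baseline + (peak - baseline) exp(-(t-center)^2 /
#' (2 width^2))`, realized by thinning: candidates are drawn from a
#' homogeneous process at the peak rate and kept with probability
#' `rate(t)/peak`.
#'
#' @param baseline,peak rates in Hz, `peak >= baseline >= 0`.
#' @param center,width bump center and width (time `qty`).
#' @param t_start,t_stop window bounds (time `qty`).
#' @param seed integer seed.
#' @return A spike train.
#' @export
gen_modulated_train <- function(baseline, peak, center, width,
                                t_start = qty(0, "s"), t_stop = qty(2, "s"),
                                seed = 1L) {
  b <- if (is_qty(baseline)) .hz(baseline) else baseline
  p <- if (is_qty(peak)) .hz(peak) else peak
  stopifnot(p >= b, b >= 0)
  ctr <- .secs(center); wd <- .secs(width)
  t0 <- .secs(t_start); t1 <- .secs(t_stop)
  stopifnot(t0 < t1)
  times <- .with_seed(seed, {
    n <- stats::rpois(1, p * (t1 - t0))
    cand <- sort(stats::runif(n, t0, t1))
    if (p > 0) {
      keep <- stats::runif(n) < bump_rate(cand, b, p, ctr, wd) / p
      cand[keep]
    } else numeric(0)
  })
  new_spike_train(qty(times, "s"), qty(t0, "s"), qty(t1, "s"))
}

#' Sinusoid-plus-noise analog signal
#'
#' Sum of sinusoidal components plus white Gaussian noise, sampled regularly.
#' Component frequencies must stay below the Nyquist frequency.
#'
#' @param components list of `c(freq_hz, amplitude)` pairs.
#' @param noise_sd Gaussian noise standard deviation.
#' @param sampling_rate `qty` (Hz) or number.
#' @param duration seconds (or time `qty`).
#' @param seed integer seed.
#' @param unit sample unit (default `"uV"`).
#' @return An analog signal.
#' @export
gen_signal <- function(components = list(), noise_sd = 0,
                       sampling_rate = qty(1, "kHz"), duration = 1,
                       seed = 1L, unit = "uV") {
  fs <- if (is_qty(sampling_rate)) .hz(sampling_rate) else sampling_rate
  dur <- if (is_qty(duration)) .secs(duration) else duration
  for (cmp in components)
    if (cmp[1] >= fs / 2)
      stop(sprintf("gen_signal: component at %g Hz is at or above the Nyquist frequency (%g Hz)",
                   cmp[1], fs / 2), call. = FALSE)
  n <- floor(dur * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (cmp in components) x <- x + cmp[2] * sin(2 * pi * cmp[1] * t)
  if (noise_sd > 0) x <- x + .with_seed(seed, stats::rnorm(n, 0, noise_sd))
  new_analog_signal(qty(x, unit), qty(fs, "Hz"), qty(0, "s"))
}

# biphasic spike waveform template on `n_samples` points
.waveform_template <- function(n_samples = 32L, amplitude = 80) {
  t <- seq(0, 1, length.out = n_samples)
  amplitude * (-exp(-((t - 0.3) / 0.08)^2) + 0.45 * exp(-((t - 0.55) / 0.15)^2))
}

#' Describe a synthetic dataset
#'
#' The defaults describe the study conditions used throughout the package's
#' tests: one block of 9 two-second trials whose `stimulus` annotation cycles
#' over three labels, one channel group with 2 tetrode channels and 2 units,
#' a `stim` event at 1 s in every trial, stimulus-locked modulated firing
#' (baseline 5 Hz, peak 40 Hz, 100 ms bump at the event) and a 50 Hz + 120 Hz
#' sinusoid LFP in noise at 1 kHz sampling.
#'
#' @param seed dataset seed; every contained object derives its own seed from
#'   it and its structural path.
#' @param n_blocks,n_segments,n_channel_groups,n_channels,n_units counts.
#' @param segment_duration seconds per trial.
#' @param stimulus_labels recycled over segments as the `stimulus` annotation.
#' @param event_time `stim` event time within each segment (s).
#' @param baseline_hz,peak_hz,bump_width_s firing-rate profile per unit.
#' @param signal_components,signal_noise_sd,signal_fs_hz LFP parameters.
#' @param waveforms attach template-plus-noise waveforms to spike trains.
#' @return A `generator_spec` (plain list).
#' @export
generator_spec <- function(seed = 1L, n_blocks = 1L, n_segments = 9L,
                           n_channel_groups = 1L, n_channels = 2L,
                           n_units = 2L, segment_duration = 2,
                           stimulus_labels = c("A", "B", "C"),
                           event_time = 1,
                           baseline_hz = 5, peak_hz = 40, bump_width_s = 0.1,
                           signal_components = list(c(50, 20), c(120, 8)),
                           signal_noise_sd = 5, signal_fs_hz = 1000,
                           waveforms = TRUE) {
  structure(as.list(environment()), class = "generator_spec")
}

#' Build a synthetic dataset from a generator spec
#'
#' Produces a hierarchy that passes [validate()] with zero violations:
#' stimulus labels cycle over segments, each unit fires a stimulus-locked
#' modulated train in every segment (with biphasic waveforms when requested),
#' each channel carries a sinusoid-plus-noise signal, and every segment has
#' one `stim` event at the stated time. Equal specs give equal datasets.
#'
#' @param spec a [generator_spec()].
#' @return List of blocks.
#' @export
build_dataset <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  blocks <- list()
  for (bi in seq_len(spec$n_blocks)) {
    bpath <- sprintf("block%d", bi - 1L)
    blk <- new_block(sprintf("Block %d", bi - 1L),
                     annotations = list(origin = "synthetic"))
    units <- list(); channels <- list()
    for (gi in seq_len(spec$n_channel_groups)) {
      cg <- new_channel_group(sprintf("Group %d", gi - 1L))
      attach_child(blk, cg)
      for (ci in seq_len(spec$n_channels)) {
        ch <- new_channel(sprintf("Channel %d", ci - 1L), index = ci - 1L)
        attach_child(cg, ch)
        channels <- c(channels, list(ch))
      }
      for (ui in seq_len(spec$n_units)) {
        u <- new_unit(sprintf("Unit %d", ui - 1L))
        attach_child(cg, u)
        units <- c(units, list(u))
      }
    }
    for (si in seq_len(spec$n_segments)) {
      lab <- spec$stimulus_labels[((si - 1L) %% length(spec$stimulus_labels)) + 1L]
      seg <- new_segment(sprintf("Segment %d", si - 1L),
                         annotations = list(stimulus = lab))
      attach_child(blk, seg)
      spath <- sprintf("%s/seg%d", bpath, si - 1L)
      attach_child(seg, new_event(qty(spec$event_time, "s"), "stim"))
      for (ui in seq_along(units)) {
        tr <- gen_modulated_train(
          baseline = spec$baseline_hz, peak = spec$peak_hz,
          center = qty(spec$event_time, "s"), width = qty(spec$bump_width_s, "s"),
          t_start = qty(0, "s"), t_stop = qty(spec$segment_duration, "s"),
          seed = .derive_seed(spec$seed, sprintf("%s/unit%d/train", spath, ui - 1L)))
        if (spec$waveforms) {
          nspk <- length(tr$times)
          tmpl <- .waveform_template()
          wseed <- .derive_seed(spec$seed, sprintf("%s/unit%d/wf", spath, ui - 1L))
          w <- .with_seed(wseed,
                          array(rep(tmpl, each = nspk), dim = c(nspk, 1, length(tmpl))) +
                            array(stats::rnorm(nspk * length(tmpl), 0, 4),
                                  dim = c(nspk, 1, length(tmpl))))
          tr$waveforms <- qty(w, "uV")
          tr$sampling_rate <- qty(20, "kHz")
        }
        attach_child(seg, tr)
        attach_child(units[[ui]], tr)
      }
      for (ci in seq_along(channels)) {
        sig <- gen_signal(components = spec$signal_components,
                          noise_sd = spec$signal_noise_sd,
                          sampling_rate = spec$signal_fs_hz,
                          duration = spec$segment_duration,
                          seed = .derive_seed(spec$seed,
                                              sprintf("%s/chan%d/sig", spath, ci - 1L)))
        attach_child(seg, sig)
        attach_child(channels[[ci]], sig)
      }
    }
    blocks <- c(blocks, list(blk))
  }
  blocks
}
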