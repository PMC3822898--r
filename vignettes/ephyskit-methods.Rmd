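---
title: "ephyskit: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ephyskit: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephyskit)
```

This vignette documents the scientific conventions the package commits to —
the statistics it computes and how, the knobs that matter, what the
synthetic generators do and do not emulate, and the design decisions taken
where more than one reasonable choice existed.

## The object model and its assumptions

A recording is a tree: a `Block` owns `Segment`s (contiguous recording
windows, usually experimental trials) and `ChannelGroup`s (an electrode or
tetrode), which own `Channel`s and `Unit`s (putative neurons from spike
sorting). Data objects hang off segments: `SpikeTrain`s (additionally owned
by a unit), `AnalogSignal`s (optionally tied to a channel), `Event`s and
`Epoch`s. Two structural assumptions are deliberate:

* **Containment is a tree, not a DAG.** A data object belongs to at most one
  segment and at most one unit/channel. This keeps selections — which address
  objects purely by their position under a block — unambiguous.
* **Spike times may tie.** Real sorters emit simultaneous spikes across and
  occasionally within units; ties are kept in stable order and produce zero
  interspike intervals rather than an error.

All numeric payloads are quantities (magnitude plus unit over time,
frequency and voltage dimensions). Every analysis converts internally, so
feeding times in `ms` instead of `s` changes no rate output; the test suite
asserts this invariance.

**Interval convention.** Every slicing and binning operation in the package
uses half-open intervals `[a, b)`. This makes bin contents a partition (no
double counting at edges) and makes the correlogram symmetry identity exact
up to lags that fall exactly on a bin edge — a measure-zero event for
continuous data. One knock-on choice: the interspike-interval histogram bins
in the unit of its `bin_size` argument, so interval values that are exact in
that unit (whole milliseconds, say) land in the intended bin instead of
straddling an edge after conversion to seconds.

## Analyses

**Correlograms.** For an ordered unit pair (a, b), each segment contributes
the differences `t_b − t_a` over all spike pairs with `|Δ| ≤ max_lag`,
counted into bins *centered on zero* (the center bin is `[−bin/2, +bin/2)`);
segment counts are summed. The auto case excludes self-pairs only (same
spike index), so with `max_lag` covering the whole train the total count is
exactly `n(n−1)` — a combinatorial identity the tests verify, along with
exact equality against a brute-force double loop. Rate normalization divides
by (number of reference spikes of unit a) × (bin width); the reference-spike
convention is a documented choice, as the literature uses several.

**PSTH.** Spikes are pooled over trials within the *intersection* of the
trial windows (trailing partial bins are dropped) and the rate is
`pooled count / (n_trials × bin width)`. The union-with-varying-trial-count
alternative is out of scope. Event alignment shifts each trial so the first
event with the requested label sits at 0; trials lacking the event are
dropped with a warning rather than silently kept misaligned.

**Spike density estimation.** The rate estimate is a Gaussian kernel sum
over the pooled spikes, normalized per trial,
`λ̂(t) = (1/n_trials) Σᵢ k_w(t − tᵢ)` with
`k_w(t) = exp(−t²/2w²)/(√(2π) w)`. The bandwidth is chosen by minimizing the
leave-one-out cost in its closed form

```
Ĉ(w) = Σ_{i,j} k_{√2·w}(tᵢ − tⱼ) − 2 Σ_{i≠j} k_w(tᵢ − tⱼ),
```

which equals `∫λ̂² dt − 2 Σᵢ λ̂^(−i)(tᵢ)` because the convolution of two
Gaussian kernels of width `w` is one of width `√2·w`. The tests confirm the
closed form against direct numerical integration to better than `1e-6`
relative. The candidate grid is 50 log-spaced widths between 1/100 and 1/2
of the data span: log spacing matches the scale-free nature of the problem,
the span-derived bounds adapt to any recording length, and a deterministic
grid (ties broken toward the smaller width) is reproducible and
oracle-checkable, unlike an iterative optimizer with data-dependent
stopping. When several units are estimated, each unit's bandwidth is
optimized independently on its own pooled spikes. The evaluation grid is
padded by 3 bandwidths so edge kernel mass is not clipped; each unit's
estimate integrates to its spikes-per-trial within 1% on such a grid.

**Spectrograms.** Short-time Fourier power via `signal::specgram`, rescaled
to a one-sided power spectral density (`unit²/Hz`): `|S|²/(Fs·Σw²)` with all
non-DC bins doubled. Summing `PSD × Δf` over frequencies then recovers the
windowed signal variance (Parseval), which the tests check to 10% on white
noise. Defaults: Hann taper, 50% overlap. The Hann taper spreads a pure DC
or tone over adjacent bins by design; the rectangular taper is available
when exact bin concentration matters.

## Selections, filters and providers

Selections serialize to canonical JSON — keys sorted, index lists sorted and
de-duplicated — so equal selections are byte-identical, which in turn makes
them usable as cache-key material. Paths are stored as given; relocating
data is the caller's concern.

Filters are one-function R sources. Two decisions are safety- rather than
science-driven: filter bodies evaluate in a restricted environment (basic
control flow, math, list tools, the quantity helpers — no filesystem or
network), and a filter that throws is *skipped with a warning, leaving the
list unchanged*, because a broken filter that silently hides all data is the
worst failure mode in an exploratory tool. Annotation predicates use strict,
type-sensitive equality (integer and double both count as numeric) so
heterogeneous annotations behave predictably.

Providers include a spike train only when both its segment *and* its unit
are selected — the connected-subgraph reading: an unselected unit's trains
do not leak in through a selected segment. Data objects with no unit or
channel are returned under the sentinel key `"<unassigned>"` rather than
dropped. Traversal order is fixed (file, block, group, unit/channel, segment
index order), so all outputs are deterministic. Lazy loading is per data
object: the container tree is always complete; arrays are read on first
touch, exactly once, with a global counter exposing the contract for tests.

## Plugin execution and the result cache

The three execution modes are semantically equivalent and the tests assert
deep equality of their results on a deterministic plugin; in-process
execution is merely faster because loaded data is shared. Subprocess
transport serializes the provider snapshot and parameters to a fresh R
process — no shared state, so concurrent plugins cannot interfere. The
standalone bundle (`run` script, selection files, `params.json`,
`manifest.json`) decouples execution entirely for batch or server use.

The cache key digests (canonical selection JSON, canonicalized parameters,
plugin name, plugin *file content digest*). Including the content digest
means editing a plugin can never serve stale results. Cached values are
restricted to a serializable family (numeric/integer/logical/character
arrays, quantities, data frames, nested lists, and the analysis result
structures); anything else is rejected with guidance, keeping cache files
portable across sessions and machines.

## File formats

* `native-h5`: one HDF5 group per container, datasets for
  times/samples/waveforms, attributes for names, units, window bounds and
  `ann_<type>_`-prefixed annotations; a root `format_version` attribute
  versions the layout. Read/write, lazy-capable; round trips are deep-equal
  including units and waveforms.
* `ascii-spikes`: one block per plain-text file, `#` headers carrying
  per-train windows, data lines `segment<TAB>unit<TAB>time_s` printed at
  nanosecond precision. Human-readable and diffable; it round-trips spike
  data only (no signals, waveforms or annotations), and at most one train
  per (segment, unit) pair.

## The synthetic generators

`build_dataset()` emulates a stimulus experiment: trials annotated with a
cycling `stimulus` label, a `stim` event at a fixed time in every trial,
each unit firing an inhomogeneous Poisson train with rate
`baseline + (peak − baseline)·exp(−(t−center)²/2·width²)` realized by
thinning (transparent to verify, if slightly wasteful), sinusoid-plus-noise
signals per channel, and biphasic template-plus-noise waveforms. Defaults: 9
trials of 2 s, labels A/B/C, event at 1 s, 5 Hz baseline with a 40 Hz peak
and 100 ms bump width, 50+120 Hz components in noise at 1 kHz — magnitudes
typical of a cortical stimulus-response protocol, chosen once.

Every object derives its own seed from the dataset seed and the object's
structural path, so equal specs give equal datasets (deep model equality;
the text serialization is byte-identical — HDF5 files embed creation
timestamps in object headers, so byte identity is asserted on the text
format) and any single object can be regenerated in isolation.

What the generators do **not** emulate — and hence what green tests do not
establish about real data: refractory periods and bursting (thinned Poisson
has neither), spike-sorting errors and drift, correlated noise or 1/f LFP
spectra, non-Gaussian waveform variability, and non-stationarity across
trials. The statistical recovery tests certify the estimators against their
own model class, not against biology.

## Problem sizes and numerical tolerances in the test suite

The suite runs on synthetic data sized for tight statistical bounds at
interactive runtimes: 10 Poisson train pairs (10 Hz × 10 s) for exact
correlogram oracle equality; 50 spikes × 50 candidate widths for the
bandwidth cost identity at `1e-6` relative (numerical integration on a
40 000-point grid); ~2 000 spikes for the optimizer-versus-dense-grid check;
100–200 trials for PSTH/density recovery at 3 standard errors per
near-independent probe point; 100 randomized selections; 200 randomized
cache-key perturbations. Statistical assertions over many simultaneous
comparisons (e.g. all samples of a mean waveform) use a Bonferroni-adjusted
bound rather than a raw per-point 3σ, which would false-alarm by
construction.

## Known limitations

* Units cover time, frequency and voltage — the dimensions the model needs —
  not a general unit system.
* The ascii-spikes format is intentionally lossy (spike data only).
* `psth()` requires overlapping trial windows; there is no varying-`n`
  union mode.
* Selections address containers, not individual data objects.
* The subprocess mode requires the package to be installed where the child
  R process can load it.
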