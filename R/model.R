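# Hierarchical object model: Block > {Segment, ChannelGroup}; ChannelGroup >
# {Channel, Unit}; data objects (SpikeTrain, AnalogSignal, Event, Epoch) hang
# off a Segment, with SpikeTrain additionally owned by a Unit and AnalogSignal
# optionally tied to a Channel. All parent/child links are bidirectional,
# which is why the model uses reference semantics (R6).

#' @import R6
NULL

EphysObject <- R6::R6Class("EphysObject",
  public = list(
    name = NULL,
    annotations = NULL,
    selected = FALSE, # membership flag set by selection resolution
    initialize = function(name = "", annotations = list()) {
      self$name <- name
      self$annotations <- annotations
    }
  )
)

Block <- R6::R6Class("Block", inherit = EphysObject,
  public = list(
    segments = NULL,
    channel_groups = NULL,
    source = NULL, # list(path, io, index) once read from / written to a file
    initialize = function(name = "", annotations = list()) {
      super$initialize(name, annotations)
      self$segments <- list()
      self$channel_groups <- list()
    }
  )
)

Segment <- R6::R6Class("Segment", inherit = EphysObject,
  public = list(
    parent = NULL,
    index_in_block = NULL,
    spike_trains = NULL,
    analog_signals = NULL,
    events = NULL,
    epochs = NULL,
    initialize = function(name = "", annotations = list()) {
      super$initialize(name, annotations)
      self$spike_trains <- list()
      self$analog_signals <- list()
      self$events <- list()
      self$epochs <- list()
    }
  )
)

ChannelGroup <- R6::R6Class("ChannelGroup", inherit = EphysObject,
  public = list(
    parent = NULL,
    channels = NULL,
    units = NULL,
    initialize = function(name = "", annotations = list()) {
      super$initialize(name, annotations)
      self$channels <- list()
      self$units <- list()
    }
  )
)

Channel <- R6::R6Class("Channel", inherit = EphysObject,
  public = list(
    parent = NULL,
    index = NULL,
    initialize = function(name = "", index = 0L, annotations = list()) {
      super$initialize(name, annotations)
      self$index <- as.integer(index)
    }
  )
)

Unit <- R6::R6Class("Unit", inherit = EphysObject,
  public = list(
    parent = NULL,
    spike_trains = NULL,
    initialize = function(name = "", annotations = list()) {
      super$initialize(name, annotations)
      self$spike_trains <- list()
    }
  )
)

SpikeTrain <- R6::R6Class("SpikeTrain",
  public = list(
    times = NULL,          # qty, time dimension
    t_start = NULL,
    t_stop = NULL,
    waveforms = NULL,      # qty 3-d array (spike x channel x sample) or NULL
    sampling_rate = NULL,  # qty (Hz) or NULL
    unit_ref = NULL,
    segment_ref = NULL,
    initialize = function(times, t_start, t_stop, waveforms = NULL,
                          sampling_rate = NULL) {
      stopifnot(is_qty(times), is_qty(t_start), is_qty(t_stop))
      self$times <- times
      self$t_start <- t_start
      self$t_stop <- t_stop
      self$waveforms <- waveforms
      self$sampling_rate <- sampling_rate
    }
  )
)

AnalogSignal <- R6::R6Class("AnalogSignal",
  public = list(
    samples = NULL,        # qty, e.g. uV
    sampling_rate = NULL,  # qty, Hz
    t_start = NULL,        # qty, time
    channel_ref = NULL,
    segment_ref = NULL,
    initialize = function(samples, sampling_rate, t_start = qty(0, "s")) {
      stopifnot(is_qty(samples), is_qty(sampling_rate), is_qty(t_start))
      self$samples <- samples
      self$sampling_rate <- sampling_rate
      self$t_start <- t_start
    }
  )
)

Event <- R6::R6Class("Event",
  public = list(
    time = NULL,
    label = NULL,
    segment_ref = NULL,
    initialize = function(time, label) {
      stopifnot(is_qty(time))
      self$time <- time
      self$label <- label
    }
  )
)

Epoch <- R6::R6Class("Epoch",
  public = list(
    time = NULL,
    duration = NULL,
    label = NULL,
    segment_ref = NULL,
    initialize = function(time, duration, label) {
      stopifnot(is_qty(time), is_qty(duration))
      self$time <- time
      self$duration <- duration
      self$label <- label
    }
  )
)

#' Construct model objects
#'
#' Constructors for the container and data objects of the electrophysiology
#' object model. Containers (block, segment, channel group, channel, unit)
#' carry a name and an annotation map; data objects carry units-aware arrays.
#' Children are linked to parents with [attach_child()].
#'
#' @param name object name.
#' @param annotations named list of scalar, string or flat numeric values.
#' @return An R6 model object.
#' @name model-constructors
NULL

#' @rdname model-constructors
#' @export
new_block <- function(name = "", annotations = list()) Block$new(name, annotations)

#' @rdname model-constructors
#' @export
new_segment <- function(name = "", annotations = list()) Segment$new(name, annotations)

#' @rdname model-constructors
#' @export
new_channel_group <- function(name = "", annotations = list()) ChannelGroup$new(name, annotations)

#' @rdname model-constructors
#' @param index integer channel index (unique within its group).
#' @export
new_channel <- function(name = "", index = 0L, annotations = list()) Channel$new(name, index, annotations)

#' @rdname model-constructors
#' @export
new_unit <- function(name = "", annotations = list()) Unit$new(name, annotations)

#' @rdname model-constructors
#' @param times spike times as a time `qty` vector, sorted ascending.
#' @param t_start,t_stop recording window bounds (time `qty` scalars).
#' @param waveforms optional `qty` 3-d array (spike x channel x sample).
#' @param sampling_rate optional waveform sampling rate (`qty`, Hz).
#' @export
new_spike_train <- function(times, t_start, t_stop, waveforms = NULL,
                            sampling_rate = NULL) {
  SpikeTrain$new(times, t_start, t_stop, waveforms, sampling_rate)
}

#' @rdname model-constructors
#' @param samples sample values as a `qty` vector (e.g. uV).
#' @export
new_analog_signal <- function(samples, sampling_rate, t_start = qty(0, "s")) {
  AnalogSignal$new(samples, sampling_rate, t_start)
}

#' @rdname model-constructors
#' @param time event/epoch time (`qty`).
#' @param label event/epoch label, nonempty string.
#' @export
new_event <- function(time, label) Event$new(time, label)

#' @rdname model-constructors
#' @param duration epoch duration (`qty` >= 0).
#' @export
new_epoch <- function(time, duration, label) Epoch$new(time, duration, label)

.is_container <- function(x) {
  inherits(x, c("Block", "Segment", "ChannelGroup", "Channel", "Unit"))
}

#' Attach a child object to a parent container
#'
#' Establishes the bidirectional parent/child link: the child is appended to
#' the parent's list for that relation (or inserted at `at`) and its back
#' reference is set. A child that already has a parent for the same relation
#' must be detached first.
#'
#' Supported relations: block>segment, block>channel_group,
#' channel_group>channel, channel_group>unit, segment>spike_train,
#' segment>analog_signal, segment>event, segment>epoch, unit>spike_train,
#' channel>analog_signal (sets the signal's channel reference).
#'
#' @param parent a container object.
#' @param child the object to attach.
#' @param at optional 1-based insert position (default: append).
#' @return `parent`, invisibly.
#' @export
attach_child <- function(parent, child, at = NULL) {
  ins <- function(lst, x, at) {
    if (is.null(at) || at > length(lst)) return(c(lst, list(x)))
    append(lst, list(x), after = at - 1L)
  }
  reindex_segments <- function(block) {
    for (i in seq_along(block$segments)) block$segments[[i]]$index_in_block <- i - 1L
  }
  if (inherits(parent, "Block") && inherits(child, "Segment")) {
    if (!is.null(child$parent)) stop("segment is already attached to a block", call. = FALSE)
    parent$segments <- ins(parent$segments, child, at)
    child$parent <- parent
    reindex_segments(parent)
  } else if (inherits(parent, "Block") && inherits(child, "ChannelGroup")) {
    if (!is.null(child$parent)) stop("channel group is already attached to a block", call. = FALSE)
    parent$channel_groups <- ins(parent$channel_groups, child, at)
    child$parent <- parent
  } else if (inherits(parent, "ChannelGroup") && inherits(child, "Channel")) {
    if (!is.null(child$parent)) stop("channel is already attached to a group", call. = FALSE)
    parent$channels <- ins(parent$channels, child, at)
    child$parent <- parent
  } else if (inherits(parent, "ChannelGroup") && inherits(child, "Unit")) {
    if (!is.null(child$parent)) stop("unit is already attached to a group", call. = FALSE)
    parent$units <- ins(parent$units, child, at)
    child$parent <- parent
  } else if (inherits(parent, "Segment") && inherits(child, "SpikeTrain")) {
    if (!is.null(child$segment_ref)) stop("spike train is already attached to a segment", call. = FALSE)
    parent$spike_trains <- ins(parent$spike_trains, child, at)
    child$segment_ref <- parent
  } else if (inherits(parent, "Unit") && inherits(child, "SpikeTrain")) {
    if (!is.null(child$unit_ref)) stop("spike train is already attached to a unit", call. = FALSE)
    parent$spike_trains <- ins(parent$spike_trains, child, at)
    child$unit_ref <- parent
  } else if (inherits(parent, "Segment") && inherits(child, "AnalogSignal")) {
    if (!is.null(child$segment_ref)) stop("analog signal is already attached to a segment", call. = FALSE)
    parent$analog_signals <- ins(parent$analog_signals, child, at)
    child$segment_ref <- parent
  } else if (inherits(parent, "Channel") && inherits(child, "AnalogSignal")) {
    if (!is.null(child$channel_ref)) stop("analog signal is already attached to a channel", call. = FALSE)
    child$channel_ref <- parent
  } else if (inherits(parent, "Segment") && inherits(child, "Event")) {
    if (!is.null(child$segment_ref)) stop("event is already attached to a segment", call. = FALSE)
    parent$events <- ins(parent$events, child, at)
    child$segment_ref <- parent
  } else if (inherits(parent, "Segment") && inherits(child, "Epoch")) {
    if (!is.null(child$segment_ref)) stop("epoch is already attached to a segment", call. = FALSE)
    parent$epochs <- ins(parent$epochs, child, at)
    child$segment_ref <- parent
  } else {
    stop(sprintf("cannot attach a %s to a %s", class(child)[1], class(parent)[1]),
         call. = FALSE)
  }
  invisible(parent)
}

#' Detach a child object from its parent container
#'
#' Reverse of [attach_child()]: removes the child from the parent's list and
#' clears the back reference. Segment indices within a block are recomputed.
#'
#' @param parent the container the child is attached to.
#' @param child the attached child.
#' @return `parent`, invisibly.
#' @export
detach_child <- function(parent, child) {
  drop_from <- function(lst) {
    keep <- !vapply(lst, identical, logical(1), y = child)
    if (all(keep)) stop("child is not attached to this parent", call. = FALSE)
    lst[keep]
  }
  if (inherits(parent, "Block") && inherits(child, "Segment")) {
    parent$segments <- drop_from(parent$segments)
    child$parent <- NULL
    child$index_in_block <- NULL
    for (i in seq_along(parent$segments)) parent$segments[[i]]$index_in_block <- i - 1L
  } else if (inherits(parent, "Block") && inherits(child, "ChannelGroup")) {
    parent$channel_groups <- drop_from(parent$channel_groups); child$parent <- NULL
  } else if (inherits(parent, "ChannelGroup") && inherits(child, "Channel")) {
    parent$channels <- drop_from(parent$channels); child$parent <- NULL
  } else if (inherits(parent, "ChannelGroup") && inherits(child, "Unit")) {
    parent$units <- drop_from(parent$units); child$parent <- NULL
  } else if (inherits(parent, "Segment") && inherits(child, "SpikeTrain")) {
    parent$spike_trains <- drop_from(parent$spike_trains); child$segment_ref <- NULL
  } else if (inherits(parent, "Unit") && inherits(child, "SpikeTrain")) {
    parent$spike_trains <- drop_from(parent$spike_trains); child$unit_ref <- NULL
  } else if (inherits(parent, "Segment") && inherits(child, "AnalogSignal")) {
    parent$analog_signals <- drop_from(parent$analog_signals); child$segment_ref <- NULL
  } else if (inherits(parent, "Channel") && inherits(child, "AnalogSignal")) {
    if (!identical(child$channel_ref, parent)) stop("child is not attached to this parent", call. = FALSE)
    child$channel_ref <- NULL
  } else if (inherits(parent, "Segment") && inherits(child, "Event")) {
    parent$events <- drop_from(parent$events); child$segment_ref <- NULL
  } else if (inherits(parent, "Segment") && inherits(child, "Epoch")) {
    parent$epochs <- drop_from(parent$epochs); child$segment_ref <- NULL
  } else {
    stop(sprintf("cannot detach a %s from a %s", class(child)[1], class(parent)[1]),
         call. = FALSE)
  }
  invisible(parent)
}

#' Extract the spikes of a train inside a half-open time window
#'
#' Returns a new spike train containing the spikes with `t0 <= t < t1`
#' (half-open, so a spike exactly at `t1` is excluded). Waveform rows are
#' sliced consistently. Bounds may be given in any time unit.
#'
#' @param train a spike train.
#' @param t0,t1 window bounds, time quantities with `t0 < t1`.
#' @return A new, unattached [new_spike_train()] with `t_start = t0`,
#'   `t_stop = t1`.
#' @export
time_slice <- function(train, t0, t1) {
  stopifnot(inherits(train, "SpikeTrain"))
  t0s <- .secs(t0); t1s <- .secs(t1)
  if (t0s >= t1s) stop("time_slice requires t0 < t1", call. = FALSE)
  tt <- .secs(train$times)
  keep <- which(tt >= t0s & tt < t1s)
  unit <- q_unit(train$times)
  wf <- NULL
  if (!is.null(train$waveforms)) {
    w <- q_mag(train$waveforms)
    wf <- qty(array(w[keep, , , drop = FALSE],
                    dim = c(length(keep), dim(w)[2], dim(w)[3])),
              q_unit(train$waveforms))
  }
  new_spike_train(times = train$times[keep],
                  t_start = q_convert(qty(t0s, "s"), unit),
                  t_stop = q_convert(qty(t1s, "s"), unit),
                  waveforms = wf,
                  sampling_rate = train$sampling_rate)
}

.ann_value_ok <- function(v) {
  (is.numeric(v) && is.null(dim(v))) ||
    (is.character(v) && length(v) == 1L) ||
    (is.logical(v) && length(v) == 1L)
}

.obj_label <- function(obj) {
  nm <- if (!is.null(obj$name) && nzchar(obj$name %||% "")) obj$name else "<unnamed>"
  sprintf("%s '%s'", class(obj)[1], nm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a model object against the structural invariants
#'
#' Walks the object (and, for containers, all descendants) and reports every
#' violated invariant: sorted spike times within `[t_start, t_stop]`,
#' consistent bidirectional references, segment indices matching list
#' positions, unique channel indices, waveform/spike count agreement,
#' annotation value types, nonempty event labels, non-negative epoch
#' durations.
#'
#' @param obj any model object.
#' @return Character vector of violation descriptions; empty when valid.
#' @export
validate <- function(obj) {
  v <- character(0)
  add <- function(...) v <<- c(v, sprintf(...))
  check_ann <- function(o) {
    ann <- o$annotations
    if (length(ann)) {
      if (is.null(names(ann)) || any(!nzchar(names(ann))))
        add("%s: annotations: keys must be nonempty strings", .obj_label(o))
      for (k in names(ann)) if (!.ann_value_ok(ann[[k]]))
        add("%s: annotations['%s']: value must be a scalar, string or flat numeric array",
            .obj_label(o), k)
    }
  }
  if (inherits(obj, "Block")) {
    check_ann(obj)
    for (i in seq_along(obj$segments)) {
      seg <- obj$segments[[i]]
      if (!identical(seg$parent, obj))
        add("%s: segments[%d]: parent: back reference does not point to this block", .obj_label(obj), i)
      if (!identical(seg$index_in_block, i - 1L))
        add("%s: index_in_block: expected %d, found %s", .obj_label(seg), i - 1L,
            format(seg$index_in_block))
      v <- c(v, validate(seg))
    }
    for (cg in obj$channel_groups) {
      if (!identical(cg$parent, obj))
        add("%s: parent: back reference does not point to this block", .obj_label(cg))
      v <- c(v, validate(cg))
    }
  } else if (inherits(obj, "Segment")) {
    check_ann(obj)
    for (d in obj$spike_trains) {
      if (!.is_lazy(d)) {
        if (!identical(d$segment_ref, obj))
          add("SpikeTrain in %s: segment_ref: back reference mismatch", .obj_label(obj))
        v <- c(v, validate(d))
      }
    }
    for (d in obj$analog_signals) if (!.is_lazy(d)) {
      if (!identical(d$segment_ref, obj))
        add("AnalogSignal in %s: segment_ref: back reference mismatch", .obj_label(obj))
      v <- c(v, validate(d))
    }
    for (d in obj$events) if (!.is_lazy(d)) {
      if (!identical(d$segment_ref, obj))
        add("Event in %s: segment_ref: back reference mismatch", .obj_label(obj))
      v <- c(v, validate(d))
    }
    for (d in obj$epochs) if (!.is_lazy(d)) {
      if (!identical(d$segment_ref, obj))
        add("Epoch in %s: segment_ref: back reference mismatch", .obj_label(obj))
      v <- c(v, validate(d))
    }
  } else if (inherits(obj, "ChannelGroup")) {
    check_ann(obj)
    idx <- vapply(obj$channels, function(ch) ch$index, integer(1))
    if (anyDuplicated(idx))
      add("%s: channels: index: duplicate channel indices", .obj_label(obj))
    for (ch in obj$channels) {
      if (!identical(ch$parent, obj))
        add("%s: parent: back reference does not point to this group", .obj_label(ch))
      check_ann(ch)
    }
    for (u in obj$units) {
      if (!identical(u$parent, obj))
        add("%s: parent: back reference does not point to this group", .obj_label(u))
      check_ann(u)
      for (tr in u$spike_trains) if (!.is_lazy(tr) && !identical(tr$unit_ref, u))
        add("%s: spike_trains: unit_ref: back reference mismatch", .obj_label(u))
    }
  } else if (inherits(obj, "SpikeTrain")) {
    tt <- .secs(obj$times)
    if (is.unsorted(tt)) add("SpikeTrain: times: times sorted ascending violated")
    t0 <- .secs(obj$t_start); t1 <- .secs(obj$t_stop)
    if (t0 >= t1) add("SpikeTrain: t_start/t_stop: t_start < t_stop violated")
    if (length(tt)) {
      if (min(tt) < t0) add("SpikeTrain: times: spike before t_start")
      if (max(tt) > t1) add("SpikeTrain: times: spike after t_stop")
    }
    if (!is.null(obj$waveforms)) {
      d <- dim(q_mag(obj$waveforms))
      if (length(d) != 3L)
        add("SpikeTrain: waveforms: must be a 3-d array (spike x channel x sample)")
      else if (d[1] != length(tt))
        add("SpikeTrain: waveforms: first dimension (%d) != number of spikes (%d)",
            d[1], length(tt))
    }
  } else if (inherits(obj, "AnalogSignal")) {
    if (.hz(obj$sampling_rate) <= 0) add("AnalogSignal: sampling_rate: must be positive")
  } else if (inherits(obj, "Event")) {
    if (!nzchar(obj$label %||% "")) add("Event: label: label nonempty violated")
  } else if (inherits(obj, "Epoch")) {
    if (.secs(obj$duration) < 0) add("Epoch: duration: duration >= 0 violated")
    if (!nzchar(obj$label %||% "")) add("Epoch: label: label nonempty violated")
  } else if (is.list(obj)) {
    for (o in obj) v <- c(v, validate(o))
  }
  v
}

#' Deep value equality of model objects
#'
#' Compares two model objects (or lists of blocks) by value: names,
#' annotations, container structure in order, and all units-aware data arrays
#' (converted to common units, compared within `tol`). Reference identity and
#' parent back references are ignored; lazy handles are materialized before
#' comparison.
#'
#' @param a,b model objects of the same kind.
#' @param tol relative/absolute numeric tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
model_equal <- function(a, b, tol = 1e-9) {
  eq <- function(x, y) model_equal(x, y, tol)
  ann_eq <- function(x, y) {
    if (length(x) != length(y)) return(FALSE)
    if (!setequal(names(x), names(y))) return(FALSE)
    for (k in names(x)) {
      vx <- x[[k]]; vy <- y[[k]]
      if (is.numeric(vx) && is.numeric(vy)) {
        if (length(vx) != length(vy) || any(abs(vx - vy) > tol)) return(FALSE)
      } else if (!identical(vx, vy)) return(FALSE)
    }
    TRUE
  }
  list_eq <- function(x, y) {
    if (length(x) != length(y)) return(FALSE)
    for (i in seq_along(x)) if (!eq(x[[i]], y[[i]])) return(FALSE)
    TRUE
  }
  if (is.list(a) && !inherits(a, "R6")) return(is.list(b) && !inherits(b, "R6") && list_eq(a, b))
  if (.is_lazy(a)) a <- materialize(a)
  if (.is_lazy(b)) b <- materialize(b)
  if (!identical(class(a)[1], class(b)[1])) return(FALSE)
  if (inherits(a, "Block")) {
    return(identical(a$name, b$name) && ann_eq(a$annotations, b$annotations) &&
             list_eq(a$segments, b$segments) &&
             list_eq(a$channel_groups, b$channel_groups))
  }
  if (inherits(a, "Segment")) {
    return(identical(a$name, b$name) && ann_eq(a$annotations, b$annotations) &&
             list_eq(a$spike_trains, b$spike_trains) &&
             list_eq(a$analog_signals, b$analog_signals) &&
             list_eq(a$events, b$events) && list_eq(a$epochs, b$epochs))
  }
  if (inherits(a, "ChannelGroup")) {
    return(identical(a$name, b$name) && ann_eq(a$annotations, b$annotations) &&
             list_eq(a$channels, b$channels) && list_eq(a$units, b$units))
  }
  if (inherits(a, "Channel")) {
    return(identical(a$name, b$name) && identical(a$index, b$index) &&
             ann_eq(a$annotations, b$annotations))
  }
  if (inherits(a, "Unit")) {
    # trains are compared under their segments; compare count only here
    return(identical(a$name, b$name) && ann_eq(a$annotations, b$annotations) &&
             length(a$spike_trains) == length(b$spike_trains))
  }
  if (inherits(a, "SpikeTrain")) {
    wf_eq <- (is.null(a$waveforms) && is.null(b$waveforms)) ||
      (!is.null(a$waveforms) && !is.null(b$waveforms) &&
         identical(dim(q_mag(a$waveforms)), dim(q_mag(b$waveforms))) &&
         q_equal(a$waveforms, b$waveforms, tol))
    sr_eq <- (is.null(a$sampling_rate) && is.null(b$sampling_rate)) ||
      (!is.null(a$sampling_rate) && !is.null(b$sampling_rate) &&
         q_equal(a$sampling_rate, b$sampling_rate, tol))
    return(q_equal(a$times, b$times, tol) && q_equal(a$t_start, b$t_start, tol) &&
             q_equal(a$t_stop, b$t_stop, tol) && wf_eq && sr_eq)
  }
  if (inherits(a, "AnalogSignal")) {
    return(q_equal(a$samples, b$samples, tol) &&
             q_equal(a$sampling_rate, b$sampling_rate, tol) &&
             q_equal(a$t_start, b$t_start, tol))
  }
  if (inherits(a, "Event")) {
    return(q_equal(a$time, b$time, tol) && identical(a$label, b$label))
  }
  if (inherits(a, "Epoch")) {
    return(q_equal(a$time, b$time, tol) && q_equal(a$duration, b$duration, tol) &&
             identical(a$label, b$label))
  }
  identical(a, b)
}
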