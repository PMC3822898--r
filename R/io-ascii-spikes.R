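# Built-in plain-text spike-train format ("ascii-spikes"): one file per
# block. Header lines start with '#' and carry the format version, block
# name, container counts and one line per train with its window bounds; data
# lines are `segment_index<TAB>unit_index<TAB>time_in_seconds` (indices
# 0-based, unit_index -1 for trains not assigned to a unit). Times are
# printed with nanosecond precision. Chosen for human-readable, diffable
# fixtures; only spike data survives the round trip (no signals, waveforms
# or annotations).

.ASCII_FORMAT_VERSION <- 1L

.ascii_write <- function(path, blocks) {
  if (length(blocks) != 1L)
    stop("capability error: backend 'ascii-spikes' writes one block per file",
         call. = FALSE)
  blk <- blocks[[1]]
  units <- list()
  for (cg in blk$channel_groups) units <- c(units, cg$units)
  unit_idx <- function(u) {
    if (is.null(u)) return(-1L)
    for (i in seq_along(units)) if (identical(units[[i]], u)) return(i - 1L)
    -1L
  }
  lines <- c(sprintf("# ascii-spikes %d", .ASCII_FORMAT_VERSION),
             sprintf("# name %s", blk$name),
             sprintf("# segments %d", length(blk$segments)),
             sprintf("# units %d", length(units)))
  data_lines <- character(0)
  seen <- character(0)
  for (si in seq_along(blk$segments)) {
    seg <- blk$segments[[si]]
    for (h in seg$spike_trains) {
      tr <- materialize(h)
      ui <- unit_idx(tr$unit_ref)
      key <- sprintf("%d:%d", si - 1L, ui)
      if (key %in% seen)
        stop(sprintf("capability error: backend 'ascii-spikes' cannot represent two trains with the same (segment, unit) pair (segment %d, unit %d)",
                     si - 1L, ui), call. = FALSE)
      seen <- c(seen, key)
      lines <- c(lines, sprintf("# train seg=%d unit=%d t_start=%.9f t_stop=%.9f",
                                si - 1L, ui, .secs(tr$t_start), .secs(tr$t_stop)))
      tt <- .secs(tr$times)
      if (length(tt))
        data_lines <- c(data_lines,
                        sprintf("%d\t%d\t%.9f", si - 1L, ui, tt))
    }
  }
  writeLines(c(lines, data_lines), path)
  invisible(path)
}

.ascii_read <- function(path, lazy) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# ascii-spikes [0-9]+", lines[1]))
    stop(sprintf("format error in backend 'ascii-spikes': '%s' line 1: missing format header",
                 path), call. = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  get1 <- function(key, default = NULL) {
    m <- grep(sprintf("^# %s ", key), hdr, value = TRUE)
    if (!length(m)) return(default)
    sub(sprintf("^# %s ", key), "", m[1])
  }
  nseg <- as.integer(get1("segments", "0"))
  nunit <- as.integer(get1("units", "0"))
  blk <- new_block(name = get1("name", ""))
  for (i in seq_len(nseg)) attach_child(blk, new_segment(sprintf("Segment %d", i - 1L)))
  units <- list()
  if (nunit > 0) {
    cg <- new_channel_group("Group 0")
    attach_child(blk, cg)
    for (i in seq_len(nunit)) {
      u <- new_unit(sprintf("Unit %d", i - 1L))
      attach_child(cg, u)
      units <- c(units, list(u))
    }
  }
  # spike times per (segment, unit) key
  data <- lines[!startsWith(lines, "#") & nzchar(lines)]
  seg_i <- integer(0); unit_i <- integer(0); tms <- numeric(0)
  if (length(data)) {
    parts <- strsplit(data, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 3L)
    if (length(bad))
      stop(sprintf("format error in backend 'ascii-spikes': '%s': malformed data line %d",
                   path, bad[1]), call. = FALSE)
    m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
    seg_i <- as.integer(m[, 1]); unit_i <- as.integer(m[, 2]); tms <- as.numeric(m[, 3])
  }
  train_hdrs <- grep("^# train ", hdr, value = TRUE)
  for (th in train_hdrs) {
    g <- function(k) as.numeric(sub(sprintf(".*%s=([-0-9.]+).*", k), "\\1", th))
    s <- as.integer(g("seg")); u <- as.integer(g("unit"))
    if (s < 0 || s >= nseg)
      stop(sprintf("format error in backend 'ascii-spikes': '%s': train header references segment %d out of range",
                   path, s), call. = FALSE)
    sel <- seg_i == s & unit_i == u
    tr <- new_spike_train(times = qty(sort(tms[sel]), "s"),
                          t_start = qty(g("t_start"), "s"),
                          t_stop = qty(g("t_stop"), "s"))
    attach_child(blk$segments[[s + 1L]], tr)
    if (u >= 0) {
      if (u >= nunit)
        stop(sprintf("format error in backend 'ascii-spikes': '%s': train header references unit %d out of range",
                     path, u), call. = FALSE)
      attach_child(units[[u + 1L]], tr)
    }
  }
  list(blk)
}

.ascii_spikes_backend <- function() {
  io_backend(name = "ascii-spikes", extensions = c(".spk.txt", ".txt"),
             read = .ascii_read, write = .ascii_write,
             lazy_capable = FALSE,
             readable_kinds = c("Block", "Segment", "ChannelGroup", "Unit",
                                "SpikeTrain"))
}
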