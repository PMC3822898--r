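# Built-in HDF5 interchange format ("native-h5"). Layout: one HDF5 group per
# container object, `/block_<i>/segment_<j>/spiketrain_<k>` etc., datasets for
# times/samples/waveforms, attributes for names, units and window bounds.
# Annotation keys are stored as attributes prefixed `ann_<type>_` so they can
# never collide with structural attributes. A `format_version` attribute on
# the root group versions the layout.

.H5_FORMAT_VERSION <- 1L

.h5_put_attrs <- function(fid, objpath, attrs) {
  oid <- rhdf5::H5Oopen(fid, objpath)
  on.exit(rhdf5::H5Oclose(oid))
  for (k in names(attrs)) {
    v <- attrs[[k]]
    if (is.null(v)) next
    if (is.logical(v)) v <- as.integer(v) # HDF5 has no native logical
    rhdf5::h5writeAttribute(v, oid, k)
  }
}

.h5_ann_attrs <- function(annotations) {
  out <- list()
  for (k in names(annotations)) {
    v <- annotations[[k]]
    if (is.character(v)) out[[paste0("ann_s_", k)]] <- v
    else if (is.logical(v)) out[[paste0("ann_b_", k)]] <- as.integer(v)
    else out[[paste0("ann_n_", k)]] <- as.numeric(v)
  }
  out
}

.h5_decode_anns <- function(attrs) {
  ann <- list()
  for (k in names(attrs)) {
    if (startsWith(k, "ann_s_")) ann[[substring(k, 7)]] <- as.character(attrs[[k]])
    else if (startsWith(k, "ann_b_")) ann[[substring(k, 7)]] <- as.logical(as.vector(attrs[[k]]))
    else if (startsWith(k, "ann_n_")) ann[[substring(k, 7)]] <- as.numeric(attrs[[k]])
  }
  ann
}

.h5_new_group <- function(fid, path, name, annotations = list(), extra = list()) {
  gid <- rhdf5::H5Gcreate(fid, path)
  rhdf5::H5Gclose(gid)
  .h5_put_attrs(fid, path, c(list(name = name), .h5_ann_attrs(annotations), extra))
}

.h5_write_qty_dataset <- function(fid, dspath, q, unit_attr) {
  m <- q_mag(q)
  rhdf5::h5write(m, fid, dspath)
  .h5_put_attrs(fid, dspath, stats::setNames(list(q_unit(q)), unit_attr))
}

.h5_write_blocks <- function(path, blocks) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit({ rhdf5::H5Fclose(fid); rhdf5::h5closeAll() })
  .h5_put_attrs(fid, "/", list(format_version = .H5_FORMAT_VERSION))
  for (bi in seq_along(blocks)) {
    blk <- blocks[[bi]]
    bp <- sprintf("block_%d", bi - 1L)
    .h5_new_group(fid, bp, blk$name, blk$annotations)

    for (gi in seq_along(blk$channel_groups)) {
      cg <- blk$channel_groups[[gi]]
      gp <- sprintf("%s/channelgroup_%d", bp, gi - 1L)
      .h5_new_group(fid, gp, cg$name, cg$annotations)
      for (ci in seq_along(cg$channels)) {
        ch <- cg$channels[[ci]]
        cp <- sprintf("%s/channel_%d", gp, ci - 1L)
        .h5_new_group(fid, cp, ch$name, ch$annotations,
                      list(index = as.integer(ch$index)))
      }
      for (ui in seq_along(cg$units)) {
        u <- cg$units[[ui]]
        up <- sprintf("%s/unit_%d", gp, ui - 1L)
        .h5_new_group(fid, up, u$name, u$annotations)
      }
    }
    addr_of <- function(obj) {
      for (gi in seq_along(blk$channel_groups)) {
        cg <- blk$channel_groups[[gi]]
        for (ui in seq_along(cg$units))
          if (identical(cg$units[[ui]], obj))
            return(sprintf("channelgroup_%d/unit_%d", gi - 1L, ui - 1L))
        for (ci in seq_along(cg$channels))
          if (identical(cg$channels[[ci]], obj))
            return(sprintf("channelgroup_%d/channel_%d", gi - 1L, ci - 1L))
      }
      ""
    }

    for (si in seq_along(blk$segments)) {
      seg <- blk$segments[[si]]
      sp <- sprintf("%s/segment_%d", bp, si - 1L)
      .h5_new_group(fid, sp, seg$name, seg$annotations)
      for (ki in seq_along(seg$spike_trains)) {
        tr <- materialize(seg$spike_trains[[ki]])
        tp <- sprintf("%s/spiketrain_%d", sp, ki - 1L)
        extra <- list(times_unit = q_unit(tr$times),
                      t_start = q_mag(tr$t_start), t_start_unit = q_unit(tr$t_start),
                      t_stop = q_mag(tr$t_stop), t_stop_unit = q_unit(tr$t_stop),
                      unit_path = if (is.null(tr$unit_ref)) "" else addr_of(tr$unit_ref))
        if (!is.null(tr$sampling_rate)) {
          extra$sampling_rate <- q_mag(tr$sampling_rate)
          extra$sampling_rate_unit <- q_unit(tr$sampling_rate)
        }
        gid <- rhdf5::H5Gcreate(fid, tp); rhdf5::H5Gclose(gid)
        .h5_put_attrs(fid, tp, extra)
        rhdf5::h5write(q_mag(tr$times), fid, paste0(tp, "/times"))
        if (!is.null(tr$waveforms)) {
          w <- q_mag(tr$waveforms)
          .h5_put_attrs(fid, tp, list(waveforms_dim = as.integer(dim(w)),
                                      waveforms_unit = q_unit(tr$waveforms)))
          if (length(w) > 0) rhdf5::h5write(w, fid, paste0(tp, "/waveforms"))
        }
      }
      for (ki in seq_along(seg$analog_signals)) {
        sig <- materialize(seg$analog_signals[[ki]])
        ap <- sprintf("%s/analogsignal_%d", sp, ki - 1L)
        gid <- rhdf5::H5Gcreate(fid, ap); rhdf5::H5Gclose(gid)
        .h5_put_attrs(fid, ap, list(
          samples_unit = q_unit(sig$samples),
          sampling_rate = q_mag(sig$sampling_rate),
          sampling_rate_unit = q_unit(sig$sampling_rate),
          t_start = q_mag(sig$t_start), t_start_unit = q_unit(sig$t_start),
          channel_path = if (is.null(sig$channel_ref)) "" else addr_of(sig$channel_ref)))
        rhdf5::h5write(q_mag(sig$samples), fid, paste0(ap, "/samples"))
      }
      for (ki in seq_along(seg$events)) {
        ev <- materialize(seg$events[[ki]])
        ep <- sprintf("%s/event_%d", sp, ki - 1L)
        gid <- rhdf5::H5Gcreate(fid, ep); rhdf5::H5Gclose(gid)
        .h5_put_attrs(fid, ep, list(time = q_mag(ev$time), time_unit = q_unit(ev$time),
                                    label = ev$label))
      }
      for (ki in seq_along(seg$epochs)) {
        eo <- materialize(seg$epochs[[ki]])
        ep <- sprintf("%s/epoch_%d", sp, ki - 1L)
        gid <- rhdf5::H5Gcreate(fid, ep); rhdf5::H5Gclose(gid)
        .h5_put_attrs(fid, ep, list(time = q_mag(eo$time), time_unit = q_unit(eo$time),
                                    duration = q_mag(eo$duration),
                                    duration_unit = q_unit(eo$duration),
                                    label = eo$label))
      }
    }
  }
  invisible(path)
}

.h5_attrs_of <- function(path, objpath) {
  a <- tryCatch(rhdf5::h5readAttributes(path, objpath), error = function(e)
    stop(sprintf("format error in backend 'native-h5': cannot read attributes of '%s' in '%s': %s",
                 objpath, path, conditionMessage(e)), call. = FALSE))
  lapply(a, as.vector)
}

.h5_children <- function(ls_df, group, prefix) {
  g <- if (group == "") "/" else group
  rows <- ls_df[ls_df$group == g &
                  grepl(sprintf("^%s_[0-9]+$", prefix), ls_df$name), , drop = FALSE]
  if (!nrow(rows)) return(character(0))
  idx <- as.integer(sub(sprintf("^%s_", prefix), "", rows$name))
  rows$name[order(idx)]
}

.h5_read_spiketrain <- function(path, tp) {
  at <- .h5_attrs_of(path, tp)
  tms <- tryCatch(as.numeric(rhdf5::h5read(path, paste0(tp, "/times"))),
                  error = function(e)
                    stop(sprintf("format error in backend 'native-h5': missing dataset '%s/times' in '%s'",
                                 tp, path), call. = FALSE))
  wf <- NULL
  if (!is.null(at$waveforms_dim)) {
    d <- as.integer(at$waveforms_dim)
    w <- if (prod(d) > 0) rhdf5::h5read(path, paste0(tp, "/waveforms")) else array(numeric(0), dim = d)
    wf <- qty(array(as.numeric(w), dim = d), at$waveforms_unit)
  }
  sr <- if (!is.null(at$sampling_rate)) qty(at$sampling_rate, at$sampling_rate_unit)
  new_spike_train(times = qty(tms, at$times_unit),
                  t_start = qty(at$t_start, at$t_start_unit),
                  t_stop = qty(at$t_stop, at$t_stop_unit),
                  waveforms = wf, sampling_rate = sr)
}

.h5_read_signal <- function(path, ap) {
  at <- .h5_attrs_of(path, ap)
  smp <- as.numeric(rhdf5::h5read(path, paste0(ap, "/samples")))
  new_analog_signal(samples = qty(smp, at$samples_unit),
                    sampling_rate = qty(at$sampling_rate, at$sampling_rate_unit),
                    t_start = qty(at$t_start, at$t_start_unit))
}

.h5_read_blocks <- function(path, lazy) {
  ls_df <- tryCatch(rhdf5::h5ls(path),
                    error = function(e)
                      stop(sprintf("format error in backend 'native-h5': '%s' is not readable HDF5: %s",
                                   path, conditionMessage(e)), call. = FALSE))
  root <- .h5_attrs_of(path, "/")
  if (is.null(root$format_version))
    stop(sprintf("format error in backend 'native-h5': '%s' lacks a format_version attribute", path),
         call. = FALSE)
  blocks <- list()
  for (bname in .h5_children(ls_df, "", "block")) {
    bat <- .h5_attrs_of(path, bname)
    blk <- new_block(name = bat$name %||% "", annotations = .h5_decode_anns(bat))
    addr_obj <- list() # structural address -> Unit/Channel object
    for (gname in .h5_children(ls_df, paste0("/", bname), "channelgroup")) {
      gp <- paste(bname, gname, sep = "/")
      gat <- .h5_attrs_of(path, gp)
      cg <- new_channel_group(name = gat$name %||% "", annotations = .h5_decode_anns(gat))
      attach_child(blk, cg)
      for (cname in .h5_children(ls_df, paste0("/", gp), "channel")) {
        cat_ <- .h5_attrs_of(path, paste(gp, cname, sep = "/"))
        ch <- new_channel(name = cat_$name %||% "", index = cat_$index,
                          annotations = .h5_decode_anns(cat_))
        attach_child(cg, ch)
        addr_obj[[paste(gname, cname, sep = "/")]] <- ch
      }
      for (uname in .h5_children(ls_df, paste0("/", gp), "unit")) {
        uat <- .h5_attrs_of(path, paste(gp, uname, sep = "/"))
        u <- new_unit(name = uat$name %||% "", annotations = .h5_decode_anns(uat))
        attach_child(cg, u)
        addr_obj[[paste(gname, uname, sep = "/")]] <- u
      }
    }
    for (sname in .h5_children(ls_df, paste0("/", bname), "segment")) {
      sp <- paste(bname, sname, sep = "/")
      sat <- .h5_attrs_of(path, sp)
      seg <- new_segment(name = sat$name %||% "", annotations = .h5_decode_anns(sat))
      attach_child(blk, seg)
      for (tname in .h5_children(ls_df, paste0("/", sp), "spiketrain")) {
        tp <- paste(sp, tname, sep = "/")
        tat <- .h5_attrs_of(path, tp)
        u <- if (nzchar(tat$unit_path %||% "")) addr_obj[[tat$unit_path]]
        if (lazy) {
          h <- local({
            path_ <- path; tp_ <- tp; seg_ <- seg; u_ <- u
            LazyHandle$new(locator = list(path = path, backend = "native-h5",
                                          address = tp),
                           kind = "SpikeTrain",
                           loader = function() {
                             tr <- .h5_read_spiketrain(path_, tp_)
                             tr$segment_ref <- seg_
                             tr$unit_ref <- u_
                             tr
                           })
          })
          seg$spike_trains <- c(seg$spike_trains, list(h))
          if (!is.null(u)) u$spike_trains <- c(u$spike_trains, list(h))
        } else {
          tr <- .h5_read_spiketrain(path, tp)
          attach_child(seg, tr)
          if (!is.null(u)) attach_child(u, tr)
        }
      }
      for (aname in .h5_children(ls_df, paste0("/", sp), "analogsignal")) {
        ap <- paste(sp, aname, sep = "/")
        aat <- .h5_attrs_of(path, ap)
        ch <- if (nzchar(aat$channel_path %||% "")) addr_obj[[aat$channel_path]]
        if (lazy) {
          h <- local({
            path_ <- path; ap_ <- ap; seg_ <- seg; ch_ <- ch
            LazyHandle$new(locator = list(path = path, backend = "native-h5",
                                          address = ap),
                           kind = "AnalogSignal",
                           loader = function() {
                             sig <- .h5_read_signal(path_, ap_)
                             sig$segment_ref <- seg_
                             sig$channel_ref <- ch_
                             sig
                           })
          })
          seg$analog_signals <- c(seg$analog_signals, list(h))
        } else {
          sig <- .h5_read_signal(path, ap)
          attach_child(seg, sig)
          if (!is.null(ch)) attach_child(ch, sig)
        }
      }
      for (ename in .h5_children(ls_df, paste0("/", sp), "event")) {
        ep <- paste(sp, ename, sep = "/")
        make_ev <- local({
          path_ <- path; ep_ <- ep; seg_ <- seg
          function() {
            eat <- .h5_attrs_of(path_, ep_)
            ev <- new_event(time = qty(eat$time, eat$time_unit), label = eat$label)
            ev$segment_ref <- seg_
            ev
          }
        })
        if (lazy) {
          seg$events <- c(seg$events, list(
            LazyHandle$new(locator = list(path = path, backend = "native-h5", address = ep),
                           kind = "Event", loader = make_ev)))
        } else {
          ev <- make_ev(); ev$segment_ref <- NULL; attach_child(seg, ev)
        }
      }
      for (ename in .h5_children(ls_df, paste0("/", sp), "epoch")) {
        ep <- paste(sp, ename, sep = "/")
        make_eo <- local({
          path_ <- path; ep_ <- ep; seg_ <- seg
          function() {
            eat <- .h5_attrs_of(path_, ep_)
            eo <- new_epoch(time = qty(eat$time, eat$time_unit),
                            duration = qty(eat$duration, eat$duration_unit),
                            label = eat$label)
            eo$segment_ref <- seg_
            eo
          }
        })
        if (lazy) {
          seg$epochs <- c(seg$epochs, list(
            LazyHandle$new(locator = list(path = path, backend = "native-h5", address = ep),
                           kind = "Epoch", loader = make_eo)))
        } else {
          eo <- make_eo(); eo$segment_ref <- NULL; attach_child(seg, eo)
        }
      }
    }
    blocks <- c(blocks, list(blk))
  }
  blocks
}

.native_h5_backend <- function() {
  io_backend(name = "native-h5", extensions = c(".h5", ".hdf5"),
             read = .h5_read_blocks, write = .h5_write_blocks,
             lazy_capable = TRUE)
}
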