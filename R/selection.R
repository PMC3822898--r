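# Selections: self-contained, data-free descriptions of a connected subgraph
# of the container hierarchy. A selection references objects only by their
# relations to higher objects (the block locator, then indices), never by
# value, so serialized selections stay small regardless of how many spikes or
# samples the data holds.
#
# JSON schema (version 1):
#   {"blocks": [{"channel_groups": [{"channels": [...], "index": i,
#                                    "units": [...]}],
#                "index": i, "io": "...", "path": "...",
#                "segments": [...]}],
#    "version": 1}
# Canonical form: keys in alphabetical order, all index arrays sorted
# ascending and duplicate-free, so equal selections serialize to identical
# bytes.

.SELECTION_VERSION <- 1L

.norm_indices <- function(x, what) {
  x <- as.integer(x)
  if (any(x < 0)) stop(sprintf("selection: %s indices must be >= 0", what), call. = FALSE)
  if (anyDuplicated(x)) {
    warning(sprintf("selection: duplicate %s indices removed", what), call. = FALSE)
    x <- unique(x)
  }
  sort(x)
}

#' Describe selected members of one channel group
#'
#' @param index channel-group index within its block (0-based).
#' @param units,channels selected unit / channel indices within the group.
#' @export
selection_group <- function(index, units = integer(0), channels = integer(0)) {
  list(index = as.integer(index),
       units = .norm_indices(units, "unit"),
       channels = .norm_indices(channels, "channel"))
}

#' Describe selected members of one block
#'
#' @param path file the block lives in.
#' @param io name of the IO backend that reads it.
#' @param index block index within the file (0-based).
#' @param segments selected segment indices.
#' @param channel_groups list of [selection_group()] entries.
#' @export
selection_block <- function(path, io, index, segments = integer(0),
                            channel_groups = list()) {
  if (as.integer(index) < 0) stop("selection: block index must be >= 0", call. = FALSE)
  groups <- channel_groups[order(vapply(channel_groups, `[[`, integer(1), "index"))]
  list(path = path, io = io, index = as.integer(index),
       segments = .norm_indices(segments, "segment"),
       channel_groups = groups)
}

#' Construct a selection
#'
#' @param blocks ordered list of [selection_block()] entries.
#' @return An object of class `selection`.
#' @export
selection <- function(blocks = list()) {
  structure(list(version = .SELECTION_VERSION, blocks = blocks),
            class = "selection")
}

#' Serialize a selection to canonical JSON
#'
#' The output is canonical: keys sorted alphabetically, index arrays sorted
#' ascending without duplicates, compact single-line output. Two equal
#' selections always produce byte-identical text.
#'
#' @param sel a [selection()].
#' @return JSON text (single string).
#' @export
to_json <- function(sel) {
  stopifnot(inherits(sel, "selection"))
  blk <- lapply(sel$blocks, function(b) {
    grp <- lapply(b$channel_groups, function(g) {
      list(channels = I(.norm_indices(g$channels, "channel")),
           index = jsonlite::unbox(as.integer(g$index)),
           units = I(.norm_indices(g$units, "unit")))
    })
    grp <- grp[order(vapply(b$channel_groups, `[[`, integer(1), "index"))]
    list(channel_groups = grp,
         index = jsonlite::unbox(as.integer(b$index)),
         io = jsonlite::unbox(b$io),
         path = jsonlite::unbox(b$path),
         segments = I(.norm_indices(b$segments, "segment")))
  })
  doc <- list(blocks = blk, version = jsonlite::unbox(.SELECTION_VERSION))
  as.character(jsonlite::toJSON(doc, auto_unbox = FALSE, digits = NA))
}

#' Parse a selection from JSON
#'
#' Accepts documents of the declared schema version; index arrays are
#' normalized (sorted, duplicates dropped with a warning). Missing required
#' keys or an unknown version raise a parse error naming the offending
#' location.
#'
#' @param text JSON text.
#' @return A [selection()].
#' @export
from_json <- function(text) {
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("selection parse error: %s", conditionMessage(e)),
                         call. = FALSE))
  if (is.null(doc$version))
    stop("selection parse error: missing required key 'version'", call. = FALSE)
  if (!identical(as.integer(doc$version), .SELECTION_VERSION))
    stop(sprintf("selection parse error: unknown schema version %s",
                 format(doc$version)), call. = FALSE)
  if (is.null(doc$blocks))
    stop("selection parse error: missing required key 'blocks'", call. = FALSE)
  blocks <- lapply(seq_along(doc$blocks), function(i) {
    b <- doc$blocks[[i]]
    for (k in c("path", "io", "index"))
      if (is.null(b[[k]]))
        stop(sprintf("selection parse error: blocks[%d]: missing required key '%s'",
                     i, k), call. = FALSE)
    groups <- lapply(seq_along(b$channel_groups), function(j) {
      g <- b$channel_groups[[j]]
      if (is.null(g$index))
        stop(sprintf("selection parse error: blocks[%d].channel_groups[%d]: missing required key 'index'",
                     i, j), call. = FALSE)
      selection_group(index = g$index,
                      units = unlist(g$units) %||% integer(0),
                      channels = unlist(g$channels) %||% integer(0))
    })
    selection_block(path = b$path, io = b$io, index = b$index,
                    segments = unlist(b$segments) %||% integer(0),
                    channel_groups = groups)
  })
  selection(blocks)
}

#' Save / load selections as `.sel.json` files
#' @param sel a selection.
#' @param path file path.
#' @export
save_selection <- function(sel, path) {
  writeLines(to_json(sel), path)
  invisible(path)
}

#' @rdname save_selection
#' @export
load_selection <- function(path) {
  if (!file.exists(path))
    stop(sprintf("selection file '%s' does not exist", path), call. = FALSE)
  from_json(paste(readLines(path), collapse = "\n"))
}

.clear_marks <- function(blk) {
  blk$selected <- FALSE
  for (seg in blk$segments) seg$selected <- FALSE
  for (cg in blk$channel_groups) {
    cg$selected <- FALSE
    for (ch in cg$channels) ch$selected <- FALSE
    for (u in cg$units) u$selected <- FALSE
  }
  invisible(blk)
}

#' Resolve a selection against its data files
#'
#' Loads every referenced block through the IO backend named in its locator
#' (files are read once per resolve even when several locators share them) and
#' sets the `selected` membership flag on exactly the containers the selection
#' names; all other containers are present but unmarked.
#'
#' @param sel a [selection()].
#' @param registry IO registry used to load the files.
#' @param lazy read lazily (no data objects materialized).
#' @return List of resolved blocks, one per locator, in selection order.
#' @export
resolve <- function(sel, registry = default_registry(), lazy = FALSE) {
  stopifnot(inherits(sel, "selection"))
  cache <- list()
  out <- list()
  for (b in sel$blocks) {
    key <- paste(b$path, b$io, sep = "||")
    if (is.null(cache[[key]])) {
      if (!file.exists(b$path))
        stop(sprintf("selection resolution error: file '%s' (io '%s') does not exist",
                     b$path, b$io), call. = FALSE)
      cache[[key]] <- read_file(b$path, backend = b$io, lazy = lazy,
                                registry = registry)
    }
    blocks <- cache[[key]]
    if (b$index >= length(blocks))
      stop(sprintf("selection resolution error: '%s' holds %d block(s) but index %d was requested",
                   b$path, length(blocks), b$index), call. = FALSE)
    blk <- blocks[[b$index + 1L]]
    .clear_marks(blk)
    blk$selected <- TRUE
    for (si in b$segments) {
      if (si >= length(blk$segments))
        stop(sprintf("selection resolution error: block %d of '%s' has %d segment(s) but index %d was requested",
                     b$index, b$path, length(blk$segments), si), call. = FALSE)
      blk$segments[[si + 1L]]$selected <- TRUE
    }
    for (g in b$channel_groups) {
      if (g$index >= length(blk$channel_groups))
        stop(sprintf("selection resolution error: block %d of '%s' has %d channel group(s) but index %d was requested",
                     b$index, b$path, length(blk$channel_groups), g$index), call. = FALSE)
      cg <- blk$channel_groups[[g$index + 1L]]
      cg$selected <- TRUE
      for (ui in g$units) {
        if (ui >= length(cg$units))
          stop(sprintf("selection resolution error: channel group %d has %d unit(s) but index %d was requested",
                       g$index, length(cg$units), ui), call. = FALSE)
        cg$units[[ui + 1L]]$selected <- TRUE
      }
      for (ci in g$channels) {
        if (ci >= length(cg$channels))
          stop(sprintf("selection resolution error: channel group %d has %d channel(s) but index %d was requested",
                       g$index, length(cg$channels), ci), call. = FALSE)
        cg$channels[[ci + 1L]]$selected <- TRUE
      }
    }
    out <- c(out, list(blk))
  }
  out
}

#' Mutable selection state over loaded blocks
#'
#' Holds loaded blocks and lets callers toggle container membership in place
#' (the headless counterpart of selecting in a navigation GUI). Use
#' [from_current()] to freeze the state into an immutable [selection()]
#' snapshot, or build a live data provider over it.
#'
#' @param blocks list of loaded blocks.
#' @param select_all mark every container selected initially.
#' @return A `selection_state` R6 object.
#' @export
selection_state <- function(blocks = list(), select_all = TRUE) {
  SelectionState$new(blocks, select_all)
}

SelectionState <- R6::R6Class("SelectionState",
  public = list(
    blocks = NULL,
    initialize = function(blocks, select_all = TRUE) {
      self$blocks <- blocks
      for (blk in blocks) {
        .clear_marks(blk)
        if (select_all) self$select_block_all(blk)
      }
    },
    select_block_all = function(blk) {
      blk$selected <- TRUE
      for (seg in blk$segments) seg$selected <- TRUE
      for (cg in blk$channel_groups) {
        cg$selected <- TRUE
        for (ch in cg$channels) ch$selected <- TRUE
        for (u in cg$units) u$selected <- TRUE
      }
      invisible(self)
    },
    set_selected = function(obj, value = TRUE) {
      if (!.is_container(obj)) stop("only container objects can be selected", call. = FALSE)
      obj$selected <- isTRUE(value)
      invisible(self)
    }
  )
)

#' Snapshot the current selection state
#'
#' Produces an immutable [selection()] recording which containers are
#' currently marked selected in `state`. Later changes to the state do not
#' affect the snapshot. Every block contributing selected content must carry a
#' source locator (i.e. have been read from or written to a file).
#'
#' @param state a [selection_state()].
#' @return A [selection()].
#' @export
from_current <- function(state) {
  stopifnot(inherits(state, "SelectionState"))
  blocks <- list()
  for (blk in state$blocks) {
    seg_idx <- which(vapply(blk$segments, function(s) isTRUE(s$selected), logical(1))) - 1L
    groups <- list()
    for (gi in seq_along(blk$channel_groups)) {
      cg <- blk$channel_groups[[gi]]
      u_idx <- which(vapply(cg$units, function(u) isTRUE(u$selected), logical(1))) - 1L
      c_idx <- which(vapply(cg$channels, function(ch) isTRUE(ch$selected), logical(1))) - 1L
      if (isTRUE(cg$selected) || length(u_idx) || length(c_idx))
        groups <- c(groups, list(selection_group(gi - 1L, units = u_idx,
                                                 channels = c_idx)))
    }
    if (!isTRUE(blk$selected) && !length(seg_idx) && !length(groups)) next
    if (is.null(blk$source))
      stop(sprintf("selection snapshot error: %s has no source locator; save it to a file first",
                   .obj_label(blk)), call. = FALSE)
    blocks <- c(blocks, list(selection_block(path = blk$source$path,
                                             io = blk$source$io,
                                             index = blk$source$index,
                                             segments = seg_idx,
                                             channel_groups = groups)))
  }
  selection(blocks)
}

#' Maintain an ordered list of named selections
#'
#' Mirrors a "stored selections" list: names are unique, with a numeric
#' suffix appended on collision.
#'
#' @param lst existing named list of selections (possibly empty).
#' @param name proposed name.
#' @param sel the selection to add.
#' @return The updated named list.
#' @export
selections_add <- function(lst, name, sel) {
  nm <- name
  k <- 1L
  while (nm %in% names(lst)) {
    k <- k + 1L
    nm <- sprintf("%s_%d", name, k)
  }
  lst[[nm]] <- sel
  lst
}
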