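# User-defined filters decide which container objects an analysis sees.
# A filter is one R function: an item predicate (object -> TRUE/FALSE, order
# preserving) or a list transform (list -> reordered subsequence of the same
# objects). Filters are linked into an ordered chain, optionally organized in
# groups; an exclusive group keeps at most one member active. Filter bodies
# run in a restricted environment exposing the object(s), basic R control
# flow and math -- no filesystem or network access from filter code.

.FILTER_TARGETS <- c("block", "segment", "channel_group", "channel", "unit")

.target_of_class <- function(obj) {
  switch(class(obj)[1],
         Block = "block", Segment = "segment", ChannelGroup = "channel_group",
         Channel = "channel", Unit = "unit",
         stop("filters apply to container objects only", call. = FALSE))
}

# strict, type-sensitive annotation comparison; the one concession is that
# integer and double count as the same (numeric) type
.ann_strict_equal <- function(a, b) {
  if (is.null(a) || is.null(b)) return(FALSE)
  if (is.numeric(a) && is.numeric(b))
    return(length(a) == length(b) && all(a == b))
  identical(a, b)
}

.FILTER_WHITELIST <- c(
  "if", "for", "while", "repeat", "break", "next", "return", "function",
  "<-", "<<-", "=", "{", "(", "[", "[[", "$",
  "+", "-", "*", "/", "^", "%%", "%/%",
  "==", "!=", "<", "<=", ">", ">=", "&", "|", "!", "&&", "||",
  "c", "list", "length", "rev", "seq", "seq_len", "seq_along", "rep",
  "sapply", "vapply", "lapply", "Filter", "which", "unlist", "sort", "order",
  "is.null", "is.na", "is.numeric", "is.character", "is.logical", "identical",
  "names", "abs", "floor", "ceiling", "round", "min", "max", "sum", "mean",
  "any", "all", "paste", "paste0", "sprintf", "nchar", "substr", "grepl",
  "startsWith", "endsWith", "tolower", "toupper", "isTRUE", "isFALSE",
  "xor", "setdiff", "intersect", "union", "head", "tail", "stop", "stopifnot"
)

.filter_eval_env <- function() {
  env <- new.env(parent = emptyenv())
  for (nm in .FILTER_WHITELIST) {
    f <- tryCatch(get(nm, envir = baseenv()), error = function(e) NULL)
    if (is.null(f)) f <- get(nm, envir = asNamespace("utils"))
    assign(nm, f, envir = env)
  }
  env$ann_equals <- .ann_strict_equal
  env$qty <- qty; env$q_in <- q_in; env$q_mag <- q_mag; env$q_unit <- q_unit
  env
}

.compile_filter_body <- function(body, name) {
  exprs <- tryCatch(parse(text = body),
                    error = function(e)
                      stop(sprintf("filter '%s': definition error: body does not parse: %s",
                                   name, conditionMessage(e)), call. = FALSE))
  if (length(exprs) != 1L)
    stop(sprintf("filter '%s': definition error: body must be exactly one function expression",
                 name), call. = FALSE)
  fn <- eval(exprs[[1]], envir = .filter_eval_env())
  if (!is.function(fn))
    stop(sprintf("filter '%s': definition error: body is not a function", name),
         call. = FALSE)
  if (length(formals(fn)) != 1L)
    stop(sprintf("filter '%s': definition error: the filter function must take exactly one argument",
                 name), call. = FALSE)
  environment(fn) <- .filter_eval_env()
  fn
}

#' Define a filter
#'
#' @param name filter name (unique within a chain).
#' @param target container type the filter applies to: one of `"block"`,
#'   `"segment"`, `"channel_group"`, `"channel"`, `"unit"`.
#' @param mode `"item_predicate"` (function of one object returning
#'   `TRUE`/`FALSE`) or `"list_transform"` (function of the object list
#'   returning a reordered subsequence).
#' @param body source text of exactly one R function taking one argument.
#' @param active whether the filter participates when its chain is applied.
#' @param group optional group name.
#' @return Object of class `filter_def`.
#' @export
filter_def <- function(name, target, mode = c("item_predicate", "list_transform"),
                       body, active = TRUE, group = NULL) {
  mode <- match.arg(mode)
  target <- match.arg(target, .FILTER_TARGETS)
  body <- paste(body, collapse = "\n")
  .compile_filter_body(body, name) # definition errors surface here
  structure(list(name = name, target = target, mode = mode, body = body,
                 active = isTRUE(active), group = group),
            class = "filter_def")
}

#' Convenience predicate on an annotation value
#'
#' Builds an item-predicate filter keeping objects whose annotation `key`
#' equals `value` under strict (type-sensitive) comparison; objects lacking
#' the key are excluded.
#'
#' @param key annotation key.
#' @param value value to match.
#' @param target container type (default `"segment"`).
#' @param name filter name (default derived from key/value).
#' @param ... passed to [filter_def()] (`active`, `group`).
#' @export
annotation_predicate <- function(key, value, target = "segment",
                                 name = sprintf("%s == %s", key, format(value)),
                                 ...) {
  body <- sprintf("function(x) ann_equals(x$annotations[[%s]], %s)",
                  deparse(key), paste(deparse(value), collapse = ""))
  filter_def(name = name, target = target, mode = "item_predicate",
             body = body, ...)
}

#' Group filters, optionally exclusively
#'
#' In an exclusive group at most one member is active: activating a member
#' via [set_active()] deactivates its siblings.
#'
#' @param name group name.
#' @param exclusive enforce the single-active-member rule.
#' @param members list of [filter_def()]s.
#' @export
filter_group <- function(name, exclusive = FALSE, members = list()) {
  if (exclusive) {
    act <- which(vapply(members, function(f) f$active, logical(1)))
    if (length(act) > 1L)
      for (i in act[-1]) members[[i]]$active <- FALSE
  }
  members <- lapply(members, function(f) { f$group <- name; f })
  structure(list(name = name, exclusive = isTRUE(exclusive), members = members),
            class = "filter_group")
}

#' Create a filter chain
#'
#' An ordered, mutable sequence of filters and filter groups. Application
#' order equals list order; [set_active()] toggles members in place.
#'
#' @param entries list of [filter_def()] / [filter_group()] entries.
#' @return A `filter_chain` (environment-backed, reference semantics).
#' @export
filter_chain <- function(entries = list()) {
  ch <- new.env(parent = emptyenv())
  ch$entries <- entries
  class(ch) <- "filter_chain"
  ch
}

#' Append a filter or group to a chain
#' @param chain a [filter_chain()].
#' @param entry a [filter_def()] or [filter_group()].
#' @export
add_filter <- function(chain, entry) {
  stopifnot(inherits(chain, "filter_chain"),
            inherits(entry, c("filter_def", "filter_group")))
  chain$entries <- c(chain$entries, list(entry))
  invisible(chain)
}

.chain_filters <- function(chain, target = NULL) {
  out <- list()
  for (e in chain$entries) {
    fs <- if (inherits(e, "filter_group")) e$members else list(e)
    for (f in fs) if (is.null(target) || f$target == target) out <- c(out, list(f))
  }
  out
}

#' Toggle filter activation
#'
#' Activating a member of an exclusive group deactivates all of its siblings;
#' deactivation never cascades. Unknown names raise a lookup error.
#'
#' @param chain a [filter_chain()].
#' @param name filter name.
#' @param active new activation state.
#' @export
set_active <- function(chain, name, active = TRUE) {
  stopifnot(inherits(chain, "filter_chain"))
  found <- FALSE
  entries <- chain$entries
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (inherits(e, "filter_def") && e$name == name) {
      .compile_filter_body(e$body, e$name) # definition errors at activation
      entries[[i]]$active <- isTRUE(active)
      found <- TRUE
    } else if (inherits(e, "filter_group")) {
      for (j in seq_along(e$members)) {
        if (e$members[[j]]$name == name) {
          .compile_filter_body(e$members[[j]]$body, name)
          if (isTRUE(active) && e$exclusive)
            for (k in seq_along(e$members)) entries[[i]]$members[[k]]$active <- FALSE
          entries[[i]]$members[[j]]$active <- isTRUE(active)
          found <- TRUE
        }
      }
    }
  }
  if (!found)
    stop(sprintf("lookup error: no filter named '%s' in chain", name), call. = FALSE)
  chain$entries <- entries
  invisible(chain)
}

.is_subsequence_with_reordering <- function(out, input) {
  if (!is.list(out)) return(FALSE)
  used <- rep(FALSE, length(input))
  for (o in out) {
    hit <- FALSE
    for (i in seq_along(input)) {
      if (!used[i] && identical(input[[i]], o)) { used[i] <- TRUE; hit <- TRUE; break }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

#' Apply a filter chain to a list of container objects
#'
#' Active filters whose target matches the objects are applied in chain
#' order. Item predicates keep the relative order of survivors; list
#' transforms may reorder but can only return objects from their input. A
#' filter whose body raises an error (or a transform that fabricates or
#' duplicates objects) is skipped with a warning and the list passes through
#' unchanged. With every filter inactive the chain is the identity.
#'
#' @param chain a [filter_chain()].
#' @param objects ordered list of containers, all of the same type.
#' @return The filtered, possibly reordered list.
#' @export
apply_chain <- function(chain, objects) {
  stopifnot(inherits(chain, "filter_chain"))
  if (!length(objects)) return(objects)
  target <- .target_of_class(objects[[1]])
  for (obj in objects) if (.target_of_class(obj) != target)
    stop("apply_chain: all objects must share the chain's target type", call. = FALSE)
  cur <- objects
  for (f in .chain_filters(chain, target)) {
    if (!f$active) next
    fn <- .compile_filter_body(f$body, f$name)
    if (f$mode == "item_predicate") {
      keep <- tryCatch(vapply(cur, function(o) isTRUE(fn(o)), logical(1)),
                       error = function(e) e)
      if (inherits(keep, "error")) {
        warning(sprintf("filter '%s' raised an error and was skipped: %s",
                        f$name, conditionMessage(keep)), call. = FALSE)
        next
      }
      cur <- cur[keep]
    } else {
      res <- tryCatch(fn(cur), error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("filter '%s' raised an error and was skipped: %s",
                        f$name, conditionMessage(res)), call. = FALSE)
        next
      }
      if (!.is_subsequence_with_reordering(res, cur)) {
        warning(sprintf("filter '%s' returned objects not drawn from its input and was skipped",
                        f$name), call. = FALSE)
        next
      }
      cur <- res
    }
  }
  cur
}

#' Persist a filter chain as an annotated R source file
#'
#' Each filter is written as one function preceded by a structured comment
#' header (`#@ key: value` lines) recording name, target, mode, activation
#' and group membership, so the file remains a valid, readable R source file.
#'
#' @param chain a [filter_chain()].
#' @param path output path (conventionally `*.filters`).
#' @export
save_filters <- function(chain, path) {
  stopifnot(inherits(chain, "filter_chain"))
  lines <- character(0)
  emit <- function(f, group = NULL, exclusive = FALSE) {
    h <- c("#@ filter",
           sprintf("#@ name: %s", f$name),
           sprintf("#@ target: %s", f$target),
           sprintf("#@ mode: %s", f$mode),
           sprintf("#@ active: %s", if (f$active) "TRUE" else "FALSE"))
    if (!is.null(group))
      h <- c(h, sprintf("#@ group: %s", group),
             sprintf("#@ exclusive: %s", if (exclusive) "TRUE" else "FALSE"))
    c(h, strsplit(f$body, "\n")[[1]], "")
  }
  for (e in chain$entries) {
    if (inherits(e, "filter_group")) {
      for (f in e$members) lines <- c(lines, emit(f, e$name, e$exclusive))
    } else {
      lines <- c(lines, emit(e, e$group, FALSE))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load a filter chain from an annotated R source file
#'
#' Inverse of [save_filters()]: `load_filters(save_filters(chain))` restores
#' an equal chain, with groups reassembled in order of first appearance. A
#' function without a metadata header, or a malformed header, is a load error
#' naming the offending line.
#'
#' @param path filter file path.
#' @return A [filter_chain()].
#' @export
load_filters <- function(path) {
  if (!file.exists(path))
    stop(sprintf("filter file '%s' does not exist", path), call. = FALSE)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) return(filter_chain())
  starts <- which(trimws(lines) == "#@ filter")
  if (!length(starts) || nonblank[1] < starts[1])
    stop(sprintf("filter load error: %s line %d: content before the first '#@ filter' header",
                 path, nonblank[1]), call. = FALSE)
  bounds <- c(starts, length(lines) + 1L)
  defs <- list()
  for (i in seq_along(starts)) {
    sec <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    meta <- list()
    j <- 1L
    while (j <= length(sec) && startsWith(trimws(sec[j]), "#@")) {
      m <- regmatches(sec[j], regexec("^#@ ([a-z_]+):\\s*(.*)$", trimws(sec[j])))[[1]]
      if (length(m) == 0)
        stop(sprintf("filter load error: %s line %d: malformed metadata header '%s'",
                     path, bounds[i] + j, sec[j]), call. = FALSE)
      meta[[m[2]]] <- m[3]
      j <- j + 1L
    }
    for (k in c("name", "target", "mode", "active"))
      if (is.null(meta[[k]]))
        stop(sprintf("filter load error: %s line %d: missing metadata key '%s'",
                     path, bounds[i], k), call. = FALSE)
    body <- paste(sec[j:length(sec)], collapse = "\n")
    f <- filter_def(name = meta$name, target = meta$target, mode = meta$mode,
                    body = body, active = identical(meta$active, "TRUE"),
                    group = meta$group)
    attr(f, "exclusive") <- identical(meta$exclusive, "TRUE")
    defs <- c(defs, list(f))
  }
  entries <- list()
  group_at <- list()
  for (f in defs) {
    if (is.null(f$group)) {
      entries <- c(entries, list(f))
    } else if (is.null(group_at[[f$group]])) {
      g <- filter_group(f$group, exclusive = isTRUE(attr(f, "exclusive")),
                        members = list(f))
      entries <- c(entries, list(g))
      group_at[[f$group]] <- length(entries)
    } else {
      i <- group_at[[f$group]]
      entries[[i]]$members <- c(entries[[i]]$members, list(f))
    }
  }
  entries <- lapply(entries, function(e) {
    if (inherits(e, "filter_group"))
      e$members <- lapply(e$members, function(f) { attr(f, "exclusive") <- NULL; f })
    else attr(e, "exclusive") <- NULL
    e
  })
  filter_chain(entries)
}

#' Compare two filter chains for equality
#' @param a,b filter chains.
#' @export
chains_equal <- function(a, b) {
  strip <- function(f) { attributes(f) <- NULL; f }
  fa <- .chain_filters(a); fb <- .chain_filters(b)
  if (length(fa) != length(fb)) return(FALSE)
  for (i in seq_along(fa)) {
    x <- fa[[i]]; y <- fb[[i]]
    same <- identical(x$name, y$name) && identical(x$target, y$target) &&
      identical(x$mode, y$mode) && identical(x$active, y$active) &&
      identical(x$group %||% "", y$group %||% "") &&
      identical(trimws(x$body), trimws(y$body))
    if (!same) return(FALSE)
  }
  TRUE
}
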