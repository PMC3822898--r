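# IO backend registry: backends are looked up by explicit name or by filename
# extension. Two backends ship with the package (native-h5, ascii-spikes);
# more can be contributed as IO plugin files, discovered recursively.

#' Define an IO backend
#'
#' @param name unique backend id.
#' @param extensions filename suffixes handled, lowercase with leading dot.
#' @param read function `(path, lazy)` returning a list of blocks, or `NULL`
#'   for write-only backends.
#' @param write function `(path, blocks)`, or `NULL` for read-only backends.
#' @param lazy_capable whether `read` honors `lazy = TRUE`.
#' @param readable_kinds model type names the backend can represent.
#' @return An object of class `io_backend`.
#' @export
io_backend <- function(name, extensions, read = NULL, write = NULL,
                       lazy_capable = FALSE,
                       readable_kinds = c("Block", "Segment", "ChannelGroup",
                                          "Channel", "Unit", "SpikeTrain",
                                          "AnalogSignal", "Event", "Epoch")) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(extensions) && any(!grepl("^\\.", extensions)))
    stop("extensions must carry a leading dot", call. = FALSE)
  structure(list(name = name, extensions = tolower(extensions),
                 read = read, write = write,
                 writable = !is.null(write), lazy_capable = lazy_capable,
                 readable_kinds = readable_kinds),
            class = "io_backend")
}

#' Create an IO backend registry
#'
#' @param builtin include the built-in `native-h5` and `ascii-spikes`
#'   backends.
#' @return A registry (environment) usable with [register_backend()],
#'   [read_file()] and [write_file()].
#' @export
io_registry <- function(builtin = TRUE) {
  reg <- new.env(parent = emptyenv())
  reg$backends <- list()
  class(reg) <- "io_registry"
  if (builtin) {
    register_backend(.native_h5_backend(), reg)
    register_backend(.ascii_spikes_backend(), reg)
  }
  reg
}

#' The package-wide default IO registry
#' @return The shared registry holding the built-in backends.
#' @export
default_registry <- function() {
  if (is.null(.ephys_state$registry)) .ephys_state$registry <- io_registry()
  .ephys_state$registry
}

#' Register an IO backend
#'
#' Makes the backend selectable by name and by filename extension. Duplicate
#' names are rejected; when several backends claim the same extension, an
#' explicit backend name wins at dispatch and otherwise registration order
#' decides (with a notice).
#'
#' @param backend an [io_backend()].
#' @param registry target registry (default: package-wide).
#' @return The backend, invisibly.
#' @export
register_backend <- function(backend, registry = default_registry()) {
  stopifnot(inherits(backend, "io_backend"), inherits(registry, "io_registry"))
  if (backend$name %in% names(registry$backends))
    stop(sprintf("an IO backend named '%s' is already registered", backend$name),
         call. = FALSE)
  registry$backends[[backend$name]] <- backend
  invisible(backend)
}

#' Look up IO backends by name or matching extension
#'
#' @param name backend name (takes precedence when given).
#' @param path a file path whose extension is matched otherwise.
#' @param registry the registry to search.
#' @return A list of matching backends (possibly empty); name lookup returns
#'   at most one.
#' @export
lookup_backend <- function(name = NULL, path = NULL,
                           registry = default_registry()) {
  if (!is.null(name)) {
    b <- registry$backends[[name]]
    return(if (is.null(b)) list() else list(b))
  }
  if (is.null(path)) return(unname(registry$backends))
  ext <- tolower(paste0(".", tools::file_ext(path)))
  hits <- Filter(function(b) ext %in% b$extensions, registry$backends)
  unname(hits)
}

.pick_backend <- function(path, backend, registry, need_write = FALSE) {
  hits <- lookup_backend(name = backend, path = if (is.null(backend)) path,
                         registry = registry)
  if (!length(hits)) {
    what <- if (is.null(backend)) sprintf("extension of '%s'", path)
            else sprintf("name '%s'", backend)
    stop(sprintf("IO dispatch error: no registered backend matches %s", what),
         call. = FALSE)
  }
  if (length(hits) > 1L)
    message(sprintf("several backends match '%s'; using '%s' (registration order)",
                    path, hits[[1]]$name))
  b <- hits[[1]]
  if (need_write && !b$writable)
    stop(sprintf("capability error: backend '%s' does not support writing", b$name),
         call. = FALSE)
  b
}

#' Read an electrophysiology file into the object model
#'
#' Dispatches to a registered backend (explicit `backend` name, otherwise by
#' extension). In lazy mode (for capable backends) the container tree is read
#' completely but the data objects are lazy handles that are materialized on
#' first access. Each returned block carries its source locator so selections
#' and provider snapshots can reference it.
#'
#' @param path file to read.
#' @param backend optional backend name.
#' @param lazy read lazily if the backend supports it.
#' @param registry IO registry to dispatch in.
#' @return List of blocks.
#' @export
read_file <- function(path, backend = NULL, lazy = FALSE,
                      registry = default_registry()) {
  if (!file.exists(path))
    stop(sprintf("IO dispatch error: file '%s' does not exist", path),
         call. = FALSE)
  b <- .pick_backend(path, backend, registry)
  if (is.null(b$read))
    stop(sprintf("capability error: backend '%s' does not support reading", b$name),
         call. = FALSE)
  if (lazy && !b$lazy_capable) {
    message(sprintf("backend '%s' cannot read lazily; reading in full", b$name))
    lazy <- FALSE
  }
  blocks <- b$read(path, lazy)
  for (i in seq_along(blocks))
    blocks[[i]]$source <- list(path = normalizePath(path), io = b$name,
                               index = i - 1L)
  blocks
}

#' Write blocks through an IO backend
#'
#' @param path output file.
#' @param blocks list of blocks (a single block may be passed bare).
#' @param backend backend name (default: by extension).
#' @param registry IO registry.
#' @return `path`, invisibly; blocks gain a source locator.
#' @export
write_file <- function(path, blocks, backend = NULL,
                       registry = default_registry()) {
  if (inherits(blocks, "Block")) blocks <- list(blocks)
  b <- .pick_backend(path, backend, registry, need_write = TRUE)
  b$write(path, blocks)
  for (i in seq_along(blocks))
    blocks[[i]]$source <- list(path = normalizePath(path), io = b$name,
                               index = i - 1L)
  invisible(path)
}

#' Discover IO plugins in a directory tree
#'
#' Recursively sources every `.R` file under `dirs` and registers each object
#' of class `io_backend` the file defines. Files that fail to load are skipped
#' with a warning; missing directories are ignored with a warning.
#'
#' @param dirs directories to scan.
#' @param registry registry to register discovered backends in.
#' @return List of newly registered backends.
#' @export
discover_io_plugins <- function(dirs, registry = default_registry()) {
  defs <- .scan_definition_files(dirs, function(obj) inherits(obj, "io_backend"))
  found <- list()
  for (d in defs) {
    ok <- tryCatch({ register_backend(d$object, registry); TRUE },
                   error = function(e) {
                     warning(sprintf("IO plugin '%s' from %s not registered: %s",
                                     d$object$name, d$path, conditionMessage(e)),
                             call. = FALSE)
                     FALSE
                   })
    if (ok) found <- c(found, list(d$object))
  }
  found
}

# Shared discovery helper: source each .R file under dirs in a fresh
# environment and collect the defined objects that satisfy `is_wanted`.
# Returns list of list(path, name, object). Broken files warn and are skipped.
.scan_definition_files <- function(dirs, is_wanted) {
  out <- list()
  for (d in dirs) {
    if (!dir.exists(d)) {
      warning(sprintf("plugin directory '%s' does not exist; skipped", d),
              call. = FALSE)
      next
    }
    files <- sort(list.files(d, pattern = "\\.[Rr]$", recursive = TRUE,
                             full.names = TRUE))
    for (f in files) {
      env <- new.env(parent = globalenv())
      ok <- tryCatch({ sys.source(f, envir = env); TRUE },
                     error = function(e) {
                       warning(sprintf("failed to load '%s': %s", f,
                                       conditionMessage(e)), call. = FALSE)
                       FALSE
                     })
      if (!ok) next
      for (nm in sort(ls(env))) {
        obj <- get(nm, envir = env)
        if (is_wanted(obj))
          out <- c(out, list(list(path = f, name = nm, object = obj)))
      }
    }
  }
  out
}
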