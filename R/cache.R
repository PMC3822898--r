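# Result persistence and the parameter-keyed result cache. Results are
# serialized to HDF5 (the documented result-structure family plus numeric /
# integer / logical / character arrays, quantities, data frames and nested
# lists); arbitrary objects such as functions or environments are rejected
# with guidance. Cache files are indexed by a JSON sidecar mapping the key
# digest to metadata, so the cache survives process restarts.

.RESULT_S3_CLASSES <- c("binned_histogram", "correlogram_result", "sde_result",
                        "spectrogram_result", "raster_data")

.h5_write_value <- function(fid, path, value) {
  mark <- function(type, extra = list()) {
    gid <- rhdf5::H5Gcreate(fid, path); rhdf5::H5Gclose(gid)
    .h5_put_attrs(fid, path, c(list(vtype = type), extra))
  }
  if (is.null(value)) {
    mark("null")
  } else if (is_qty(value)) {
    mark("qty", list(unit = q_unit(value),
                     vdim = as.integer(dim(q_mag(value)) %||% length(q_mag(value)))))
    if (length(q_mag(value))) rhdf5::h5write(q_mag(value), fid, paste0(path, "/value"))
  } else if (is.logical(value) && is.null(dim(value))) {
    mark("logical", list(n = length(value)))
    if (length(value)) rhdf5::h5write(as.integer(value), fid, paste0(path, "/value"))
  } else if (is.numeric(value) || is.character(value)) {
    type <- if (is.integer(value)) "integer"
            else if (is.character(value)) "character" else "numeric"
    mark(type, list(vdim = as.integer(dim(value) %||% length(value)),
                    has_names = !is.null(names(value))))
    if (length(value)) rhdf5::h5write(value, fid, paste0(path, "/value"))
    if (!is.null(names(value))) rhdf5::h5write(names(value), fid, paste0(path, "/names"))
  } else if (is.data.frame(value)) {
    mark("data.frame", list(columns = names(value), nrow = nrow(value)))
    for (i in seq_along(value))
      .h5_write_value(fid, sprintf("%s/col_%d", path, i), value[[i]])
  } else if (inherits(value, .RESULT_S3_CLASSES)) {
    mark("s3", list(s3class = class(value)[1], keys = names(value)))
    v <- unclass(value)
    for (i in seq_along(v))
      .h5_write_value(fid, sprintf("%s/item_%d", path, i), v[[i]])
  } else if (is.list(value)) {
    mark("list", list(n = length(value),
                      keys = if (!is.null(names(value))) names(value) else character(0)))
    for (i in seq_along(value))
      .h5_write_value(fid, sprintf("%s/item_%d", path, i), value[[i]])
  } else {
    stop(sprintf("cannot serialize a value of class '%s' to the result layout; supported: NULL, numeric/integer/logical/character arrays, quantities, data frames, nested lists and the analysis result structures",
                 class(value)[1]), call. = FALSE)
  }
}

.h5_read_value <- function(path_file, path) {
  at <- .h5_attrs_of(path_file, path)
  type <- at$vtype
  rd <- function(sub) rhdf5::h5read(path_file, paste(path, sub, sep = "/"))
  if (type == "null") return(NULL)
  if (type == "qty") {
    d <- as.integer(at$vdim)
    v <- if (prod(d) == 0 && length(d) == 1L) numeric(0) else as.numeric(rd("value"))
    if (length(d) > 1L) v <- array(v, dim = d)
    return(qty(v, at$unit))
  }
  if (type == "logical") {
    n <- as.integer(at$n)
    return(if (n == 0) logical(0) else as.logical(as.vector(rd("value"))))
  }
  if (type %in% c("numeric", "integer", "character")) {
    d <- as.integer(at$vdim)
    v <- if (prod(d) == 0 && length(d) == 1L) {
      switch(type, numeric = numeric(0), integer = integer(0), character = character(0))
    } else rd("value")
    v <- switch(type, numeric = as.numeric(v), integer = as.integer(v),
                character = as.character(v))
    if (length(d) > 1L) v <- array(v, dim = d)
    if (isTRUE(as.logical(at$has_names))) names(v) <- as.character(rd("names"))
    return(v)
  }
  if (type == "data.frame") {
    cols <- as.character(at$columns)
    vals <- lapply(seq_along(cols), function(i)
      .h5_read_value(path_file, sprintf("%s/col_%d", path, i)))
    names(vals) <- cols
    df <- as.data.frame(vals, stringsAsFactors = FALSE, check.names = FALSE)
    return(df)
  }
  if (type == "s3") {
    keys <- as.character(at$keys)
    v <- lapply(seq_along(keys), function(i)
      .h5_read_value(path_file, sprintf("%s/item_%d", path, i)))
    names(v) <- keys
    class(v) <- at$s3class
    return(v)
  }
  if (type == "list") {
    n <- as.integer(at$n)
    v <- lapply(seq_len(n), function(i)
      .h5_read_value(path_file, sprintf("%s/item_%d", path, i)))
    if (length(at$keys)) names(v) <- as.character(at$keys)
    return(v)
  }
  stop(sprintf("unknown result node type '%s' in '%s'", type, path_file),
       call. = FALSE)
}

#' Write / read an analysis result in the HDF5 result layout
#'
#' @param value a serializable result (see [result_cache()] for the supported
#'   family).
#' @param path `.h5` file to write / read.
#' @export
write_result <- function(value, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit({ rhdf5::H5Fclose(fid); rhdf5::h5closeAll() })
  .h5_put_attrs(fid, "/", list(result_format_version = 1L))
  .h5_write_value(fid, "result", value)
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  .h5_read_value(path, "result")
}

#' Cache key from selection, parameters and plugin identity
#'
#' A stable digest of (canonical selection JSON, canonicalized parameter
#' mapping, plugin name, plugin version tag). Equal inputs give equal
#' digests; changing any component changes the digest.
#'
#' @param selection_json canonical selection JSON text (see [to_json()]).
#' @param params named list of parameter values.
#' @param plugin_name plugin name.
#' @param plugin_version version tag, typically [plugin_file_digest()].
#' @return A `cache_key`.
#' @export
cache_key <- function(selection_json, params, plugin_name, plugin_version = "") {
  if (length(params)) params <- params[order(names(params))]
  canon_params <- as.character(jsonlite::toJSON(params, auto_unbox = TRUE,
                                                digits = NA))
  material <- paste(selection_json, canon_params, plugin_name, plugin_version,
                    sep = "\n")
  structure(list(digest = digest::digest(material, algo = "sha256"),
                 selection_json = selection_json, params = params,
                 plugin_name = plugin_name, plugin_version = plugin_version),
            class = "cache_key")
}

#' Parameter-keyed result cache backed by HDF5 files
#'
#' Results are stored one HDF5 file per key digest under `dir`, with a JSON
#' index sidecar (`index.json`) recording metadata. The index is reloaded on
#' construction, so a cache directory opened in a later process serves the
#' results stored earlier. A corrupt index or result file degrades to a cold
#' cache with a warning rather than an error.
#'
#' @param dir cache directory (created if missing).
#' @return A `result_cache`.
#' @export
result_cache <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cc <- new.env(parent = emptyenv())
  cc$dir <- dir
  cc$index <- list()
  idx_file <- file.path(dir, "index.json")
  if (file.exists(idx_file)) {
    cc$index <- tryCatch(
      jsonlite::fromJSON(paste(readLines(idx_file), collapse = "\n"),
                         simplifyVector = FALSE),
      error = function(e) {
        warning(sprintf("corrupt cache index '%s'; starting with a cold cache",
                        idx_file), call. = FALSE)
        list()
      })
  }
  class(cc) <- "result_cache"
  cc
}

.cache_write_index <- function(cache) {
  writeLines(as.character(jsonlite::toJSON(cache$index, auto_unbox = TRUE)),
             file.path(cache$dir, "index.json"))
}

#' Store a result under a cache key
#' @param cache a [result_cache()].
#' @param key a [cache_key()].
#' @param result a serializable result value.
#' @export
cache_store <- function(cache, key, result) {
  stopifnot(inherits(cache, "result_cache"), inherits(key, "cache_key"))
  file <- paste0(key$digest, ".h5")
  write_result(result, file.path(cache$dir, file))
  cache$index[[key$digest]] <- list(file = file, plugin = key$plugin_name,
                                    version = key$plugin_version,
                                    created = format(Sys.time(), tz = "UTC"))
  .cache_write_index(cache)
  invisible(key$digest)
}

#' Fetch a cached result, or NULL on a miss
#'
#' A hit requires the full key digest to match -- same canonical selection,
#' same parameters, same plugin name and version. A missing or unreadable
#' result file is treated as a miss with a warning.
#'
#' @param cache a [result_cache()].
#' @param key a [cache_key()].
#' @return The stored result, or `NULL`.
#' @export
cache_fetch <- function(cache, key) {
  stopifnot(inherits(cache, "result_cache"), inherits(key, "cache_key"))
  entry <- cache$index[[key$digest]]
  if (is.null(entry)) return(NULL)
  f <- file.path(cache$dir, entry$file)
  if (!file.exists(f)) {
    warning(sprintf("cache file '%s' is missing; treating as a miss", f),
            call. = FALSE)
    return(NULL)
  }
  tryCatch(read_result(f),
           error = function(e) {
             warning(sprintf("cache file '%s' is unreadable (%s); treating as a miss",
                             f, conditionMessage(e)), call. = FALSE)
             NULL
           })
}
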