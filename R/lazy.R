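# Lazy materialization: in lazy reading mode the container tree is complete
# but data objects are placeholders that read their arrays from the source
# file on first access. Granularity is one handle per data object.

.ephys_state <- new.env(parent = emptyenv())
.ephys_state$materializations <- 0L

LazyHandle <- R6::R6Class("LazyHandle",
  public = list(
    locator = NULL,  # list(path, backend, address)
    kind = NULL,     # model type name, e.g. "SpikeTrain"
    loaded = FALSE,
    payload = NULL,
    loader = NULL,   # function() -> model object, called at most once
    initialize = function(locator, kind, loader) {
      self$locator <- locator
      self$kind <- kind
      self$loader <- loader
    }
  )
)

.is_lazy <- function(x) inherits(x, "LazyHandle")

#' Materialize a lazily loaded data object
#'
#' Returns the object unchanged if it is not a lazy handle. For a handle, the
#' first call reads the object from its source file (incrementing the global
#' materialization counter) and caches it; later calls return the cached
#' payload without touching the file.
#'
#' @param x a data object or lazy handle.
#' @return The materialized model object.
#' @export
materialize <- function(x) {
  if (!.is_lazy(x)) return(x)
  if (!x$loaded) {
    x$payload <- x$loader()
    x$loaded <- TRUE
    .ephys_state$materializations <- .ephys_state$materializations + 1L
  }
  x$payload
}

#' Global materialization counter
#'
#' Diagnostic counter of how many lazy data objects have been read from disk
#' since the last reset. Used to verify the laziness contract: 0 after a lazy
#' open, the number of returned objects after one full query, unchanged after
#' a repeated query.
#'
#' @return Integer count.
#' @export
materialization_count <- function() .ephys_state$materializations

#' @rdname materialization_count
#' @export
reset_materialization_count <- function() {
  .ephys_state$materializations <- 0L
  invisible(0L)
}
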