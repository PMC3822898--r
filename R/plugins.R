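# Analysis plugins: a plugin is one R object built by analysis_plugin(),
# defined in an ordinary R source file. Plugin directories are scanned
# recursively; subdirectories become branches of the resulting plugin tree.
# Files that fail to load are skipped with a warning and re-discovery
# reflects on-disk edits, so plugins can be developed without restarting.

#' Declare a plugin parameter
#'
#' @param name parameter name (unique within the plugin).
#' @param kind `"boolean"`, `"integer"`, `"real"`, `"text"` or `"choice"`.
#' @param default default value, consistent with `kind` (and a member of
#'   `choices` for choice parameters).
#' @param label human-readable label.
#' @param choices allowed values for `kind = "choice"`.
#' @return A `plugin_param`.
#' @export
plugin_param <- function(name, kind = c("boolean", "integer", "real", "text",
                                        "choice"),
                         default, label = name, choices = NULL) {
  kind <- match.arg(kind)
  ok <- switch(kind,
               boolean = is.logical(default) && length(default) == 1L,
               integer = is.numeric(default) && length(default) == 1L &&
                 default == as.integer(default),
               real = is.numeric(default) && length(default) == 1L,
               text = is.character(default) && length(default) == 1L,
               choice = !is.null(choices) && default %in% choices)
  if (!ok)
    stop(sprintf("plugin_param '%s': default does not satisfy kind '%s'",
                 name, kind), call. = FALSE)
  structure(list(name = name, kind = kind, default = default, label = label,
                 choices = choices),
            class = "plugin_param")
}

#' Define an analysis plugin
#'
#' @param name plugin name (nonempty; shown in listings, used for lookups).
#' @param start the plugin body: `function(provider, selections, config)`.
#'   `config` holds the validated parameter values.
#' @param parameters list of [plugin_param()] declarations.
#' @return An `analysis_plugin`.
#' @export
analysis_plugin <- function(name, start, parameters = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.function(start))
  pnames <- vapply(parameters, function(p) p$name, character(1))
  if (anyDuplicated(pnames))
    stop("analysis_plugin: parameter names must be unique", call. = FALSE)
  structure(list(name = name, parameters = parameters, start = start,
                 source_path = NULL, version = NULL),
            class = "analysis_plugin")
}

#' Name of a plugin
#' @param plugin an `analysis_plugin`.
#' @export
plugin_name <- function(plugin) plugin$name

#' Validate a parameter mapping against a plugin's declarations
#'
#' Unknown keys are rejected; missing keys take their declared defaults;
#' values must satisfy the declared kind (integers may be given as whole
#' doubles; choice values must be members of the choice list).
#'
#' @param plugin an `analysis_plugin`.
#' @param params named list of parameter values.
#' @return Complete named list of validated values.
#' @export
validate_params <- function(plugin, params = list()) {
  decls <- stats::setNames(plugin$parameters,
                           vapply(plugin$parameters, function(p) p$name,
                                  character(1)))
  unknown <- setdiff(names(params), names(decls))
  if (length(unknown))
    stop(sprintf("plugin '%s': validation error: unknown parameter(s): %s",
                 plugin$name, paste(unknown, collapse = ", ")), call. = FALSE)
  out <- list()
  for (nm in names(decls)) {
    d <- decls[[nm]]
    v <- if (nm %in% names(params)) params[[nm]] else d$default
    ok <- switch(d$kind,
                 boolean = is.logical(v) && length(v) == 1L && !is.na(v),
                 integer = is.numeric(v) && length(v) == 1L && v == as.integer(v),
                 real = is.numeric(v) && length(v) == 1L,
                 text = is.character(v) && length(v) == 1L,
                 choice = length(v) == 1L && v %in% d$choices)
    if (!ok)
      stop(sprintf("plugin '%s': validation error: parameter '%s' does not satisfy kind '%s'",
                   plugin$name, nm, d$kind), call. = FALSE)
    if (d$kind == "integer") v <- as.integer(v)
    out[[nm]] <- v
  }
  out
}

#' Discover plugins under directories
#'
#' Scans `dirs` recursively for R source files defining `analysis_plugin`
#' objects. The result mirrors the directory structure: each subdirectory is
#' a branch, each plugin a leaf. Files that fail to load are skipped with a
#' warning; calling again after editing files reflects the changes.
#'
#' @param dirs directories to scan.
#' @return A `plugin_tree` with fields `plugins` (at this level) and
#'   `children` (named list of subtrees).
#' @export
discover_plugins <- function(dirs) {
  root <- list(plugins = list(), children = list())
  defs <- .scan_definition_files(dirs, function(o) inherits(o, "analysis_plugin"))
  for (d in defs) {
    p <- d$object
    p$source_path <- normalizePath(d$path)
    p$version <- plugin_file_digest(d$path)
    # relative subdirectory under whichever scan root contains the file
    rel <- NULL
    for (base in dirs) {
      nb <- suppressWarnings(normalizePath(base))
      np <- p$source_path
      if (startsWith(np, paste0(nb, "/"))) {
        rel <- dirname(substring(np, nchar(nb) + 2L))
        break
      }
    }
    segs <- if (is.null(rel) || rel == ".") character(0)
            else strsplit(rel, "/", fixed = TRUE)[[1]]
    node <- root
    insert <- function(node, segs, p) {
      if (!length(segs)) {
        node$plugins <- c(node$plugins, list(p))
        return(node)
      }
      s <- segs[1]
      if (is.null(node$children[[s]]))
        node$children[[s]] <- list(plugins = list(), children = list())
      node$children[[s]] <- insert(node$children[[s]], segs[-1], p)
      node
    }
    root <- insert(root, segs, p)
  }
  structure(root, class = "plugin_tree")
}

#' Content digest of a plugin source file
#'
#' Part of the cache key, so cached results are never served after the plugin
#' changes.
#'
#' @param path plugin file.
#' @export
plugin_file_digest <- function(path) digest::digest(file = path, algo = "sha256")

#' All plugins in a tree, depth first
#' @param tree a `plugin_tree`.
#' @export
plugin_tree_leaves <- function(tree) {
  out <- tree$plugins
  for (nm in names(tree$children))
    out <- c(out, plugin_tree_leaves(tree$children[[nm]]))
  out
}

#' Find a plugin by name in a tree
#' @param tree a `plugin_tree`.
#' @param name plugin name.
#' @export
find_plugin <- function(tree, name) {
  for (p in plugin_tree_leaves(tree)) if (p$name == name) return(p)
  NULL
}
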