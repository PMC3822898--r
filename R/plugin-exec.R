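# Plugin execution modes. In-process execution shares memory with the
# caller; subprocess execution serializes a provider snapshot and the
# parameters, restores them in a fresh R process and ships the result back;
# standalone export writes a self-describing bundle that can be executed
# later or elsewhere. For deterministic plugins all three modes produce
# deep-equal results; the in-process mode is merely faster because loaded
# data is reused.

#' Run a plugin in the current process
#'
#' Parameters are validated against the plugin's declarations before the body
#' runs ([validate_params()]); plugin errors are re-raised with the plugin
#' name attached.
#'
#' @param plugin an `analysis_plugin`.
#' @param provider a data provider.
#' @param params named list of parameter values (missing ones take defaults).
#' @param selections optional list of additional providers passed through to
#'   the plugin.
#' @param config extra configuration entries merged into the validated
#'   parameters.
#' @return The plugin's result value.
#' @export
run_in_process <- function(plugin, provider, params = list(),
                           selections = list(), config = list()) {
  stopifnot(inherits(plugin, "analysis_plugin"))
  cfg <- utils::modifyList(config, validate_params(plugin, params))
  tryCatch(plugin$start(provider, selections, cfg),
           error = function(e)
             stop(sprintf("plugin '%s' failed: %s", plugin$name,
                          conditionMessage(e)), call. = FALSE))
}

.load_plugin_file <- function(path, name = NULL) {
  env <- new.env(parent = globalenv())
  sys.source(path, envir = env)
  plugins <- Filter(function(o) inherits(o, "analysis_plugin"),
                    lapply(sort(ls(env)), get, envir = env))
  if (!length(plugins))
    stop(sprintf("no analysis_plugin defined in '%s'", path), call. = FALSE)
  if (!is.null(name)) {
    for (p in plugins) if (p$name == name) return(p)
    stop(sprintf("no plugin named '%s' in '%s'", name, path), call. = FALSE)
  }
  plugins[[1]]
}

#' Run a plugin in its own R process
#'
#' The provider snapshot, plugin file path and parameters are sent to a fresh
#' R process, which restores the provider (loading the data itself), runs the
#' plugin and returns the result. Nothing is shared with the parent, so
#' several plugins can run concurrently. Requires the package to be
#' installed so the child can load it.
#'
#' @param plugin_path path to the plugin source file.
#' @param snap a `provider_snapshot` (see [snapshot()]).
#' @param params named list of parameter values.
#' @param plugin_name plugin to pick when the file defines several.
#' @return The plugin's result value.
#' @export
run_subprocess <- function(plugin_path, snap, params = list(),
                           plugin_name = NULL) {
  stopifnot(inherits(snap, "provider_snapshot"))
  snap_json <- snapshot_to_json(snap)
  errfile <- tempfile(fileext = ".log")
  res <- tryCatch(
    callr::r(function(snap_json, plugin_path, params, plugin_name) {
      library(ephyskit)
      prov <- ephyskit::restore(snap_json)
      plugin <- ephyskit:::.load_plugin_file(plugin_path, plugin_name)
      ephyskit::run_in_process(plugin, prov, params)
    }, args = list(snap_json = snap_json,
                   plugin_path = normalizePath(plugin_path),
                   params = params, plugin_name = plugin_name),
    stderr = errfile),
    error = function(e) {
      log <- if (file.exists(errfile))
        paste(utils::tail(readLines(errfile, warn = FALSE), 5), collapse = "\n")
      else ""
      stop(sprintf("subprocess plugin execution failed: %s\nchild log:\n%s",
                   conditionMessage(e), log), call. = FALSE)
    })
  res
}

#' Export a standalone execution bundle
#'
#' Writes a directory that fully decouples plugin execution from the calling
#' session: the plugin source, the stored selections, the parameter file, a
#' manifest naming all inputs, and a `run` entry-point script. Executing the
#' bundle later (or on another machine that can reach the data files)
#' reproduces the in-process result for deterministic plugins.
#'
#' @param plugin_path plugin source file.
#' @param selections list of [selection()]s (the first drives the provider).
#' @param params named list of parameter values.
#' @param out_dir bundle directory to create.
#' @param plugin_name plugin to pick when the file defines several.
#' @return `out_dir`, invisibly.
#' @export
export_standalone <- function(plugin_path, selections, params, out_dir,
                              plugin_name = NULL) {
  if (inherits(selections, "selection")) selections <- list(selections)
  dir.create(file.path(out_dir, "selections"), recursive = TRUE,
             showWarnings = FALSE)
  file.copy(plugin_path, file.path(out_dir, "plugin.R"), overwrite = TRUE)
  sel_files <- character(0)
  for (i in seq_along(selections)) {
    f <- sprintf("selections/sel_%03d.sel.json", i)
    save_selection(selections[[i]], file.path(out_dir, f))
    sel_files <- c(sel_files, f)
  }
  writeLines(as.character(jsonlite::toJSON(params, auto_unbox = TRUE,
                                           digits = NA)),
             file.path(out_dir, "params.json"))
  manifest <- list(format_version = 1L,
                   plugin_file = "plugin.R",
                   plugin_name = plugin_name,
                   plugin_digest = plugin_file_digest(plugin_path),
                   selections = sel_files,
                   params_file = "params.json",
                   result_file = "result.h5",
                   package = "ephyskit",
                   package_version = as.character(utils::packageVersion("ephyskit")))
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE)),
             file.path(out_dir, "manifest.json"))
  writeLines(c("#!/usr/bin/env Rscript",
               "# standalone analysis bundle: restores the stored selections,",
               "# runs the bundled plugin and writes result.h5 next to this script",
               "args <- commandArgs(trailingOnly = FALSE)",
               "self <- sub('^--file=', '', grep('^--file=', args, value = TRUE)[1])",
               "library(ephyskit)",
               "run_bundle(dirname(normalizePath(self)))"),
             file.path(out_dir, "run"))
  Sys.chmod(file.path(out_dir, "run"), "0755")
  invisible(out_dir)
}

#' Execute a standalone bundle
#'
#' Loads the manifest, selections and parameters from `dir`, restores a
#' provider over the first selection (all restored selections are passed to
#' the plugin), runs the plugin and writes the result to the bundle's result
#' file in the HDF5 result layout.
#'
#' @param dir bundle directory written by [export_standalone()].
#' @param registry IO registry used to reload the data.
#' @return The result value, invisibly.
#' @export
run_bundle <- function(dir, registry = default_registry()) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path))
    stop(sprintf("bundle error: '%s' has no manifest.json", dir), call. = FALSE)
  mf <- jsonlite::fromJSON(paste(readLines(mf_path), collapse = "\n"),
                           simplifyVector = TRUE)
  sels <- lapply(mf$selections, function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p))
      stop(sprintf("bundle error: selection file '%s' is missing", p),
           call. = FALSE)
    load_selection(p)
  })
  if (!length(sels))
    stop(sprintf("bundle error: '%s' stores no selections", dir), call. = FALSE)
  params <- jsonlite::fromJSON(paste(readLines(file.path(dir, mf$params_file)),
                                     collapse = "\n"),
                               simplifyVector = TRUE)
  if (!is.list(params)) params <- as.list(params)
  plugin <- .load_plugin_file(file.path(dir, mf$plugin_file),
                              if (!is.null(mf$plugin_name) && !is.na(mf$plugin_name %||% NA)) mf$plugin_name)
  providers <- lapply(sels, provider_from_selection, registry = registry)
  res <- run_in_process(plugin, providers[[1]], params, selections = providers)
  write_result(res, file.path(dir, mf$result_file))
  invisible(res)
}

#' Run a startup script
#'
#' Executes an R script before plugins or data are loaded, letting users
#' adjust configuration (plugin directories, autoload behavior, plot colors,
#' ...). The script sees and may modify the list `config`. A missing script
#' is a no-op; a failing script logs the error and the defaults are kept.
#'
#' @param path script path.
#' @param config named list of configuration defaults.
#' @return The (possibly updated) configuration list.
#' @export
run_startup_script <- function(path, config = list()) {
  if (is.null(path) || !file.exists(path)) return(config)
  env <- new.env(parent = globalenv())
  env$config <- config
  ok <- tryCatch({ sys.source(path, envir = env); TRUE },
                 error = function(e) {
                   warning(sprintf("startup script '%s' failed (%s); continuing with defaults",
                                   path, conditionMessage(e)), call. = FALSE)
                   FALSE
                 })
  if (ok) env$config else config
}
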