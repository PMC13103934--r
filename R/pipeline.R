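# Registered pipeline operations: name -> (fn(set, params) -> SpectrumSet,
# defaults, required). Baseline steps return the corrected set; their full
# diagnostics are available through the standalone baseline* functions.
.opRegistry <- new.env(parent = emptyenv())

.registerOp <- function(name, fn, defaults = list(), required = character(0),
                        aliases = character(0)) {
  entry <- list(name = name, fn = fn, defaults = defaults, required = required)
  assign(name, entry, envir = .opRegistry)
  for (a in aliases) assign(a, entry, envir = .opRegistry)
}

.initRegistry <- function() {
  .registerOp("interpolate_to_grid",
              function(set, p) interpolateToGrid(set),
              aliases = "interpolate")
  .registerOp("crop",
              function(set, p) cropSpectra(set, p$lo, p$hi),
              required = c("lo", "hi"))
  .registerOp("despike",
              function(set, p) despike(set, p$regions, p$threshold, p$window),
              defaults = list(regions = "all", threshold = 300, window = 11L))
  .registerOp("smooth_savgol",
              function(set, p) smoothSavgol(set, p$window, p$polyorder),
              defaults = list(window = 15L, polyorder = 2L),
              aliases = "savgol")
  .registerOp("smooth_fourier",
              function(set, p) smoothFourier(set, p$cutoff),
              required = "cutoff",
              aliases = "fourier")
  .registerOp("baseline_airpls",
              function(set, p) correctedSet(set,
                baselineAirPLS(set, p$lam, p$order, p$max_iter, p$tol)),
              defaults = list(lam = 100, order = 1L, max_iter = 15L,
                              tol = 0.001),
              aliases = "airpls")
  .registerOp("baseline_polynomial",
              function(set, p) correctedSet(set,
                baselinePolynomial(set, p$order, p$max_iter, p$tol)),
              defaults = list(order = 3L, max_iter = 100L, tol = 1e-3))
  .registerOp("baseline_glfit",
              function(set, p) correctedSet(set,
                baselineGLFit(set, p$n_components, p$min_width)),
              defaults = list(n_components = 1L, min_width = 200))
  .registerOp("normalize",
              function(set, p) normalizeSpectra(set, p$mode, p$peak_position),
              defaults = list(mode = "area", peak_position = NULL))
}

#' List the registered pipeline operations
#'
#' @return Character vector of canonical operation names and aliases.
#' @export
pipelineOperations <- function() sort(ls(.opRegistry))

#' Build a validated pipeline configuration
#'
#' A configuration is an ordered list of steps, each an operation name plus a
#' parameter map. Every name must resolve to a registered operation and every
#' parameter must be one that operation declares; defaults are expanded at
#' validation time so the resolved configuration (and any provenance recorded
#' from it) is self-contained.
#'
#' @param steps list of steps; each step is `list(op = "name", <param> = ...)`.
#' @return List of class `"PipelineConfig"` with fully resolved parameters.
#' @examples
#' cfg <- pipelineConfig(list(
#'   list(op = "crop", lo = 600, hi = 1600),
#'   list(op = "normalize", mode = "area")))
#' @export
pipelineConfig <- function(steps) {
  if (!is.list(steps)) stop("steps must be a list")
  resolved <- vector("list", length(steps))
  for (i in seq_along(steps)) {
    s <- steps[[i]]
    if (is.character(s) && length(s) == 1L) s <- list(op = s)
    if (!is.null(s$params)) s <- c(list(op = s$op), s$params)  # resolved form
    if (!is.list(s) || is.null(s$op))
      stop("step ", i, ": each step needs an 'op' field")
    if (!exists(s$op, envir = .opRegistry))
      stop("step ", i, ": unknown operation '", s$op, "' (known: ",
           paste(pipelineOperations(), collapse = ", "), ")")
    entry <- get(s$op, envir = .opRegistry)
    given <- s[setdiff(names(s), "op")]
    known <- c(names(entry$defaults), entry$required)
    bad <- setdiff(names(given), known)
    if (length(bad))
      stop("step ", i, " (", entry$name, "): unknown parameter(s) ",
           paste(bad, collapse = ", "))
    absent <- setdiff(entry$required, names(given))
    if (length(absent))
      stop("step ", i, " (", entry$name, "): missing required parameter(s) ",
           paste(absent, collapse = ", "))
    params <- entry$defaults
    params[names(given)] <- given
    resolved[[i]] <- list(op = entry$name, params = params)
  }
  structure(list(steps = resolved), class = "PipelineConfig")
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig with", length(x$steps), "step(s):\n")
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat(sprintf("  %d. %s(%s)\n", i, s$op, .paramString(s$params)))
  }
  invisible(x)
}

.paramString <- function(p) {
  if (!length(p)) return("")
  paste(vapply(names(p), function(k) {
    v <- p[[k]]
    paste0(k, "=", if (is.null(v)) "NULL" else
      paste(unlist(v), collapse = ";"))
  }, ""), collapse = ", ")
}

#' Read / write a pipeline configuration as YAML
#'
#' The on-disk dialect is a YAML map with an ordered `steps` list whose items
#' carry the registered operation name under `op` plus its parameters, e.g.
#' `steps: [{op: baseline_airpls, lam: 100, order: 1, max_iter: 15, tol: 0.001}]`.
#'
#' @param path YAML file.
#' @return `readPipelineConfig` returns a validated [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$steps)) stop("config file has no 'steps' list: ", path)
  pipelineConfig(raw$steps)
}

#' @rdname readPipelineConfig
#' @param config a `PipelineConfig`.
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  steps <- lapply(config$steps, function(s) c(list(op = s$op), s$params))
  yaml::write_yaml(list(steps = steps), path)
  invisible(path)
}

#' Run a preprocessing pipeline with provenance recording
#'
#' Applies the configured steps in order to all spectra of the set. The
#' returned provenance log holds, per executed step, the operation name, the
#' exact parameters used (defaults expanded), input/output shapes and a
#' timestamp; [replayPipeline()] on the original input reproduces the output
#' bit-identically. The first failing step aborts the run, reporting its
#' index and cause; no partial output is returned.
#'
#' @param set a [SpectrumSet-class].
#' @param config a [pipelineConfig()] (or the bare list of steps, which is
#'   validated first).
#' @return List with `set` (processed) and `log` (a `ProvenanceLog`).
#' @export
runPipeline <- function(set, config) {
  stopifnot(is(set, "SpectrumSet"))
  if (!inherits(config, "PipelineConfig")) config <- pipelineConfig(config)
  out <- set
  entries <- vector("list", length(config$steps))
  for (i in seq_along(config$steps)) {
    s <- config$steps[[i]]
    entry <- get(s$op, envir = .opRegistry)
    inShape <- c(nSpectra(out), nWavenumbers(out))
    res <- tryCatch(entry$fn(out, s$params), error = function(e)
      stop("pipeline step ", i, " (", s$op, ") failed: ",
           conditionMessage(e), call. = FALSE))
    entries[[i]] <- list(step = i, op = s$op, params = s$params,
                         input_shape = inShape,
                         output_shape = c(nSpectra(res), nWavenumbers(res)),
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"))
    out <- res
  }
  list(set = out, log = structure(entries, class = "ProvenanceLog"))
}

#' @export
print.ProvenanceLog <- function(x, ...) {
  cat(sprintf("ProvenanceLog with %d %s:\n", length(x),
              if (length(x) == 1L) "entry" else "entries"))
  for (e in x)
    cat(sprintf("  %d. %s(%s)  %dx%d -> %dx%d\n", e$step, e$op,
                .paramString(e$params), e$input_shape[1L], e$input_shape[2L],
                e$output_shape[1L], e$output_shape[2L]))
  invisible(x)
}

#' Replay a provenance log on its original input
#'
#' Re-executes the recorded operations with their recorded parameters, in
#' order. Because every operation is deterministic, replay reproduces the
#' original pipeline output bit-identically.
#'
#' @param log a `ProvenanceLog` (or a path to one written by
#'   [writeProvenanceLog()]).
#' @param set the original input [SpectrumSet-class].
#' @return The reproduced `SpectrumSet`.
#' @export
replayPipeline <- function(log, set) {
  if (is.character(log)) log <- readProvenanceLog(log)
  stopifnot(inherits(log, "ProvenanceLog"), is(set, "SpectrumSet"))
  cfg <- pipelineConfig(lapply(log, function(e) c(list(op = e$op), e$params)))
  runPipeline(set, cfg)$set
}

#' Serialize / restore a provenance log (JSON, one object per step)
#'
#' @param log a `ProvenanceLog`.
#' @param path JSON file.
#' @return `readProvenanceLog` returns the restored `ProvenanceLog`.
#' @export
writeProvenanceLog <- function(log, path) {
  stopifnot(inherits(log, "ProvenanceLog"))
  jsonlite::write_json(unclass(log), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeProvenanceLog
#' @export
readProvenanceLog <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  entries <- lapply(raw, function(e) {
    e$params <- lapply(e$params, function(v) {
      if (is.list(v)) lapply(v, unlist) else v
    })
    e$input_shape <- unlist(e$input_shape)
    e$output_shape <- unlist(e$output_shape)
    e
  })
  structure(entries, class = "ProvenanceLog")
}
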