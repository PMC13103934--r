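#' spectrakit: reproducible preprocessing and chemometrics for Raman/SERS spectra
#'
#' Spectra live in a [SpectrumSet]: a shared, strictly increasing wavenumber
#' axis (cm\eqn{^{-1}}) and an N x M intensity matrix (N spectra, M axis
#' points), with per-spectrum labels and optional class groups. Preprocessing
#' operations ([interpolateToGrid()], [cropSpectra()], [despike()],
#' [smoothSavgol()], [smoothFourier()], [baselineAirPLS()],
#' [baselinePolynomial()], [baselineGLFit()], [normalizeSpectra()],
#' [detectOutliers()]) act on all spectra of a set at once and never mutate
#' their input. [runPipeline()] chains them under a validated [pipelineConfig()]
#' and records a replayable provenance log. Analytics cover reproducibility
#' statistics ([sigmaAvg()], [relativeVariation()], [summarizeSpectra()]),
#' correlation ([correlationMatrix()]), peak identification ([findPeaks()]),
#' Ward clustering ([hcaWard()]), [pcaSpectra()] and [tsneEmbed()]. The
#' [generateSpectra()] simulator produces seeded replicate sets with stored
#' ground truth so every stage is testable offline.
#'
#' @importFrom methods new validObject is slot
#' @importFrom stats approx runmed sd cor median fft mvfft lm.fit rnorm runif
#'   hclust dist prcomp setNames
#' @importFrom utils read.csv head tail packageVersion
#' @keywords internal
"_PACKAGE"

#' SpectrumSet: a set of spectra on one wavenumber axis
#'
#' The central container: a strictly increasing wavenumber axis of length M
#' shared by N spectra whose intensities form an N x M matrix. Row order of
#' the matrix, `labels` and (optional) `groups` correspond.
#'
#' @slot wavenumbers numeric length-M axis in cm^-1, strictly increasing.
#' @slot intensities numeric N x M matrix, all values finite.
#' @slot labels character length-N unique spectrum identifiers.
#' @slot groups character length-N class labels, or length 0 when ungrouped.
#'
#' @seealso [readSpectra()], [writeSpectra()], [mergeSpectra()]
#' @export
setClass("SpectrumSet",
  slots = c(
    wavenumbers = "numeric",
    intensities = "matrix",
    labels      = "character",
    groups      = "character"
  )
)

setValidity("SpectrumSet", function(object) {
  wn <- object@wavenumbers
  x  <- object@intensities
  msgs <- character(0)
  if (length(wn) < 2L) msgs <- c(msgs, "axis must have at least 2 wavenumbers")
  if (anyNA(wn) || any(!is.finite(wn))) msgs <- c(msgs, "axis must be finite")
  if (length(wn) >= 2L && any(diff(wn) <= 0)) {
    msgs <- c(msgs, "axis must be strictly increasing")
  }
  if (!is.numeric(x)) msgs <- c(msgs, "intensities must be numeric")
  if (nrow(x) < 1L) msgs <- c(msgs, "need at least one spectrum")
  if (ncol(x) != length(wn)) {
    msgs <- c(msgs, sprintf("intensity columns (%d) != axis length (%d)",
                            ncol(x), length(wn)))
  }
  if (any(!is.finite(x))) msgs <- c(msgs, "all intensities must be finite")
  if (length(object@labels) != nrow(x)) {
    msgs <- c(msgs, "one label per spectrum required")
  }
  if (anyDuplicated(object@labels)) msgs <- c(msgs, "labels must be unique")
  if (length(object@groups) != 0L && length(object@groups) != nrow(x)) {
    msgs <- c(msgs, "groups must be empty or one per spectrum")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpectrumSet
#'
#' @param wavenumbers strictly increasing numeric axis (cm^-1), length M.
#' @param intensities N x M numeric matrix (one row per spectrum). A plain
#'   vector is treated as a single spectrum.
#' @param labels spectrum identifiers; defaults to `"s1" ... "sN"`.
#' @param groups optional class labels (length N).
#' @return A validated [SpectrumSet-class] object.
#' @examples
#' s <- SpectrumSet(400:410, rbind(a = rnorm(11), b = rnorm(11)))
#' nSpectra(s)
#' @export
SpectrumSet <- function(wavenumbers, intensities, labels = NULL, groups = NULL) {
  if (is.null(dim(intensities))) intensities <- matrix(intensities, nrow = 1L)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(labels)) {
    labels <- rownames(intensities)
    if (is.null(labels) || anyDuplicated(labels))
      labels <- paste0("s", seq_len(nrow(intensities)))
  }
  rownames(intensities) <- NULL
  dimnames(intensities) <- NULL
  new("SpectrumSet",
      wavenumbers = as.numeric(wavenumbers),
      intensities = intensities,
      labels      = as.character(labels),
      groups      = if (is.null(groups)) character(0) else as.character(groups))
}

#' @describeIn SpectrumSet number of spectra N.
#' @param x,object a `SpectrumSet`.
#' @export
nSpectra <- function(x) nrow(x@intensities)

#' @describeIn SpectrumSet number of axis points M.
#' @export
nWavenumbers <- function(x) length(x@wavenumbers)

#' @describeIn SpectrumSet the shared wavenumber axis.
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname SpectrumSet
#' @export
setMethod("wavenumbers", "SpectrumSet", function(x) x@wavenumbers)

#' @describeIn SpectrumSet the N x M intensity matrix (labels as rownames).
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname SpectrumSet
#' @export
setMethod("intensities", "SpectrumSet", function(x) {
  m <- x@intensities
  rownames(m) <- x@labels
  m
})

#' @describeIn SpectrumSet spectrum labels.
#' @export
setGeneric("spectrumNames", function(x) standardGeneric("spectrumNames"))

#' @rdname SpectrumSet
#' @export
setMethod("spectrumNames", "SpectrumSet", function(x) x@labels)

#' @describeIn SpectrumSet class labels (`NULL` when ungrouped).
#' @export
setGeneric("spectrumGroups", function(x) standardGeneric("spectrumGroups"))

#' @rdname SpectrumSet
#' @export
setMethod("spectrumGroups", "SpectrumSet", function(x) {
  if (length(x@groups)) x@groups else NULL
})

#' @rdname SpectrumSet
#' @param i spectrum (row) index, label, or logical selector.
#' @param j axis (column) index or logical selector.
#' @param ... ignored.
#' @param drop ignored; subsetting always returns a `SpectrumSet`.
#' @export
setMethod("[", "SpectrumSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nSpectra(x))
  if (is.character(i)) i <- match(i, x@labels)
  if (missing(j)) j <- seq_len(nWavenumbers(x))
  SpectrumSet(x@wavenumbers[j],
              x@intensities[i, j, drop = FALSE],
              labels = x@labels[i],
              groups = if (length(x@groups)) x@groups[i] else NULL)
})

setMethod("show", "SpectrumSet", function(object) {
  wn <- object@wavenumbers
  cat(sprintf("SpectrumSet: %d spectra x %d wavenumbers [%g, %g] cm^-1\n",
              nSpectra(object), nWavenumbers(object), min(wn), max(wn)))
  lab <- object@labels
  cat("  labels: ", paste(head(lab, 4L), collapse = ", "),
      if (length(lab) > 4L) ", ..." else "", "\n", sep = "")
  if (length(object@groups)) {
    tab <- table(object@groups)
    cat("  groups: ",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n",
        sep = "")
  }
  invisible(NULL)
})

# internal: replace the intensity matrix, preserving axis/labels/groups
.withIntensities <- function(x, m) {
  dimnames(m) <- NULL
  new("SpectrumSet", wavenumbers = x@wavenumbers, intensities = m,
      labels = x@labels, groups = x@groups)
}

#' BaselineResult: estimated baselines and corrected spectra
#'
#' Returned by the baseline-correction operations. `corrected + baselines`
#' reconstructs the input to floating-point round-off (conservation).
#'
#' @slot baselines N x M matrix of estimated baselines.
#' @slot corrected N x M matrix of input minus baseline.
#' @slot iterationsUsed integer per-spectrum iteration counts.
#' @slot converged logical per-spectrum convergence flags.
#' @slot method character, the baseline method name.
#' @slot labels character spectrum labels (input order).
#'
#' @seealso [baselineAirPLS()], [baselinePolynomial()], [baselineGLFit()],
#'   [correctedSet()]
#' @export
setClass("BaselineResult",
  slots = c(
    baselines      = "matrix",
    corrected      = "matrix",
    iterationsUsed = "integer",
    converged      = "logical",
    method         = "character",
    labels         = "character"
  )
)

setValidity("BaselineResult", function(object) {
  if (!identical(dim(object@baselines), dim(object@corrected)))
    return("baselines and corrected must have identical dimensions")
  n <- nrow(object@baselines)
  if (length(object@iterationsUsed) != n || length(object@converged) != n)
    return("per-spectrum iteration counts and flags required")
  TRUE
})

setMethod("show", "BaselineResult", function(object) {
  cat(sprintf("BaselineResult (%s): %d spectra x %d points; %d/%d converged; iterations %s\n",
              object@method, nrow(object@baselines), ncol(object@baselines),
              sum(object@converged), length(object@converged),
              paste(range(object@iterationsUsed), collapse = "-")))
  invisible(NULL)
})

#' @describeIn BaselineResult estimated baselines (N x M matrix).
#' @param x,object a `BaselineResult`.
#' @export
baselines <- function(x) {
  stopifnot(is(x, "BaselineResult"))
  m <- x@baselines
  rownames(m) <- x@labels
  m
}

#' @describeIn BaselineResult baseline-corrected intensities (N x M matrix).
#' @export
correctedIntensities <- function(x) {
  stopifnot(is(x, "BaselineResult"))
  m <- x@corrected
  rownames(m) <- x@labels
  m
}

#' Rebuild a SpectrumSet from a baseline correction
#'
#' @param set the `SpectrumSet` the correction was computed from.
#' @param result the matching [BaselineResult-class].
#' @return `set` with its intensities replaced by the corrected matrix.
#' @export
correctedSet <- function(set, result) {
  stopifnot(is(set, "SpectrumSet"), is(result, "BaselineResult"))
  if (!identical(dim(set@intensities), dim(result@corrected)))
    stop("set and BaselineResult dimensions disagree")
  .withIntensities(set, result@corrected)
}

#' Export a BaselineResult's per-spectrum record as a data.frame
#'
#' @param x a `BaselineResult`.
#' @return data.frame with label, iterations and convergence flag per spectrum.
#' @export
baselineReport <- function(x) {
  stopifnot(is(x, "BaselineResult"))
  data.frame(label = x@labels,
             iterations = x@iterationsUsed,
             converged = x@converged,
             stringsAsFactors = FALSE)
}
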