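#' Read spectra from text files
#'
#' Two supported layouts. `two_column`: per-spectrum files, whitespace- or
#' comma-separated, `#` comment lines allowed, column 1 = wavenumber (cm^-1),
#' column 2 = intensity; all files must share an identical axis (interpolate
#' to a common grid first if they do not). `wide_table`: one CSV with a header
#' row, first column named `wavenumber` (case-insensitive), remaining columns
#' one spectrum each.
#'
#' @param paths file path(s); `wide_table` expects exactly one.
#' @param format `"two_column"` or `"wide_table"`.
#' @return A [SpectrumSet-class]; labels default to file stems / header names.
#' @details A decreasing or duplicated axis is an error, never silently
#'   re-sorted. Decimal points only (no locale decimal commas).
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("# demo", "400 10", "401 12", "402 11"), f)
#' readSpectra(f, "two_column")
#' @export
readSpectra <- function(paths, format = c("two_column", "wide_table")) {
  format <- match.arg(format)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing file(s): ", paste(missing, collapse = ", "))
  if (format == "two_column") .readTwoColumn(paths) else .readWideTable(paths)
}

.checkAxis <- function(wn, where) {
  if (anyNA(wn)) stop("non-numeric wavenumber in ", where)
  if (anyDuplicated(wn)) stop("duplicate wavenumber in ", where)
  if (any(diff(wn) <= 0))
    stop("wavenumber axis not strictly increasing in ", where,
         " (sort the file explicitly; auto-sorting is refused)")
  wn
}

.readTwoColumn <- function(paths) {
  one <- function(p) {
    lines <- readLines(p, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) stop("no data rows in ", p)
    fields <- strsplit(gsub(",", " ", lines), "[[:space:]]+")
    ncols <- lengths(fields)
    if (any(ncols < 2L))
      stop("row with fewer than 2 columns in ", p)
    wn <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
    y  <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
    if (anyNA(y)) stop("non-numeric intensity in ", p)
    .checkAxis(wn, p)
    list(wn = wn, y = y)
  }
  parsed <- lapply(paths, one)
  wn <- parsed[[1L]]$wn
  for (i in seq_along(parsed)[-1L]) {
    if (!identical(length(parsed[[i]]$wn), length(wn)) ||
        !all(parsed[[i]]$wn == wn)) {
      stop("axis mismatch: '", paths[i], "' does not share the axis of '",
           paths[1L], "'. Interpolate all spectra to a common grid ",
           "(interpolateToGrid) before combining two-column files.")
    }
  }
  SpectrumSet(wn,
              do.call(rbind, lapply(parsed, `[[`, "y")),
              labels = make.unique(tools::file_path_sans_ext(basename(paths))))
}

.readWideTable <- function(paths) {
  if (length(paths) != 1L)
    stop("wide_table format expects exactly one file")
  df <- read.csv(paths, check.names = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("wide table needs a wavenumber column plus >= 1 spectrum")
  if (tolower(names(df)[1L]) != "wavenumber")
    stop("first column of a wide table must be named 'wavenumber' (got '",
         names(df)[1L], "')")
  wn <- suppressWarnings(as.numeric(df[[1L]]))
  .checkAxis(wn, paths)
  m <- as.matrix(df[-1L])
  if (!is.numeric(m) || anyNA(m)) stop("non-numeric intensity cell in ", paths)
  SpectrumSet(wn, t(m), labels = names(df)[-1L])
}

# repr-faithful double formatting: %.17g round-trips exactly through as.numeric
.fmt <- function(x) sprintf("%.17g", x)

#' Write spectra to text files
#'
#' Inverse of [readSpectra()]: round-tripping reproduces axis, intensities and
#' labels exactly (doubles are printed with 17 significant digits).
#'
#' @param set a [SpectrumSet-class].
#' @param path `wide_table`: the output CSV file. `two_column`: a directory;
#'   one `<label>.txt` file per spectrum is written into it.
#' @param format `"two_column"` or `"wide_table"`.
#' @return Invisibly, the path(s) written.
#' @export
writeSpectra <- function(set, path, format = c("two_column", "wide_table")) {
  format <- match.arg(format)
  stopifnot(is(set, "SpectrumSet"))
  if (format == "wide_table") {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    header <- paste(c("wavenumber", set@labels), collapse = ",")
    body <- apply(cbind(set@wavenumbers, t(set@intensities)), 1L,
                  function(r) paste(.fmt(r), collapse = ","))
    writeLines(c(header, body), path)
    invisible(path)
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    files <- file.path(path, paste0(set@labels, ".txt"))
    for (i in seq_len(nSpectra(set))) {
      writeLines(paste(.fmt(set@wavenumbers), .fmt(set@intensities[i, ])),
                 files[i])
    }
    invisible(files)
  }
}

#' Merge two SpectrumSets sharing an axis
#'
#' @param a,b [SpectrumSet-class] objects on identical axes with disjoint
#'   labels.
#' @return A `SpectrumSet` with `nSpectra(a) + nSpectra(b)` spectra; group
#'   labels are preserved (spectra of an ungrouped operand get `NA`).
#' @export
mergeSpectra <- function(a, b) {
  stopifnot(is(a, "SpectrumSet"), is(b, "SpectrumSet"))
  if (length(a@wavenumbers) != length(b@wavenumbers) ||
      !all(a@wavenumbers == b@wavenumbers))
    stop("axis mismatch: sets must share an identical wavenumber axis")
  clash <- intersect(a@labels, b@labels)
  if (length(clash))
    stop("label collision: ", paste(clash, collapse = ", "))
  groups <- NULL
  if (length(a@groups) || length(b@groups)) {
    ga <- if (length(a@groups)) a@groups else rep(NA_character_, nSpectra(a))
    gb <- if (length(b@groups)) b@groups else rep(NA_character_, nSpectra(b))
    groups <- c(ga, gb)
  }
  SpectrumSet(a@wavenumbers, rbind(a@intensities, b@intensities),
              labels = c(a@labels, b@labels), groups = groups)
}
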