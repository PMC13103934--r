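#' Interpolate spectra onto the integer wavenumber grid
#'
#' Standardizes spacing by rounding the axis to whole wavenumbers: the new
#' axis runs in steps of 1 cm^-1 from `ceiling(min(axis))` to
#' `floor(max(axis))` and intensities are linearly interpolated between the
#' two bracketing original samples. No extrapolation beyond the original
#' range ever occurs.
#'
#' @param set a [SpectrumSet-class].
#' @return A `SpectrumSet` on the integer grid.
#' @export
interpolateToGrid <- function(set) {
  stopifnot(is(set, "SpectrumSet"))
  wn <- set@wavenumbers
  grid <- seq(ceiling(min(wn)), floor(max(wn)))
  if (length(grid) < 2L)
    stop("axis range [", min(wn), ", ", max(wn),
         "] spans fewer than 2 integer wavenumbers")
  m <- t(apply(set@intensities, 1L,
               function(y) approx(wn, y, xout = grid, method = "linear")$y))
  SpectrumSet(as.numeric(grid), m, labels = set@labels,
              groups = spectrumGroups(set))
}

#' Crop spectra to a wavenumber window
#'
#' Restricts the axis to `[lo, hi]` inclusive, e.g. the feature-rich
#' 600-1600 cm^-1 fingerprint region.
#'
#' @param set a [SpectrumSet-class].
#' @param lo,hi window bounds in cm^-1, `lo < hi`.
#' @return The cropped `SpectrumSet` (at least 2 points must remain).
#' @export
cropSpectra <- function(set, lo, hi) {
  stopifnot(is(set, "SpectrumSet"))
  if (!(is.numeric(lo) && is.numeric(hi)) || lo >= hi)
    stop("crop bounds must satisfy lo < hi (got ", lo, ", ", hi, ")")
  keep <- which(set@wavenumbers >= lo & set@wavenumbers <= hi)
  if (length(keep) < 2L)
    stop("fewer than 2 axis points in [", lo, ", ", hi, "]")
  set[, keep]
}

#' Remove cosmic-ray spikes by running-median thresholding
#'
#' Within each requested window, points whose intensity exceeds the running
#' median (window length `window`) by more than `threshold` are flagged as
#' spikes and replaced by linear interpolation across the nearest unflagged
#' neighbours. Points outside the windows are left bit-identical. The running
#' median is robust to the spike itself, so single-sample cosmic-ray events
#' do not mask their own detection.
#'
#' @param set a [SpectrumSet-class].
#' @param regions list of `c(lo, hi)` wavenumber windows, or `"all"` (default)
#'   for the whole axis.
#' @param threshold detection threshold in absolute intensity units (> 0);
#'   300 is a typical value on raw counts.
#' @param window odd running-median window length, `3 <= window <= M`.
#' @return The despiked `SpectrumSet`.
#' @export
despike <- function(set, regions = "all", threshold = 300, window = 11L) {
  stopifnot(is(set, "SpectrumSet"))
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  window <- as.integer(window)
  M <- nWavenumbers(set)
  if (window %% 2L == 0L || window < 3L || window > M)
    stop("window must be odd, >= 3 and <= ", M, " (got ", window, ")")
  wn <- set@wavenumbers
  if (identical(regions, "all")) regions <- list(range(wn))
  if (is.matrix(regions)) regions <- asplit(regions, 1L)
  if (!is.list(regions)) regions <- list(regions)
  idx <- lapply(regions, function(r) {
    r <- sort(as.numeric(r))
    k <- which(wn >= r[1L] & wn <= r[2L])
    if (!length(k))
      stop("region [", r[1L], ", ", r[2L], "] contains no axis points")
    k
  })
  m <- set@intensities
  for (i in seq_len(nrow(m))) {
    y <- m[i, ]
    flagged <- logical(M)
    for (k in idx) {
      seg <- y[k]
      w <- min(window, if (length(seg) %% 2L) length(seg) else length(seg) - 1L)
      med <- if (w >= 3L) runmed(seg, w, endrule = "median") else seg
      flagged[k[seg - med > threshold]] <- TRUE
    }
    if (any(flagged)) {
      ok <- which(!flagged)
      for (j in which(flagged)) {
        left  <- ok[ok < j]
        right <- ok[ok > j]
        if (length(left) && length(right)) {
          l <- max(left); r <- min(right)
          y[j] <- y[l] + (wn[j] - wn[l]) / (wn[r] - wn[l]) * (y[r] - y[l])
        } else if (length(left)) {
          y[j] <- y[max(left)]
        } else {
          y[j] <- y[min(right)]
        }
      }
      m[i, ] <- y
    }
  }
  .withIntensities(set, m)
}

# Savitzky-Golay least-squares design: coefficients that evaluate the
# polynomial fit over offsets `offs` at offset `at`
.sgRow <- function(offs, polyorder, at) {
  A <- outer(offs, 0:polyorder, `^`)
  # row of pinv(A) picked out by the monomial basis evaluated at `at`
  drop(at^(0:polyorder) %*% solve(crossprod(A), t(A)))
}

#' Savitzky-Golay smoothing
#'
#' Moving least-squares polynomial smoothing: each point is replaced by the
#' value at its own position of a degree-`polyorder` polynomial fitted to the
#' surrounding `window` samples. Interior points use the centred kernel; at
#' the edges the polynomial is fitted to the available one-sided window so no
#' signal is truncated and M is unchanged. Polynomials of degree up to
#' `polyorder` are reproduced exactly.
#'
#' @param set a [SpectrumSet-class].
#' @param window odd window length, `polyorder < window <= M`.
#' @param polyorder polynomial order (e.g. 2).
#' @return The smoothed `SpectrumSet`.
#' @export
smoothSavgol <- function(set, window = 15L, polyorder = 2L) {
  stopifnot(is(set, "SpectrumSet"))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  M <- nWavenumbers(set)
  if (window %% 2L == 0L) stop("window must be odd (got ", window, ")")
  if (polyorder < 0L || polyorder >= window || window > M)
    stop("need polyorder < window <= M (got polyorder=", polyorder,
         ", window=", window, ", M=", M, ")")
  h <- (window - 1L) %/% 2L
  centre <- .sgRow(-h:h, polyorder, 0)
  m <- set@intensities
  out <- m
  for (i in seq_len(nrow(m))) {
    y <- m[i, ]
    sm <- as.numeric(stats::filter(y, rev(centre), sides = 2L))
    # edges: polynomial fitted to the first/last `window` samples,
    # evaluated at each edge position
    for (j in seq_len(h)) {
      sm[j]         <- sum(.sgRow(0:(window - 1L), polyorder, j - 1L) *
                             y[seq_len(window)])
      sm[M - j + 1L] <- sum(.sgRow(-(window - 1L):0, polyorder, -(j - 1L)) *
                              y[(M - window + 1L):M])
    }
    out[i, ] <- sm
  }
  .withIntensities(set, out)
}

#' Fourier low-pass smoothing
#'
#' Each spectrum is mirror-padded to length 2M (bounding edge ringing),
#' transformed with the FFT, components above `cutoff` x Nyquist are zeroed,
#' and the first M real values of the inverse transform are returned.
#'
#' @param set a [SpectrumSet-class].
#' @param cutoff pass-band edge as a fraction of the Nyquist frequency,
#'   in (0, 1]; `cutoff = 1` is the identity to round-off.
#' @return The filtered `SpectrumSet`.
#' @export
smoothFourier <- function(set, cutoff) {
  stopifnot(is(set, "SpectrumSet"))
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1)
    stop("cutoff must be in (0, 1]")
  M <- nWavenumbers(set)
  L <- 2L * M
  j <- 0:(L - 1L)
  freq <- pmin(j, L - j) / L          # cycles per sample; Nyquist = 0.5
  kill <- freq > cutoff * 0.5
  m <- set@intensities
  for (i in seq_len(nrow(m))) {
    yp <- c(m[i, ], rev(m[i, ]))
    Y <- fft(yp)
    Y[kill] <- 0
    m[i, ] <- Re(fft(Y, inverse = TRUE) / L)[seq_len(M)]
  }
  .withIntensities(set, m)
}

#' Normalize spectra
#'
#' `area`: divides each spectrum by its trapezoidal area over the axis so the
#' integrated area equals one. `peak`: divides by the maximum intensity, or by
#' the intensity at the axis sample nearest `peak_position` when given.
#' `minmax`: affine map of each spectrum so min -> 0 and max -> 1. All three
#' modes are idempotent.
#'
#' @param set a [SpectrumSet-class].
#' @param mode `"area"`, `"peak"` or `"minmax"`.
#' @param peak_position optional wavenumber for `peak` mode.
#' @return The normalized `SpectrumSet`.
#' @export
normalizeSpectra <- function(set, mode = c("area", "peak", "minmax"),
                             peak_position = NULL) {
  stopifnot(is(set, "SpectrumSet"))
  mode <- match.arg(mode)
  m <- set@intensities
  wn <- set@wavenumbers
  for (i in seq_len(nrow(m))) {
    y <- m[i, ]
    lab <- set@labels[i]
    if (mode == "area") {
      a <- pracma::trapz(wn, y)
      if (a == 0) stop("zero trapezoidal area for spectrum '", lab, "'")
      m[i, ] <- y / a
    } else if (mode == "peak") {
      ref <- if (is.null(peak_position)) max(y) else
        y[which.min(abs(wn - peak_position))]
      if (ref == 0) stop("zero peak reference for spectrum '", lab, "'")
      m[i, ] <- y / ref
    } else {
      rng <- range(y)
      if (rng[1L] == rng[2L])
        stop("constant spectrum '", lab, "' cannot be min/max scaled")
      m[i, ] <- (y - rng[1L]) / (rng[2L] - rng[1L])
    }
  }
  .withIntensities(set, m)
}

#' Screen a set for outlier spectra
#'
#' Each spectrum is compared against the leave-one-out consensus mean of the
#' remaining spectra using three criteria: (a) Pearson correlation with the
#' consensus below `corr_thresh`; (b) mean absolute deviation from the
#' consensus above `sd_thresh` times the mean per-wavenumber sample SD of the
#' full set; (c) Euclidean distance to the consensus above `dist_thresh`
#' times the median of those distances over all spectra. Flags combine with
#' OR (`combine = "any"`, default) or AND (`"all"`).
#'
#' @param set a [SpectrumSet-class] with at least 3 spectra.
#' @param corr_thresh correlation threshold in (-1, 1).
#' @param sd_thresh,dist_thresh positive multipliers.
#' @param combine `"any"` or `"all"`.
#' @return A data.frame with one row per spectrum: the three scores, the
#'   per-criterion flags, and the combined `outlier` flag. If a leave-one-out
#'   consensus is constant the correlation criterion is skipped for that
#'   spectrum (score `NA`, flag `FALSE`) and a warning is recorded in
#'   `attr(, "warnings")`.
#' @export
detectOutliers <- function(set, corr_thresh = 0.9, sd_thresh = 3,
                           dist_thresh = 3, combine = c("any", "all")) {
  stopifnot(is(set, "SpectrumSet"))
  combine <- match.arg(combine)
  n <- nSpectra(set)
  if (n < 3L) stop("outlier screening needs at least 3 spectra")
  m <- set@intensities
  colMean <- colMeans(m)
  pooledSD <- mean(apply(m, 2L, sd))
  corScore <- distScore <- devScore <- numeric(n)
  warns <- character(0)
  for (i in seq_len(n)) {
    consensus <- (colMean * n - m[i, ]) / (n - 1L)   # leave-one-out mean
    if (sd(consensus) == 0 || sd(m[i, ]) == 0) {
      corScore[i] <- NA_real_
      warns <- c(warns, sprintf(
        "correlation undefined for '%s' (constant spectrum or consensus); criterion skipped",
        set@labels[i]))
    } else {
      corScore[i] <- cor(m[i, ], consensus)
    }
    devScore[i]  <- mean(abs(m[i, ] - consensus)) /
      (if (pooledSD > 0) pooledSD else 1)
    distScore[i] <- sqrt(sum((m[i, ] - consensus)^2))
  }
  medDist <- median(distScore)
  distRatio <- if (medDist > 0) distScore / medDist else
    ifelse(distScore > 0, Inf, 0)
  flagCor  <- !is.na(corScore) & corScore < corr_thresh
  flagDev  <- devScore > sd_thresh
  flagDist <- distRatio > dist_thresh
  outlier <- if (combine == "any") flagCor | flagDev | flagDist else
    flagCor & flagDev & flagDist
  out <- data.frame(label = set@labels,
                    correlation = corScore,
                    deviation = devScore,
                    distance_ratio = distRatio,
                    flag_correlation = flagCor,
                    flag_deviation = flagDev,
                    flag_distance = flagDist,
                    outlier = outlier,
                    stringsAsFactors = FALSE)
  attr(out, "combine") <- combine
  if (length(warns)) {
    attr(out, "warnings") <- warns
    warning(paste(warns, collapse = "; "))
  }
  out
}
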