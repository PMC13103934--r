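#' Average spectral variation
#'
#' The reproducibility statistic
#' \deqn{\sigma_{avg} = \frac{1}{M}\sum_{k=1}^{M}
#'   \sqrt{\frac{1}{N-1}\sum_{i=1}^{N}\bigl(I_i(\Delta v_k) -
#'   \bar I(\Delta v_k)\bigr)^2},}
#' the mean over wavenumbers of the across-replicate sample standard
#' deviation. It is scale-equivariant (`sigmaAvg(c*I) = |c|*sigmaAvg(I)`) and
#' invariant to adding a constant to all spectra simultaneously.
#'
#' @param set a [SpectrumSet-class] with N >= 2.
#' @return Scalar, in intensity units.
#' @export
sigmaAvg <- function(set) {
  stopifnot(is(set, "SpectrumSet"))
  if (nSpectra(set) < 2L) stop("sigmaAvg needs at least 2 spectra")
  mean(apply(set@intensities, 2L, sd))
}

#' Relative spectral variation
#'
#' [sigmaAvg()] divided by the integrated (trapezoidal) area under the mean
#' spectrum — a dimensionless reproducibility measure, invariant to scaling
#' all intensities by a common positive factor. After area normalization the
#' mean-spectrum area is one, so the relative variation equals `sigmaAvg`.
#'
#' @param set a [SpectrumSet-class] with N >= 2.
#' @return Dimensionless scalar.
#' @export
relativeVariation <- function(set) {
  stopifnot(is(set, "SpectrumSet"))
  if (nSpectra(set) < 2L) stop("relativeVariation needs at least 2 spectra")
  area <- pracma::trapz(set@wavenumbers, colMeans(set@intensities))
  if (area == 0) stop("mean spectrum has zero trapezoidal area")
  sigmaAvg(set) / area
}

#' Per-wavenumber summary statistics
#'
#' Mean spectrum, per-wavenumber sample standard deviation (N-1 denominator)
#' and the `mean +/- k*SD` confidence band.
#'
#' @param set a [SpectrumSet-class] with N >= 2.
#' @param k band half-width in standard deviations (default 1).
#' @return data.frame with columns `wavenumber`, `mean`, `sd`, `lower`,
#'   `upper` (M rows).
#' @export
summarizeSpectra <- function(set, k = 1) {
  stopifnot(is(set, "SpectrumSet"))
  if (nSpectra(set) < 2L) stop("summarizeSpectra needs at least 2 spectra")
  mu <- colMeans(set@intensities)
  s <- apply(set@intensities, 2L, sd)
  data.frame(wavenumber = set@wavenumbers, mean = mu, sd = s,
             lower = mu - k * s, upper = mu + k * s)
}

#' Pairwise Pearson correlation matrix of a spectral set
#'
#' Correlations between all spectra, optionally with the grand mean spectrum
#' appended as a final reference row/column (labelled `"mean"`). Uniformly
#' high values (e.g. >= 0.95) indicate good replicate reproducibility.
#'
#' @param set a [SpectrumSet-class] with N >= 2 and no constant spectrum.
#' @param include_mean append the mean spectrum as the final reference
#'   (default `TRUE`).
#' @return Symmetric matrix with unit diagonal, labelled rows/columns;
#'   `(N+1) x (N+1)` when `include_mean`.
#' @export
correlationMatrix <- function(set, include_mean = TRUE) {
  stopifnot(is(set, "SpectrumSet"))
  if (nSpectra(set) < 2L) stop("correlationMatrix needs at least 2 spectra")
  m <- set@intensities
  sds <- apply(m, 1L, sd)
  if (any(sds == 0))
    stop("constant spectrum (undefined correlation): ",
         paste(set@labels[sds == 0], collapse = ", "))
  X <- t(m)
  colnames(X) <- set@labels
  if (include_mean) {
    X <- cbind(X, mean = colMeans(m))
    if (sd(X[, "mean"]) == 0) stop("constant mean spectrum (undefined correlation)")
  }
  cor(X)
}

#' Prominence-based peak identification
#'
#' Local maxima are axis points strictly greater than both immediate
#' neighbours; an interior plateau is reported at its midpoint (left-biased
#' for even plateau lengths). The prominence of a peak is its height minus
#' the larger of its two base levels, where each base level is the minimum of
#' the signal between the peak and the nearest strictly higher point on that
#' side (or the axis boundary when no higher point exists). Prominence
#' measures how far a peak stands out from its surrounding valleys, so it is
#' insensitive to a constant offset and to baseline level.
#'
#' @param spectrum a single-spectrum [SpectrumSet-class], a 1-row matrix, or a
#'   numeric vector of intensities (with `wavenumbers` supplied).
#' @param top_n keep at most this many peaks, by descending prominence
#'   (default all).
#' @param min_prominence optional prominence floor.
#' @param wavenumbers axis, required when `spectrum` is a bare vector.
#' @return data.frame with columns `position`, `height`, `prominence`, sorted
#'   by ascending wavenumber; `attr(, "rank")` gives the descending-prominence
#'   order.
#' @export
findPeaks <- function(spectrum, top_n = Inf, min_prominence = NULL,
                      wavenumbers = NULL) {
  if (is(spectrum, "SpectrumSet")) {
    if (nSpectra(spectrum) != 1L)
      stop("findPeaks works on a single spectrum; subset the set first")
    wavenumbers <- spectrum@wavenumbers
    y <- as.numeric(spectrum@intensities[1L, ])
  } else {
    y <- as.numeric(spectrum)
    if (is.null(wavenumbers)) stop("wavenumbers required for a bare vector")
  }
  M <- length(y)
  if (M < 3L) stop("need at least 3 points to define a local maximum")
  apexes <- integer(0)
  j <- 2L
  while (j <= M - 1L) {
    if (y[j] > y[j - 1L]) {
      # scan forward over any plateau at this level
      jEnd <- j
      while (jEnd < M && y[jEnd + 1L] == y[j]) jEnd <- jEnd + 1L
      if (jEnd < M && y[jEnd + 1L] < y[j]) {
        apexes <- c(apexes, j + (jEnd - j) %/% 2L)   # plateau midpoint
      }
      j <- jEnd + 1L
    } else {
      j <- j + 1L
    }
  }
  if (!length(apexes)) stop("no local maxima found (monotone signal)")
  prom <- vapply(apexes, function(p) {
    h <- y[p]
    left <- y[seq_len(p - 1L)]
    higher <- which(left > h)
    lBase <- min(if (length(higher)) left[(max(higher) + 1L):(p - 1L)] else left)
    right <- y[(p + 1L):M]
    higher <- which(right > h)
    rBase <- min(if (length(higher)) right[seq_len(min(higher) - 1L)] else right)
    h - max(lBase, rBase)
  }, numeric(1))
  keep <- rep(TRUE, length(apexes))
  if (!is.null(min_prominence)) keep <- prom >= min_prominence
  apexes <- apexes[keep]; prom <- prom[keep]
  if (!length(apexes)) {
    out <- data.frame(position = numeric(0), height = numeric(0),
                      prominence = numeric(0))
    attr(out, "rank") <- integer(0)
    return(out)
  }
  ord <- order(-prom, apexes)
  if (is.finite(top_n)) ord <- ord[seq_len(min(top_n, length(ord)))]
  sel <- sort(ord)
  out <- data.frame(position = wavenumbers[apexes[sel]],
                    height = y[apexes[sel]],
                    prominence = prom[sel])
  attr(out, "rank") <- order(-out$prominence, out$position)
  out
}

#' Ward hierarchical clustering of spectra
#'
#' Agglomerative clustering on Euclidean distances between spectra with
#' Ward's linkage, which at each step merges the pair of clusters whose union
#' minimally increases the within-cluster variance. Merge heights are on the
#' standard Ward scale where the height of a merge of two singletons a, b
#' equals `||a - b||`; heights are non-decreasing down the merge table.
#'
#' @param set a [SpectrumSet-class] with N >= 2.
#' @return List of class `"SpectraHCA"`: `merge` (the (N-1) x 2 merge table,
#'   negative entries = leaves), `height`, `order` (leaf order for display),
#'   `labels`, and `hclust` (the underlying [stats::hclust] object, plottable
#'   directly).
#' @export
hcaWard <- function(set) {
  stopifnot(is(set, "SpectrumSet"))
  if (nSpectra(set) < 2L) stop("clustering needs at least 2 spectra")
  d <- dist(set@intensities, method = "euclidean")
  h <- hclust(d, method = "ward.D2")
  h$labels <- set@labels
  structure(list(merge = h$merge, height = h$height, order = h$order,
                 labels = set@labels, hclust = h),
            class = "SpectraHCA")
}

#' @export
print.SpectraHCA <- function(x, ...) {
  cat(sprintf("Ward HCA of %d spectra; merge heights %.4g .. %.4g\n",
              length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

#' Cut a Ward tree into k clusters
#'
#' @param x a `"SpectraHCA"` result.
#' @param k number of clusters.
#' @return Integer cluster assignment named by spectrum label.
#' @export
cutClusters <- function(x, k) {
  stopifnot(inherits(x, "SpectraHCA"))
  stats::cutree(x$hclust, k = k)
}

#' Principal component analysis of spectra
#'
#' Column-centred (no per-wavenumber scaling) singular value decomposition of
#' the N x M intensity matrix. Scores are the projections of the centred
#' spectra onto the loadings; explained-variance ratios are the squared
#' singular values over their total. For a reproducible orientation, each
#' loading is flipped so that its largest-magnitude element is positive.
#'
#' @param set a [SpectrumSet-class] with N >= 2.
#' @param n_components number of components, `1 <= n_components <= min(N-1, M)`.
#' @return List of class `"SpectraPCA"`: `scores` (N x n_components),
#'   `loadings` (n_components x M, orthonormal rows), `explained_variance_ratio`,
#'   `labels`, `groups`.
#' @export
pcaSpectra <- function(set, n_components = 2L) {
  stopifnot(is(set, "SpectrumSet"))
  n <- nSpectra(set); M <- nWavenumbers(set)
  if (n < 2L) stop("PCA needs at least 2 spectra")
  n_components <- as.integer(n_components)
  kmax <- min(n - 1L, M)
  if (n_components < 1L || n_components > kmax)
    stop("n_components must be in [1, ", kmax, "]")
  p <- prcomp(set@intensities, center = TRUE, scale. = FALSE)
  ratios <- p$sdev^2 / sum(p$sdev^2)
  rot <- p$rotation[, seq_len(n_components), drop = FALSE]
  scores <- p$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {          # sign convention
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- set@labels
  structure(list(scores = scores,
                 loadings = t(rot),
                 explained_variance_ratio = ratios[seq_len(n_components)],
                 all_variance_ratios = ratios[seq_len(kmax)],
                 labels = set@labels,
                 groups = spectrumGroups(set)),
            class = "SpectraPCA")
}

#' @export
print.SpectraPCA <- function(x, ...) {
  cat(sprintf("PCA of %d spectra: %d components, variance ratios %s\n",
              length(x$labels), nrow(x$loadings),
              paste(sprintf("%.3f", x$explained_variance_ratio), collapse = ", ")))
  invisible(x)
}
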