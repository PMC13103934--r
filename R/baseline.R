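# Sparse difference matrix of order `order` for the Whittaker penalty.
# Polynomials of degree < order are in the penalty null space (order 2
# reproduces straight lines exactly).
.diffMatrix <- function(M, order) {
  D <- Matrix::Diagonal(M)
  for (k in seq_len(order)) D <- Matrix::diff(D)
  D
}

# Weighted Whittaker smoother solve: (W + lam D'D) z = W y
.whittakerSolve <- function(y, w, lam, DtD) {
  A <- Matrix::Diagonal(x = w) + lam * DtD
  z <- try(Matrix::solve(A, w * y), silent = TRUE)
  if (inherits(z, "try-error"))
    stop("singular Whittaker smoother system (lam = ", lam, ")")
  as.numeric(z)
}

#' airPLS baseline correction
#'
#' Adaptive iteratively reweighted penalized least squares: alternates a
#' weighted Whittaker smoother fit `z = argmin sum_k w_k (y_k - z_k)^2 +
#' lam * sum (diff^order z)^2` with residual-driven reweighting. At
#' iteration `t`, with residual `d = y - z` and `D = sum_{d_k < 0} |d_k|`,
#' weights are 0 where `d_k >= 0`, `exp(t |d_k| / D)` where `d_k < 0`, and
#' both endpoints get `exp(t max_{d_k<0} |d_k| / D)` to pin the ends of the
#' baseline. Iteration stops when the negative-residual mass `D` falls below
#' `tol` times the total absolute intensity, or after `max_iter` smoother
#' solves.
#'
#' @param set a [SpectrumSet-class].
#' @param lam smoothness penalty weight (> 0); larger = stiffer baseline.
#' @param order difference order of the roughness penalty (1 or 2); order 2
#'   leaves straight-line trends unpenalized and reproduces them exactly.
#' @param max_iter maximum smoother solves per spectrum (>= 1).
#' @param tol convergence tolerance as a fraction of total |y| mass, in (0, 1).
#' @return A [BaselineResult-class].
#' @export
baselineAirPLS <- function(set, lam = 100, order = 1L, max_iter = 15L,
                           tol = 0.001) {
  stopifnot(is(set, "SpectrumSet"))
  if (!is.numeric(lam) || lam <= 0) stop("lam must be > 0")
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (!is.numeric(tol) || tol <= 0 || tol >= 1) stop("tol must be in (0, 1)")
  m <- set@intensities
  M <- ncol(m)
  DtD <- Matrix::crossprod(.diffMatrix(M, order))
  baselines <- matrix(0, nrow(m), M)
  iters <- integer(nrow(m))
  conv <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    y <- m[i, ]
    totalMass <- sum(abs(y))
    if (totalMass == 0) { iters[i] <- 0L; conv[i] <- TRUE; next }
    w <- rep(1, M)
    z <- y
    for (t in seq_len(max_iter)) {
      z <- .whittakerSolve(y, w, lam, DtD)
      d <- y - z
      neg <- d < 0
      Dmass <- sum(abs(d[neg]))
      iters[i] <- t
      if (Dmass < tol * totalMass) { conv[i] <- TRUE; break }
      w[!neg] <- 0
      w[neg] <- exp(t * abs(d[neg]) / Dmass)
      wEnd <- exp(t * max(abs(d[neg])) / Dmass)
      w[1L] <- wEnd
      w[M] <- wEnd
    }
    baselines[i, ] <- z
  }
  new("BaselineResult", baselines = baselines, corrected = m - baselines,
      iterationsUsed = iters, converged = conv, method = "airpls",
      labels = set@labels)
}

#' Iterative minimum-polynomial baseline correction
#'
#' Fits a degree-`order` polynomial to the working signal by least squares,
#' replaces the working signal with the pointwise minimum of itself and the
#' fit, and repeats until the fit changes by less than `tol` (relative L2) or
#' `max_iter` iterations. Peaks are progressively clipped away so the final
#' fit tracks the background.
#'
#' @param set a [SpectrumSet-class].
#' @param order polynomial degree (>= 0, < M).
#' @param max_iter maximum iterations (>= 1); `max_iter = 1` is a plain
#'   least-squares polynomial fit.
#' @param tol relative-change stopping tolerance.
#' @return A [BaselineResult-class].
#' @export
baselinePolynomial <- function(set, order = 3L, max_iter = 100L, tol = 1e-3) {
  stopifnot(is(set, "SpectrumSet"))
  order <- as.integer(order); max_iter <- as.integer(max_iter)
  if (order < 0L) stop("order must be >= 0")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  M <- nWavenumbers(set)
  if (order >= M) stop("order must be < M = ", M, " (underdetermined fit)")
  wn <- set@wavenumbers
  x <- (wn - mean(wn)) / (diff(range(wn)) / 2)   # scaled for conditioning
  X <- outer(x, 0:order, `^`)
  m <- set@intensities
  baselines <- matrix(0, nrow(m), M)
  iters <- integer(nrow(m))
  conv <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    work <- m[i, ]
    fitOld <- NULL
    for (t in seq_len(max_iter)) {
      fit <- drop(X %*% lm.fit(X, work)$coefficients)
      iters[i] <- t
      if (!is.null(fitOld)) {
        denom <- sqrt(sum(fitOld^2))
        if (sqrt(sum((fit - fitOld)^2)) <= tol * (if (denom > 0) denom else 1)) {
          conv[i] <- TRUE
          break
        }
      }
      fitOld <- fit
      work <- pmin(work, fit)
    }
    baselines[i, ] <- fit
  }
  new("BaselineResult", baselines = baselines,
      corrected = m - baselines, iterationsUsed = iters, converged = conv,
      method = "polynomial", labels = set@labels)
}

# pseudo-Voigt profile, apex amplitude A at centre c, width w
.pseudoVoigt <- function(x, A, c, w, eta) {
  eta <- min(max(eta, 0), 1)
  g <- exp(-(x - c)^2 / (2 * w^2))
  l <- w^2 / ((x - c)^2 + w^2)
  A * ((1 - eta) * g + eta * l)
}

#' Gaussian-Lorentzian broad-background baseline correction
#'
#' Models the background as a constant offset plus `n_components` broad
#' pseudo-Voigt (Gaussian-Lorentzian mixture) profiles whose widths are
#' constrained to be at least `min_width`, fitted by bounded nonlinear least
#' squares. With `min_width` well above vibrational peak widths the fit can
#' only follow the slowly varying background (e.g. fluorescence humps), so
#' narrow Raman peaks survive the correction.
#'
#' @param set a [SpectrumSet-class].
#' @param n_components number of broad components (>= 1).
#' @param min_width lower bound on component width in cm^-1 (default 200,
#'   well above typical vibrational peak widths of 5-30 cm^-1).
#' @return A [BaselineResult-class]; per-spectrum non-convergence is reported
#'   via the `converged` flag with the last iterate returned.
#' @export
baselineGLFit <- function(set, n_components = 1L, min_width = 200) {
  stopifnot(is(set, "SpectrumSet"))
  n_components <- as.integer(n_components)
  if (n_components < 1L) stop("n_components must be >= 1")
  if (!is.numeric(min_width) || min_width <= 0) stop("min_width must be > 0")
  wn <- set@wavenumbers
  M <- length(wn)
  m <- set@intensities
  span <- diff(range(wn))
  baselines <- matrix(0, nrow(m), M)
  iters <- integer(nrow(m))
  conv <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    y <- m[i, ]
    if (all(y == 0)) { iters[i] <- 0L; conv[i] <- TRUE; next }
    # start: components spread across the axis, amplitudes at the local level
    centres0 <- seq(min(wn) + span / (2 * n_components),
                    max(wn) - span / (2 * n_components),
                    length.out = n_components)
    amp0 <- pmax(stats::quantile(y, 0.5) - min(y), diff(range(y)) / 4)
    start <- list(off = min(y))
    lower <- c(off = -Inf)
    upper <- c(off = Inf)
    for (k in seq_len(n_components)) {
      start[[paste0("A", k)]] <- as.numeric(amp0)
      start[[paste0("c", k)]] <- centres0[k]
      start[[paste0("w", k)]] <- max(min_width, span / 3)
      start[[paste0("e", k)]] <- 0.5
      lower <- c(lower, 0, min(wn) - span, min_width, 0)
      upper <- c(upper, Inf, max(wn) + span, Inf, 1)
    }
    model <- function(p) {
      b <- rep(p[["off"]], M)
      for (k in seq_len(n_components)) {
        b <- b + .pseudoVoigt(wn, p[[paste0("A", k)]], p[[paste0("c", k)]],
                              p[[paste0("w", k)]], p[[paste0("e", k)]])
      }
      b
    }
    fit <- try(minpack.lm::nls.lm(
      par = start,
      fn = function(p) y - model(p),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) {
      baselines[i, ] <- rep(min(y), M)
      iters[i] <- 0L
      conv[i] <- FALSE
    } else {
      baselines[i, ] <- model(fit$par)
      iters[i] <- fit$niter
      conv[i] <- fit$info %in% 1:4
    }
  }
  new("BaselineResult", baselines = baselines, corrected = m - baselines,
      iterationsUsed = iters, converged = conv, method = "glfit",
      labels = set@labels)
}
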