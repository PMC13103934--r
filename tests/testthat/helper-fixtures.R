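# Shared fixtures and independent oracles, all built in code.

# small random SpectrumSet (positive, non-constant spectra)
randomSet <- function(seed, n = 4L, m = 30L, groups = NULL) {
  set.seed(seed)
  SpectrumSet(sort(runif(m, 400, 1800)),
              matrix(runif(n * m, 1, 100), n, m),
              labels = paste0("r", seq_len(n)),
              groups = groups)
}

# naive double-loop implementation of the average spectral variation:
# mean over wavenumbers of the (N-1)-denominator sample SD
naiveSigmaAvg <- function(m) {
  m <- unname(m)
  N <- nrow(m); M <- ncol(m)
  tot <- 0
  for (k in seq_len(M)) {
    mu <- sum(m[, k]) / N
    ss <- 0
    for (i in seq_len(N)) ss <- ss + (m[i, k] - mu)^2
    tot <- tot + sqrt(ss / (N - 1))
  }
  tot / M
}

# explicit least-squares Savitzky-Golay interior kernel: coefficients of the
# fitted polynomial value at the window centre
naiveSgKernel <- function(window, polyorder) {
  h <- (window - 1L) %/% 2L
  A <- outer(-h:h, 0:polyorder, `^`)
  drop((solve(t(A) %*% A) %*% t(A))[1L, ])   # value at offset 0 = coef of x^0
}

# the standard six-stage preprocessing chain used throughout
fig4Steps <- function() list(
  list(op = "interpolate_to_grid"),
  list(op = "crop", lo = 600, hi = 1600),
  list(op = "despike", regions = list(c(600, 750), c(1050, 1150)),
       threshold = 300, window = 11L),
  list(op = "smooth_savgol", window = 15L, polyorder = 2L),
  list(op = "baseline_airpls", lam = 100, order = 1L, max_iter = 15L,
       tol = 0.001),
  list(op = "normalize", mode = "area"))

# trapezoid area (independent of the package's helper)
trapArea <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# default processed two-class fixture for multivariate analytics
twoClassFixture <- function() {
  sp <- twoClassSpecs()
  tc <- generateTwoClass(sp$a, sp$b)
  list(raw = tc$set, norm = normalizeSpectra(tc$set, "area"),
       truth = tc$truth)
}

meanSpectrum <- function(set) {
  SpectrumSet(wavenumbers(set), colMeans(intensities(set)), labels = "mean")
}
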