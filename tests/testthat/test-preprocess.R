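test_that("interpolation to the integer grid matches hand linear interpolation", {
  # already-integer axis: identity
  s <- SpectrumSet(600:650, rbind(sin(600:650), cos(600:650)))
  out <- interpolateToGrid(s)
  expect_identical(wavenumbers(out), as.numeric(600:650))
  expect_equal(unname(intensities(out)), unname(intensities(s)))
  # hand bracket: value at 101 between (100.4, 0) and (101.6, 12)
  s2 <- SpectrumSet(c(100.4, 101.6, 103), rbind(c(0, 12, 0)))
  out2 <- interpolateToGrid(s2)
  expect_equal(wavenumbers(out2), c(101, 102, 103))
  expect_equal(unname(intensities(out2)[1, 1]),
               (101 - 100.4) / (101.6 - 100.4) * 12)
  # piecewise-linear signal: interpolants come from the bracketing segment
  x <- c(99.9, 100.1, 100.9, 101.1)
  y <- c(1, 3, 7, 5)
  out3 <- interpolateToGrid(SpectrumSet(x, rbind(y)))
  expect_equal(wavenumbers(out3), c(100, 101))
  expect_equal(unname(intensities(out3)[1, ]),
               c(1 + (100 - 99.9) / (100.1 - 99.9) * (3 - 1),
                 7 + (101 - 100.9) / (101.1 - 100.9) * (5 - 7)),
               tolerance = 1e-12)
  # a range spanning < 2 integer wavenumbers errors
  expect_error(interpolateToGrid(SpectrumSet(c(100.4, 101.6), rbind(c(0, 12)))),
               "fewer than 2 integer")
})

test_that("cropping restricts the axis and validates its bounds", {
  s <- generateSpectra(bsaLikeSpec())$set
  out <- cropSpectra(s, 600, 1600)
  expect_true(all(wavenumbers(out) >= 600 & wavenumbers(out) <= 1600))
  idx <- which(wavenumbers(s) >= 600 & wavenumbers(s) <= 1600)
  expect_identical(unname(intensities(out)), unname(intensities(s)[, idx]))
  # full-range crop is the identity
  full <- cropSpectra(s, min(wavenumbers(s)), max(wavenumbers(s)))
  expect_identical(intensities(full), intensities(s))
  expect_error(cropSpectra(s, 1600, 600), "lo < hi")
  expect_error(cropSpectra(s, 5000, 5001), "fewer than 2")
})

test_that("despiking removes injected spikes and touches nothing else", {
  wn <- 600:1600
  smooth <- 200 + 100 * sin(wn / 50)
  spiked <- smooth
  spiked[wn == 700] <- spiked[wn == 700] + 500
  spiked[wn == 1100] <- spiked[wn == 1100] + 800
  s <- SpectrumSet(wn, rbind(spiked))
  out <- despike(s, regions = list(c(600, 750), c(1050, 1150)),
                 threshold = 300, window = 11L)
  y <- intensities(out)[1, ]
  inRegion <- (wn >= 600 & wn <= 750) | (wn >= 1050 & wn <= 1150)
  # spikes repaired to near the smooth truth
  expect_lt(max(abs(y[inRegion] - smooth[inRegion])), 1)
  # outside the regions: bit-identical
  expect_identical(y[!inRegion], spiked[!inRegion])
  # nothing above median + threshold: identity everywhere
  clean <- despike(SpectrumSet(wn, rbind(smooth)), threshold = 300,
                   window = 11L)
  expect_identical(intensities(clean)[1, ], smooth)
  expect_error(despike(s, window = 10L), "odd")
  expect_error(despike(s, regions = list(c(2000, 2100))), "no axis points")
  expect_error(despike(s, threshold = -1), "threshold")
})

test_that("Savitzky-Golay reproduces polynomials and matches the explicit kernel", {
  wn <- seq_len(101)
  quad <- 2 + 0.3 * wn - 0.01 * wn^2
  out <- smoothSavgol(SpectrumSet(wn, rbind(quad)), 15L, 2L)
  expect_lt(max(abs(intensities(out)[1, ] - quad)), 1e-10)
  # kernel normalization: constants preserved exactly
  k <- naiveSgKernel(15L, 2L)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  # interior agrees with the explicit least-squares kernel on noise
  set.seed(9)
  y <- rnorm(101)
  sm <- intensities(smoothSavgol(SpectrumSet(wn, rbind(y)), 15L, 2L))[1, ]
  ref <- as.numeric(stats::filter(y, rev(k), sides = 2))
  expect_equal(sm[8:94], ref[8:94], tolerance = 1e-12)
  expect_error(smoothSavgol(SpectrumSet(wn, rbind(y)), 15L, 15L), "polyorder")
})

test_that("Savitzky-Golay noise variance shrinks by the sum of squared weights", {
  k <- naiveSgKernel(15L, 2L)
  n <- 1e5
  set.seed(17)
  y <- rnorm(n)
  sm <- intensities(smoothSavgol(SpectrumSet(seq_len(n), rbind(y)), 15L, 2L))[1, ]
  emp <- var(sm[8:(n - 7)])
  expect_equal(emp, sum(k^2), tolerance = 0.05)
})

test_that("Savitzky-Golay interior matches signal::sgolayfilt", {
  skip_if_not_installed("signal")
  set.seed(4)
  y <- cumsum(rnorm(200))
  mine <- intensities(smoothSavgol(SpectrumSet(1:200, rbind(y)), 11L, 3L))[1, ]
  ref <- signal::sgolayfilt(y, p = 3, n = 11)
  expect_equal(mine[6:195], ref[6:195], tolerance = 1e-9)
})

test_that("Fourier filtering passes low frequencies and rejects high ones", {
  M <- 512L
  wn <- seq_len(M)
  set.seed(2)
  y <- rnorm(M)
  allPass <- intensities(smoothFourier(SpectrumSet(wn, rbind(y)), 1))[1, ]
  expect_equal(allPass, y, tolerance = 1e-10)
  # mirror-symmetric cosines map to single DFT bins of the padded signal:
  # cos(pi*k*(t+1/2)/M), even k, is bin k/2 of length 2M
  lo <- cos(pi * 10 * (wn - 0.5) / M)     # bin 5; cutoff 0.2 keeps bins <= 102
  kept <- intensities(smoothFourier(SpectrumSet(wn, rbind(lo)), 0.2))[1, ]
  expect_equal(kept, lo, tolerance = 1e-10)
  # high-frequency component above the cutoff loses > 99% of its energy
  hi <- cos(pi * 400 * (wn - 0.5) / M)    # bin 200 > 102: rejected
  mix <- lo + hi
  filt <- intensities(smoothFourier(SpectrumSet(wn, rbind(mix)), 0.2))[1, ]
  residHi <- filt - lo
  expect_lt(sum(residHi^2) / sum(hi^2), 0.01)
  expect_error(smoothFourier(SpectrumSet(wn, rbind(y)), 0), "cutoff")
  expect_error(smoothFourier(SpectrumSet(wn, rbind(y)), 1.5), "cutoff")
})

test_that("airPLS conserves signal and honors its iteration contract", {
  g <- generateSpectra(bsaLikeSpec())
  s <- cropSpectra(g$set, 600, 1600)
  r <- baselineAirPLS(s, 100, 1L, 15L, 0.001)
  expect_equal(unname(baselines(r) + correctedIntensities(r)),
               unname(intensities(s)), tolerance = 1e-12)
  expect_true(all(r@iterationsUsed <= 15L))
  one <- baselineAirPLS(s, 100, 1L, 1L, 0.001)
  expect_true(all(one@iterationsUsed == 1L))
})

test_that("the order-2 Whittaker penalty reproduces straight lines exactly", {
  wn <- 600:1600
  line <- 100 + 0.5 * wn
  r <- baselineAirPLS(SpectrumSet(wn, rbind(line)), 100, 2L, 15L, 0.001)
  expect_lt(max(abs(baselines(r)[1, ] - line)), 1e-6)
  expect_lt(max(abs(correctedIntensities(r)[1, ])), 1e-6)
  # order 1 (constant null space) still tracks a line closely away from edges
  r1 <- baselineAirPLS(SpectrumSet(wn, rbind(line)), 100, 1L, 15L, 0.001)
  expect_lt(sqrt(mean((baselines(r1)[1, ] - line)^2)),
            0.05 * diff(range(line)))
})

test_that("airPLS recovers a linear baseline under Lorentzian peaks", {
  wn <- 600:1600
  lor <- function(c, A, w) A * w^2 / ((wn - c)^2 + w^2)
  base <- 100 + 0.5 * wn
  y <- base + lor(800, 500, 10) + lor(1100, 700, 12) + lor(1400, 400, 9)
  r <- baselineAirPLS(SpectrumSet(wn, rbind(y)), 100, 1L, 15L, 0.001)
  rmse <- sqrt(mean((baselines(r)[1, ] - base)^2))
  expect_lt(rmse, 0.05 * diff(range(base)))
})

test_that("airPLS negative-residual mass is non-increasing until convergence", {
  wn <- 600:1600
  base <- 100 + 0.5 * wn
  y <- base + 500 * 10^2 / ((wn - 900)^2 + 10^2)
  s <- SpectrumSet(wn, rbind(y))
  dmass <- function(max_iter) {
    r <- baselineAirPLS(s, 100, 1L, max_iter, 1e-12)  # tiny tol: never stops early
    d <- intensities(s)[1, ] - baselines(r)[1, ]
    sum(abs(d[d < 0]))
  }
  masses <- vapply(1:8, dmass, numeric(1))
  expect_true(all(diff(masses) <= 1e-8 * masses[-length(masses)] + 1e-8))
})

test_that("iterative polynomial baseline clips peaks down to the background", {
  wn <- seq(600, 1600, by = 2)
  # exact polynomial input: baseline == input after one fit
  py <- 5 + 0.02 * wn + 1e-5 * wn^2
  r0 <- baselinePolynomial(SpectrumSet(wn, rbind(py)), order = 2L)
  expect_equal(baselines(r0)[1, ], py, tolerance = 1e-8)
  expect_lt(max(abs(correctedIntensities(r0)[1, ])), 1e-6)
  # quadratic background + peaks: peak-free regions corrected to ~0
  bg <- 400 - 0.3 * wn + 2e-4 * wn^2
  peaks <- 600 * exp(-(wn - 900)^2 / (2 * 5^2)) +
    450 * exp(-(wn - 1300)^2 / (2 * 6^2))
  r <- baselinePolynomial(SpectrumSet(wn, rbind(bg + peaks)), order = 2L,
                          max_iter = 200L, tol = 1e-8)
  free <- abs(wn - 900) > 60 & abs(wn - 1300) > 60
  expect_lt(max(abs(correctedIntensities(r)[1, free])), 0.01 * 600)
  # max_iter = 1 is a plain least-squares fit
  plain <- baselinePolynomial(SpectrumSet(wn, rbind(bg + peaks)), order = 2L,
                              max_iter = 1L)
  X <- outer((wn - mean(wn)) / (diff(range(wn)) / 2), 0:2, `^`)
  ls <- drop(X %*% qr.solve(X, bg + peaks))
  expect_equal(baselines(plain)[1, ], ls, tolerance = 1e-8)
  expect_error(baselinePolynomial(SpectrumSet(400:402, rbind(1:3)), order = 5L),
               "underdetermined")
})

test_that("Gaussian-Lorentzian background fitting spares narrow peaks", {
  wn <- 400:1800
  bg <- 2000 * exp(-(wn - 1000)^2 / (2 * 400^2))
  r1 <- baselineGLFit(SpectrumSet(wn, rbind(bg)), 1L, 200)
  expect_lt(max(abs(correctedIntensities(r1)[1, ])), 0.01 * 2000)
  flat <- baselineGLFit(SpectrumSet(wn, rbind(rep(0, length(wn)))), 1L, 200)
  expect_equal(baselines(flat)[1, ], rep(0, length(wn)))
  expect_true(all(flat@converged))
  pk <- 500 * exp(-(wn - 700)^2 / (2 * 10^2)) +
    700 * exp(-(wn - 1300)^2 / (2 * 12^2))
  r2 <- baselineGLFit(SpectrumSet(wn, rbind(bg + pk)), 1L, 200)
  co <- correctedIntensities(r2)[1, ]
  expect_equal(co[wn == 700], 500, tolerance = 0.1)
  expect_equal(co[wn == 1300], 700, tolerance = 0.1)
})

test_that("normalization modes scale as documented and are idempotent", {
  s <- generateSpectra(bsaLikeSpec())$set
  wn <- wavenumbers(s)
  a <- normalizeSpectra(s, "area")
  areas <- apply(intensities(a), 1L, function(y) trapArea(wn, y))
  expect_true(all(abs(areas - 1) < 1e-9))
  a2 <- normalizeSpectra(a, "area")
  expect_equal(intensities(a2), intensities(a), tolerance = 1e-12)
  # peak mode: spectrum with max 5 becomes input/5
  y <- c(1, 5, 2, 0.5, 3)
  p <- normalizeSpectra(SpectrumSet(1:5, rbind(y)), "peak")
  expect_equal(intensities(p)[1, ], y / 5)
  # peak mode at a stated position scales that sample to 1
  p2 <- normalizeSpectra(SpectrumSet(1:5, rbind(y)), "peak", peak_position = 3)
  expect_equal(unname(intensities(p2)[1, 3]), 1)
  mm <- normalizeSpectra(s, "minmax")
  expect_true(all(abs(apply(intensities(mm), 1, min)) < 1e-12))
  expect_true(all(abs(apply(intensities(mm), 1, max) - 1) < 1e-12))
  expect_equal(intensities(normalizeSpectra(mm, "minmax")), intensities(mm),
               tolerance = 1e-12)
  const <- SpectrumSet(1:4, rbind(first = c(1, 2, 1, 3), flat = rep(2, 4)))
  expect_error(normalizeSpectra(const, "minmax"), "flat")
})

test_that("outlier screening matches hand-computed scores", {
  y <- sin(seq(0, 6, length.out = 80)) * 10 + 20
  s <- SpectrumSet(seq_len(80), rbind(y, y, y, y, y, 10 * y),
                   labels = paste0("r", 1:6))
  rep <- detectOutliers(s, corr_thresh = 0.9, sd_thresh = 3, dist_thresh = 3,
                        combine = "any")
  # scaled spectrum: consensus is y itself -> r = 1 (criterion a silent);
  # deviation = 9*mean|y| / (sd(c(1,1,1,1,1,10))*mean|y|) = 9/sqrt(13.5);
  # distance ratio = 9||y|| / (1.8||y||) = 5 -> criterion c flags it
  expect_equal(rep$correlation[6], 1, tolerance = 1e-12)
  expect_equal(rep$deviation[6], 9 / sqrt(13.5), tolerance = 1e-9)
  expect_equal(rep$distance_ratio[6], 5, tolerance = 1e-9)
  expect_identical(which(rep$outlier), 6L)
  expect_false(rep$flag_correlation[6])
  expect_true(rep$flag_distance[6])
  # five identical non-constant spectra: nothing flagged
  clean <- detectOutliers(SpectrumSet(seq_len(80), rbind(y, y, y, y, y)))
  expect_false(any(clean$outlier))
  # anti-correlated spectrum trips the correlation criterion at r = -1
  neg <- SpectrumSet(seq_len(80), rbind(y, y, y, y, 2 * mean(y) - y))
  r3 <- detectOutliers(neg, corr_thresh = 0, sd_thresh = 1e6, dist_thresh = 1e6)
  expect_equal(r3$correlation[5], -1, tolerance = 1e-12)
  expect_identical(which(r3$outlier), 5L)
  expect_error(detectOutliers(SpectrumSet(1:4, rbind(1:4, 2:5))), "at least 3")
})

test_that("preprocessing is pure and label/group-preserving", {
  s <- randomSet(11, n = 3L, m = 120L, groups = c("a", "a", "b"))
  before <- intensities(s)
  for (f in list(function(x) interpolateToGrid(x),
                 function(x) cropSpectra(x, 600, 1500),
                 function(x) despike(x, threshold = 50, window = 5L),
                 function(x) smoothSavgol(x, 7L, 2L),
                 function(x) smoothFourier(x, 0.5),
                 function(x) normalizeSpectra(x, "area"),
                 function(x) correctedSet(x, baselineAirPLS(x)))) {
    out <- f(s)
    expect_identical(intensities(s), before)       # input untouched
    expect_identical(spectrumNames(out), spectrumNames(s))
    expect_identical(spectrumGroups(out), spectrumGroups(s))
  }
})
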