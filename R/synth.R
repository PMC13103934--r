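#' Describe a synthetic Raman/SERS replicate set
#'
#' A `SyntheticSpec` fixes everything the generator needs: the axis, a peak
#' table, a polynomial-plus-broad-hump baseline, noise and cosmic-ray spikes,
#' the replicate count, replicate-to-replicate jitter, and the seed. The seed
#' fixes all randomness; replicate `i` draws from its own stream derived from
#' `(seed, i)`, so changing `n_replicates` never reshuffles earlier
#' replicates.
#'
#' Peak profiles (amplitude = apex height): Gaussian
#' `A exp(-(x-c)^2 / (2 w^2))` and Lorentzian `A w^2 / ((x-c)^2 + w^2)`.
#' Cosmic-ray spikes are single-sample positive excursions, matching typical
#' cosmic-ray morphology and the despiker's single-point replacement model.
#' Replicate variation = one global peak-amplitude factor plus an independent
#' baseline scale factor per replicate, which reproduces the
#' baseline-dominated variability of raw replicate sets.
#'
#' @param axis_min,axis_max,axis_step axis range and spacing in cm^-1.
#' @param peaks data.frame with columns `center`, `amplitude`, `width`
#'   (cm^-1) and `shape` (`"gaussian"` or `"lorentzian"`).
#' @param baseline_coef polynomial baseline coefficients, ascending powers of
#'   the wavenumber.
#' @param humps optional data.frame of broad background components (`center`,
#'   `amplitude`, `width`), widths >= 200 cm^-1 (fluorescence-like).
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param spikes optional data.frame of cosmic-ray spikes (`position`,
#'   `amplitude`); amplitudes must exceed `noise_sd`.
#' @param spike_count,spike_amp alternative to `spikes`: draw this many
#'   spikes per replicate, amplitudes uniform in `spike_amp = c(lo, hi)`.
#' @param n_replicates number of replicate spectra N.
#' @param amp_jitter per-replicate global peak-amplitude jitter fraction.
#' @param baseline_jitter per-replicate baseline scale jitter fraction.
#' @param seed integer master seed.
#' @return A validated list of class `"SyntheticSpec"`.
#' @seealso [generateSpectra()], [generateTwoClass()], [bsaLikeSpec()]
#' @export
syntheticSpec <- function(axis_min, axis_max, axis_step = 1,
                          peaks,
                          baseline_coef = 0,
                          humps = NULL,
                          noise_sd = 0,
                          spikes = NULL,
                          spike_count = 0L, spike_amp = c(0, 0),
                          n_replicates = 1L,
                          amp_jitter = 0,
                          baseline_jitter = 0,
                          seed = 1L) {
  peaks <- as.data.frame(peaks)
  need <- c("center", "amplitude", "width", "shape")
  if (!all(need %in% names(peaks)))
    stop("peaks needs columns ", paste(need, collapse = ", "))
  if (any(peaks$width <= 0)) stop("peak widths must be > 0")
  if (any(peaks$amplitude < 0)) stop("peak amplitudes must be >= 0")
  if (!all(peaks$shape %in% c("gaussian", "lorentzian")))
    stop("peak shape must be 'gaussian' or 'lorentzian'")
  if (!is.null(humps)) {
    humps <- as.data.frame(humps)
    if (!all(c("center", "amplitude", "width") %in% names(humps)))
      stop("humps needs columns center, amplitude, width")
    if (any(humps$width <= 0)) stop("hump widths must be > 0")
  }
  if (!is.null(spikes)) {
    spikes <- as.data.frame(spikes)
    if (!all(c("position", "amplitude") %in% names(spikes)))
      stop("spikes needs columns position, amplitude")
    if (noise_sd > 0 && any(spikes$amplitude <= noise_sd))
      stop("spike amplitudes must exceed the noise SD")
  }
  if (axis_min >= axis_max || axis_step <= 0) stop("invalid axis")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  structure(list(axis_min = axis_min, axis_max = axis_max,
                 axis_step = axis_step, peaks = peaks,
                 baseline_coef = as.numeric(baseline_coef), humps = humps,
                 noise_sd = noise_sd, spikes = spikes,
                 spike_count = as.integer(spike_count),
                 spike_amp = as.numeric(spike_amp),
                 n_replicates = as.integer(n_replicates),
                 amp_jitter = amp_jitter,
                 baseline_jitter = baseline_jitter,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

.peakProfile <- function(x, center, amplitude, width, shape) {
  if (shape == "gaussian") amplitude * exp(-(x - center)^2 / (2 * width^2))
  else amplitude * width^2 / ((x - center)^2 + width^2)
}

# one RNG stream per (seed, replicate); kept below 2^31
.replicateSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 11939 * as.numeric(i)) %% 2147483647)
}

#' Generate a synthetic replicate set with stored ground truth
#'
#' Each replicate is `baseline + peaks + noise + spikes`: the shared
#' polynomial/hump baseline scaled by a per-replicate factor, the peak table
#' with a per-replicate global amplitude factor, i.i.d. Gaussian noise, and
#' single-sample cosmic-ray spikes. The returned truth record holds, per
#' replicate, the noise-free baseline, the noise-free peaks-only signal, the
#' noise matrix and the spike table, so `baseline + peaks + noise + spikes`
#' reconstructs the output exactly.
#'
#' @param spec a [syntheticSpec()].
#' @return List with `set` (a [SpectrumSet-class], labels `rep1..repN`) and
#'   `truth` (list: `baselines`, `peaks` — N x M matrices, `noise` — N x M,
#'   `spikes` — per-replicate data.frames with `index`, `position`,
#'   `amplitude`, plus the per-replicate `amp_factor` and `baseline_factor`).
#' @export
generateSpectra <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  wn <- seq(spec$axis_min, spec$axis_max, by = spec$axis_step)
  M <- length(wn)
  if (M < 2L) stop("axis resolves to fewer than 2 points")
  N <- spec$n_replicates
  baseShape <- rep(0, M)
  for (p in seq_along(spec$baseline_coef))
    baseShape <- baseShape + spec$baseline_coef[p] * wn^(p - 1L)
  if (!is.null(spec$humps)) {
    for (r in seq_len(nrow(spec$humps)))
      baseShape <- baseShape + .peakProfile(wn, spec$humps$center[r],
                                            spec$humps$amplitude[r],
                                            spec$humps$width[r], "gaussian")
  }
  peakShape <- rep(0, M)
  for (r in seq_len(nrow(spec$peaks)))
    peakShape <- peakShape + .peakProfile(wn, spec$peaks$center[r],
                                          spec$peaks$amplitude[r],
                                          spec$peaks$width[r],
                                          spec$peaks$shape[r])
  baselines <- peaksM <- noiseM <- matrix(0, N, M)
  spikeList <- vector("list", N)
  ampF <- baseF <- numeric(N)
  intens <- matrix(0, N, M)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  for (i in seq_len(N)) {
    set.seed(.replicateSeed(spec$seed, i))
    ampF[i]  <- max(0.05, 1 + spec$amp_jitter * rnorm(1))
    baseF[i] <- max(0.05, 1 + spec$baseline_jitter * rnorm(1))
    noise <- if (spec$noise_sd > 0) rnorm(M, 0, spec$noise_sd) else rep(0, M)
    if (!is.null(spec$spikes)) {
      sp <- spec$spikes
      idx <- vapply(sp$position, function(p) which.min(abs(wn - p)), 1L)
      spikeList[[i]] <- data.frame(index = idx, position = wn[idx],
                                   amplitude = sp$amplitude)
    } else if (spec$spike_count > 0L) {
      idx <- sample.int(M, spec$spike_count)
      spikeList[[i]] <- data.frame(
        index = idx, position = wn[idx],
        amplitude = runif(spec$spike_count, spec$spike_amp[1L],
                          spec$spike_amp[2L]))
    } else {
      spikeList[[i]] <- data.frame(index = integer(0), position = numeric(0),
                                   amplitude = numeric(0))
    }
    baselines[i, ] <- baseF[i] * baseShape
    peaksM[i, ]    <- ampF[i] * peakShape
    noiseM[i, ]    <- noise
    y <- baselines[i, ] + peaksM[i, ] + noise
    if (nrow(spikeList[[i]])) {
      y[spikeList[[i]]$index] <- y[spikeList[[i]]$index] +
        spikeList[[i]]$amplitude
    }
    intens[i, ] <- y
  }
  set <- SpectrumSet(wn, intens, labels = paste0("rep", seq_len(N)))
  list(set = set,
       truth = list(baselines = baselines, peaks = peaksM, noise = noiseM,
                    spikes = spikeList, amp_factor = ampF,
                    baseline_factor = baseF))
}

#' Generate a two-analyte class-structured set
#'
#' Generates both specs on their (identical) axes and merges them into one
#' group-labelled set, emulating a two-analyte experiment whose classes are
#' distinguished by unmatched peak positions. Peak tables must be disjoint:
#' an error if any cross-class centre pair is closer than the wider of the
#' two peaks, a warning when closer than 3x that width.
#'
#' @param spec_a,spec_b [syntheticSpec()] objects on the same axis.
#' @param group_a,group_b class labels (defaults `"A"`, `"B"`).
#' @return List with `set` (merged, group-labelled [SpectrumSet-class]) and
#'   `truth` (per-class truth records, named by group).
#' @export
generateTwoClass <- function(spec_a, spec_b, group_a = "A", group_b = "B") {
  stopifnot(inherits(spec_a, "SyntheticSpec"), inherits(spec_b, "SyntheticSpec"))
  if (spec_a$axis_min != spec_b$axis_min || spec_a$axis_max != spec_b$axis_max ||
      spec_a$axis_step != spec_b$axis_step)
    stop("the two specs must share one axis")
  sep <- outer(spec_a$peaks$center, spec_b$peaks$center,
               function(a, b) abs(a - b))
  wmax <- outer(spec_a$peaks$width, spec_b$peaks$width, pmax)
  if (any(sep < wmax))
    stop("overlapping peak tables: cross-class centres closer than one width")
  if (any(sep < 3 * wmax))
    warning("cross-class peak centres closer than 3x peak width; classes may overlap")
  ga <- generateSpectra(spec_a)
  gb <- generateSpectra(spec_b)
  a <- ga$set; b <- gb$set
  a@labels <- paste0(group_a, "_", a@labels)
  a@groups <- rep(group_a, nSpectra(a))
  b@labels <- paste0(group_b, "_", b@labels)
  b@groups <- rep(group_b, nSpectra(b))
  truth <- list(ga$truth, gb$truth)
  names(truth) <- c(group_a, group_b)
  list(set = mergeSpectra(a, b), truth = truth)
}

#' Built-in fixture: a BSA-like protein replicate set
#'
#' Five replicates over 400-1800 cm^-1 with vibrational peaks at 702, 877,
#' 1087, 1308 and 1443 cm^-1 (amide/CH-deformation region of a serum
#' albumin), a sloped baseline under a broad fluorescence hump, additive
#' noise, and cosmic-ray spikes at 700 and 1100 cm^-1 — the raw-data
#' morphology the preprocessing chain is designed for.
#'
#' @param seed master seed.
#' @param n_replicates replicate count (default 5).
#' @param noise_sd noise SD (default 20, raw counts).
#' @return A [syntheticSpec()].
#' @export
bsaLikeSpec <- function(seed = 42L, n_replicates = 5L, noise_sd = 20) {
  syntheticSpec(
    axis_min = 400, axis_max = 1800, axis_step = 1,
    peaks = data.frame(
      center    = c(702, 877, 1087, 1308, 1443),
      amplitude = c(600, 420, 800, 480, 650),
      width     = c(10, 12, 9, 14, 11),
      shape     = c("lorentzian", "gaussian", "lorentzian", "gaussian",
                    "lorentzian")),
    baseline_coef = c(900, -0.25),
    humps = data.frame(center = 1100, amplitude = 1800, width = 450),
    noise_sd = noise_sd,
    spikes = data.frame(position = c(700, 1100), amplitude = c(1500, 1200)),
    n_replicates = n_replicates,
    amp_jitter = 0.08,
    baseline_jitter = 0.15,
    seed = seed)
}

#' Built-in fixtures: a two-analyte (BPE-like / R6G-like) pair
#'
#' Two five-replicate specs on a common 600-1600 cm^-1 axis with disjoint
#' peak tables (cross-class centre separation > 3x peak width), mild
#' baselines and noise — the class structure that drives the clustering /
#' PCA / t-SNE demonstrations.
#'
#' @param seed master seed (the second class uses `seed + 1000`).
#' @param n_replicates replicates per class (default 5).
#' @return List with elements `a` and `b`, both [syntheticSpec()].
#' @export
twoClassSpecs <- function(seed = 7L, n_replicates = 5L) {
  list(
    a = syntheticSpec(
      axis_min = 600, axis_max = 1600, axis_step = 1,
      peaks = data.frame(
        center    = c(660, 1020, 1200, 1340, 1560),
        amplitude = c(500, 900, 700, 450, 600),
        width     = c(9, 10, 12, 10, 9),
        shape     = c("lorentzian", "lorentzian", "gaussian", "lorentzian",
                      "gaussian")),
      baseline_coef = c(150, -0.05),
      humps = data.frame(center = 1050, amplitude = 250, width = 400),
      noise_sd = 10,
      n_replicates = n_replicates,
      amp_jitter = 0.10, baseline_jitter = 0.10,
      seed = seed),
    b = syntheticSpec(
      axis_min = 600, axis_max = 1600, axis_step = 1,
      peaks = data.frame(
        center    = c(612, 774, 1090, 1270, 1507),
        amplitude = c(650, 500, 850, 550, 750),
        width     = c(10, 9, 11, 10, 9),
        shape     = c("lorentzian", "gaussian", "lorentzian", "gaussian",
                      "lorentzian")),
      baseline_coef = c(120, -0.04),
      humps = data.frame(center = 1000, amplitude = 220, width = 380),
      noise_sd = 10,
      n_replicates = n_replicates,
      amp_jitter = 0.10, baseline_jitter = 0.10,
      seed = seed + 1000L))
}

#' Read / write a SyntheticSpec as YAML
#'
#' @param path YAML file.
#' @return `readSyntheticSpec` returns a [syntheticSpec()];
#'   `writeSyntheticSpec` invisibly returns `path`.
#' @export
readSyntheticSpec <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("peaks", "humps", "spikes")) {
    if (!is.null(raw[[f]]))
      raw[[f]] <- as.data.frame(do.call(rbind, lapply(raw[[f]], as.data.frame)))
  }
  do.call(syntheticSpec, raw)
}

#' @rdname readSyntheticSpec
#' @param spec a `SyntheticSpec`.
#' @export
writeSyntheticSpec <- function(spec, path) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  out <- unclass(spec)
  for (f in c("peaks", "humps", "spikes")) {
    if (!is.null(out[[f]])) {
      df <- out[[f]]
      out[[f]] <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
    }
  }
  out <- Filter(Negate(is.null), out)
  yaml::write_yaml(out, path)
  invisible(path)
}
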