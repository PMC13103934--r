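---
title: "Methods: preprocessing and chemometrics for Raman/SERS replicate sets"
author: "spectrakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preprocessing and chemometrics for Raman/SERS replicate sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectrakit)
```

## The data model

A `SpectrumSet` couples a strictly increasing wavenumber axis (cm⁻¹, length
M) with an N × M intensity matrix, unique per-spectrum labels and optional
class groups. The axis is shared by construction: operations that need a
common grid (merging, the variation statistics, all multivariate analytics)
can then assume it, and files that disagree on their axis are rejected at
read time with a pointer to `interpolateToGrid()` rather than silently
fuzz-matched. Axis equality between files is exact equality of parsed
doubles — the toolkit itself establishes a common grid via interpolation, so
the reader has no reason to tolerate approximate matches. Decreasing or
duplicated axes are errors, never auto-sorted: a reversed file usually
signals an export problem upstream, and silently fixing it would mask that.

Intensities are 64-bit doubles end to end, and the writers print them with
17 significant digits (`%.17g`), so a write/read round trip reproduces every
value bit-for-bit. Number parsing accepts comma or whitespace delimiters and
decimal points only; locale decimal commas are deliberately unsupported
because they are indistinguishable from column separators in two-column
files.

## The preprocessing chain

Each operation acts on all spectra of a set, never mutates its input, and
preserves labels and groups. The standard chain is: integer-grid
interpolation → crop to the 600–1600 cm⁻¹ fingerprint region → despike →
Savitzky–Golay smoothing → airPLS baseline correction → area normalization.

**Interpolation** resamples onto consecutive integer wavenumbers from
⌈min⌉ to ⌊max⌋ by linear interpolation between the two bracketing samples,
never extrapolating. An input whose range contains fewer than two integers
is an error (the container requires M ≥ 2, so a one-point "set" cannot
exist).

**Despiking** targets cosmic-ray events: single-sample, high-amplitude,
positive excursions. Within each requested window, a point is flagged when
it exceeds the running median (default window 11) by more than the threshold
(default 300, in absolute intensity units on raw counts — the threshold is
not normalized, matching how detector counts are usually screened), and
flagged points are replaced by linear interpolation across the nearest
unflagged neighbours. The running median is robust to the spike itself, so a
spike cannot mask its own detection; points outside the windows are left
bit-identical. When no windows are given the whole axis is screened.

**Savitzky–Golay smoothing** (default window 15, order 2) is the moving
least-squares polynomial filter; interior points use the centred kernel
built by explicit least squares, and each edge point is the value at its own
position of a polynomial fitted to the nearest full window, so no samples
are truncated and M is unchanged. The filter reproduces polynomials up to
its order exactly, which the tests exploit as an oracle. **Fourier
filtering** is offered as an alternative: mirror padding to length 2M (which
bounds edge ringing and is deterministic), a hard cutoff at the stated
fraction of Nyquist, inverse transform, truncate.

**airPLS baseline correction** alternates a weighted Whittaker smoother
`z = argmin Σ w_k (y_k − z_k)² + λ Σ (Δ^d z)²` with the reference
reweighting scheme: with residual d = y − z and D = Σ_{d_k<0} |d_k|, weights
are 0 where d_k ≥ 0, exp(t·|d_k|/D) where d_k < 0, and both endpoints get
exp(t·max|d_k|/D); iteration stops when D < tol·Σ|y| or at `max_iter`. The
`order` parameter is the difference order d of the penalty, exactly as in
the reference algorithm. Note that d = 1 penalizes slope, so its null space
contains only constants; a straight-line input is reproduced exactly at
d = 2, while at d = 1 it is tracked closely but not to round-off (the
endpoint weighting pins the ends). The default parameters (λ = 100, order 1,
15 iterations, tolerance 0.001) recover a linear baseline under narrow
Lorentzian peaks to well under 5% of the baseline's dynamic range, which is
what the acceptance checks assert. The Whittaker system is solved exactly
(sparse symmetric solve via the Matrix package); a singular system is
reported, not silently regularized. Two alternatives are provided:
**iterative minimum-polynomial** fitting (fit, clip to the pointwise
minimum, repeat), and a **Gaussian–Lorentzian (pseudo-Voigt)
broad-background fit** whose component widths are bounded below (default
200 cm⁻¹, well above vibrational peak widths of 5–30 cm⁻¹) so the fit can
only follow the slowly varying background. The pseudo-Voigt formulation is
this package's own operational definition of Gaussian–Lorentzian baseline
fitting, chosen because it nests both profile families with one mixing
parameter per component. All three return baselines and corrected spectra
satisfying `corrected + baseline = input` to round-off.

**Normalization** offers area (trapezoidal area → 1), peak (maximum, or the
sample nearest a stated position, → 1) and min–max ([0, 1]) modes; all are
idempotent. The trapezoidal rule defines "integrated area" everywhere in the
package — on the integer grid it coincides with the interior sum, and it
makes the relative variation equal σ_avg after area normalization, an
identity the tests assert. Degenerate inputs (zero area, zero peak, constant
spectrum) raise errors naming the offending spectrum rather than emitting
NaNs that would poison the multivariate analytics downstream.

**Outlier screening** compares each spectrum with the leave-one-out
consensus mean under three criteria — Pearson correlation below a threshold,
mean absolute deviation above a multiple of the pooled per-wavenumber SD,
and Euclidean distance above a multiple of the median such distance. The
criteria combine with OR by default (a spectrum failing any screen is
suspect); AND is exposed for conservative screening. If a consensus is
constant the correlation criterion is skipped with a recorded warning.

## Reproducibility statistics and analytics

σ_avg is the mean over the current (possibly cropped) axis of the
across-replicate sample SD (N − 1 denominator, fixed by the definition).
The relative variation divides by the trapezoidal area under the mean
spectrum. Peak identification uses the contour definition of prominence:
each side's base level is the signal minimum between the peak and the
nearest strictly higher point (or the axis boundary when none exists), and
the prominence is the height above the larger base level. Interior plateaus
report their midpoint, left-biased for even lengths — a deterministic
convention. Ties in the top-n ranking break toward lower wavenumber.

Ward HCA runs on Euclidean distances with the standard Ward height scale
(two singletons merge at ‖a − b‖), delegated to `stats::hclust(method =
"ward.D2")` and verified in the tests against a hand Lance–Williams
computation. PCA is column-centred SVD without per-wavenumber scaling —
the spectra entering PCA are already normalized, and standardizing would
inflate quiet spectral regions; each loading is oriented so its
largest-magnitude element is positive, making score plots reproducible.
The correlation matrix optionally appends the grand mean of all spectra as
a final reference row/column (the mean is not recomputed leave-one-out; it
is the same reference for every spectrum).

t-SNE is implemented exactly (dense gradient, perplexity-calibrated
Gaussian input kernel, Student-t embedding kernel, early exaggeration 12
for the first quarter of iterations, momentum 0.5 → 0.8, learning rate 200
with adaptive gains), because the environment this package targets ships no
R t-SNE implementation to delegate to. For the replicate-set sizes the
workflow is designed around (tens of spectra) the exact gradient is
instantaneous and, unlike approximate schemes, bit-reproducible for a given
seed. The feasibility bound is perplexity ≤ (N − 1)/3, inclusive so that
the conventional small-sample setting (perplexity 3 at N = 10) is usable.
The RNG state is saved and restored around the embedding, so calling it
never perturbs a caller's random stream; the same holds for the synthetic
generator.

## The pipeline runner and provenance

A `PipelineConfig` is an ordered list of steps, each a registered operation
name plus parameters. Validation happens before any computation: unknown
operations, unknown parameters and missing required parameters are all
rejected up front, and defaults are expanded at validation time so the
resolved configuration is self-contained. Each executed step appends a
provenance entry carrying the operation name, the exact (fully expanded)
parameters, input/output shapes and a timestamp. Because every operation is
deterministic, replaying a log on the original input reproduces the output
bit-identically — the package's reproducibility contract, asserted in the
tests at the level of file checksums. The CLI's `process` command
additionally writes a run manifest with input and output checksums so stale
inputs are detectable.

## The synthetic generator

`generateSpectra()` emulates the raw-data morphology the chain is built
for: a polynomial baseline under broad Gaussian fluorescence humps,
vibrational peaks (Gaussian `A·exp(−(x−c)²/2w²)` or Lorentzian
`A·w²/((x−c)²+w²)`, amplitude = apex height), i.i.d. Gaussian noise, and
single-sample positive spikes. Replicate-to-replicate variation is one
global peak-amplitude factor plus an independent baseline scale factor per
replicate — the structure that makes raw σ_avg baseline-dominated and lets
baseline correction collapse it, mirroring the behaviour demonstrated on
real protein replicates. Each replicate draws from its own stream derived
from (seed, replicate index), so increasing N extends a set without
reshuffling earlier replicates. The truth record (noise-free baseline,
peaks-only signal, noise matrix, spike table, jitter factors) reconstructs
the output exactly, which is what makes truth-based testing unambiguous.

The built-in fixtures state the study conditions used throughout the tests
and the acceptance script: `bsaLikeSpec()` — five replicates over
400–1800 cm⁻¹, peaks at 702/877/1087/1308/1443 cm⁻¹, noise SD 20 counts,
8% amplitude and 15% baseline jitter, spikes (+1500, +1200 counts) at 700
and 1100 cm⁻¹; `twoClassSpecs()` — two five-replicate classes on
600–1600 cm⁻¹ with disjoint peak tables (cross-class centre separation
greater than three peak widths), mild baselines, noise SD 10. These sizes
(N = 5–10, M = 1001–1401) match typical SERS replicate experiments and keep
the full suite fast. What the generator does **not** emulate: detector
physics (wavelength-dependent response, shot-noise scaling with intensity),
correlated noise, peak-position drift between replicates, and negative-going
artifacts. Passing tests therefore demonstrate algorithmic correctness on
data with known structure, not robustness to every instrumental pathology.

## Known limitations

- airPLS convergence uses the reference negative-residual-mass criterion,
  which can terminate early on very smooth, noise-free inputs; the default
  λ = 100 is tuned for raw-count scales and may need raising for weak
  signals.
- The Gaussian–Lorentzian background fit is a bounded nonlinear least
  squares problem; with many components it can converge to local minima,
  which is reported per spectrum via the convergence flag.
- The exact t-SNE is O(N²) per iteration and intended for small sets; for
  hundreds of spectra PCA or HCA are the appropriate first tools.
- Outlier screening assumes at least three spectra and a meaningful
  consensus; it screens whole spectra, not individual wavenumber artifacts
  (that is the despiker's job).
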