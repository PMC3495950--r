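---
title: "Models and methods in seldiproc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in seldiproc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seldiproc)
```

This vignette is the package's own account of its models: what is being
estimated, which defaults matter and why, the numerical choices that are
not visible from the API, and what a green test suite does and does not
establish.

## The data model

A SELDI-TOF spectrum is a vector of detector intensities on an m/z grid.
The package's working model, which the synthetic generator states
explicitly, has four ingredients:

1. **Peaks** are approximately Gaussian with width proportional to mass
   (`sigma = width_coeff * mz`): TOF resolution degrades with m/z, so a
   1,000 Da analyte and a 12,000 Da analyte differ in width by an order
   of magnitude. Nothing downstream assumes Gaussianity — detection is by
   local maxima and quantification is trapezoidal — but feature windows
   and the clustering tolerance are proportional to m/z for this reason.
2. **Across spectra**, the same analyte appears within a small relative
   mass jitter (default 0.1 %, safely inside the 0.3 % clustering
   tolerance), with a per-cluster *prevalence*: the probability the
   analyte is present in a given sample.
3. A smooth decaying **baseline** (chemical/matrix background) sits under
   everything.
4. **Noise** is additive, independent across grid points, with variance a
   quadratic function of the local mean intensity — the quadratic
   variance function (QVF) v(mu) = c0 + c1 mu + c2 mu^2. This captures a
   detector whose noise grows with signal, interpolating between
   constant-variance (c1 = c2 = 0) and Poisson-like (c0 = c2 = 0)
   behavior.

## QVF estimation and variance stabilization

`pointwise_mean_var()` computes, at every grid point inside user-chosen
peak-free regions, the across-spectra mean and unbiased variance;
`fit_qvf()` regresses variance on `[1, mu, mu^2]` by OLS. Region choice
is deliberately manual-first (the package only *proposes* regions, by a
low-quantile rule on the smoothed set mean) because peak-free is a
judgment the analyst is better placed to make; an automated default is
provided so pipelines run unattended.

The QVF feeds the denoiser through the variance-stabilizing transform
`z = \int dy / sqrt(v(y))`, evaluated in closed form per branch of the
quadratic (logarithmic for c2 > 0, arcsine for c2 < 0, square-root for
c2 = 0, linear for constant variance). After stabilization the noise is
approximately unit variance, so a single universal threshold applies to
all wavelet levels, and `unstabilize_variance()` restores the intensity
scale exactly (round-trip to 1e-8 relative, tested).

Two numerical guards exist because OLS fits of a near-linear QVF
routinely produce slightly negative c2 or negative predicted variances
near zero mean:

* predictions are floored at the smallest positive observed variance;
* before stabilizing a trace, c0 is raised just enough that v stays
  positive over that trace's observed intensity range (a fitted QVF is
  only trusted near the means it was fitted on).

## The two processing tracks

A single smoother cannot serve both peak detection and quantification:
aggressive wavelet shrinkage gives clean traces whose local maxima are
trustworthy but whose apex heights are biased low; a gentle linear
smoother preserves heights but leaves hundreds of noise maxima. The
pipeline therefore keeps both tracks.

### Detection track: cycle-spinning wavelet shrinkage

The orthonormal periodic DWT of a length-n signal (n a power of 2;
non-dyadic inputs are padded by symmetric reflection and cropped after)
is materialized once as a sparse matrix and cached on disk; denoising is
then `W' T(W z)` with `T` soft thresholding of the detail coefficients at
the universal threshold sqrt(2 log n). Cycle spinning averages this
estimator over circular shifts — shift, denoise, unshift, average —
which suppresses the pseudo-Gibbs ringing a single orthonormal basis
produces near sharp features; with the full shift set the estimator is
exactly translation-invariant (tested exhaustively at n = 64).

Defaults and the reasoning behind them:

* **Wavelet**: Daubechies with 8 vanishing moments, constructed at run
  time by spectral factorization of the binomial half-band polynomial
  (no wavelet dependency exists in the target environment; construction
  is verified against orthonormality and vanishing-moment identities).
  Smooth enough for peak-shaped signals; the family is configurable.
* **Shift set**: the consecutive shifts `0..k-1`, default k = 32. This
  is a deliberate deviation from "k evenly spaced shifts": evenly spaced
  shifts of a dyadic signal are multiples of 2^levels, which the
  decimated DWT *commutes with*, so averaging over them changes nothing
  (we measured it: identical output to one shift, to 1e-13). Consecutive
  shifts are the standard sufficient set.
* **Depth**: 4 levels, i.e. only the four finest detail scales are
  thresholded and an approximation band of n/16 coefficients passes
  untouched. Deep decompositions (e.g. log2(n) - 4 levels, leaving a
  16-coefficient approximation band) threshold coarse bands that carry
  peak and baseline energy; on the stated synthetic world they make the
  denoised RMSE *worse than the raw input* (raw 1.6 -> 2.2–2.5 at depth
  8, versus 0.6–0.9 at depth 4). The trade-off: at depth 4 pure noise
  retains the ~1/16 of its energy living in the approximation band, so
  the "output energy <= 5 % of input on pure noise" property holds at
  depth 8 (where it is tested), not at the default depth. Detection is
  indifferent — the surviving approximation-band noise is smooth and
  sits below the SNR threshold.

### Quantification track: zero-phase equiripple FIR

`design_quant_filter()` runs a Parks–McClellan (Remez exchange)
equiripple design, implemented in-package (Type I and II linear-phase
lowpass; the exchange solves the alternation system directly on the
extremal set and iterates to the equiripple solution). Defaults: order
67 (68 symmetric taps), transition band 0.15–0.25 of Nyquist, passband
weight 1, stopband weight 10 = ripple / 10^(-60/20). The measured
single-pass response exceeds both printed specs with margin (~0.0035
passband deviation against 0.01 allowed; ~69 dB stopband against 60
required). The order is *fixed* rather than re-derived from an
order-estimation formula: published order-estimation heuristics disagree
and the ripple spec's units (linear vs dB) are ambiguous, so pinning the
published order and verifying the measured response is the reproducible
choice. "Pass-band ripple of 0.01" is read as linear deviation, and
tested as such.

`zero_phase_filter()` applies the filter forward and backward
(effective response |H|^2, zero phase), with reflective padding of three
filter lengths per edge, so apex locations are preserved exactly and
heights within 5 % for peaks at least 5 grid steps wide (tested).

## Peaks, clusters, prevalence

Local maxima are strict, with plateaus resolved to their center sample
(left-of-center on even plateaus — an arbitrary but fixed tie-break) and
flanking valleys at the nearest local minima. The detection threshold in
the pipeline is `snr_min` (default 5) times the noise sd implied by the
fitted QVF at the median denoised intensity — a single global threshold
tied to the noise model rather than a per-peak S/N heuristic.

Clustering of pooled apex lists is single-linkage with a relative gap
cut: adjacent sorted apexes link while their gap is at most 0.3 % of the
pair mean. The gap-based rule (rather than distance-from-cluster-mean)
makes the partition order-free and deterministic; an O(n^2) union-find
oracle over all pairs confirms the partitions agree on random data. At
most one peak per spectrum is kept per cluster (the one closest to the
cluster mean), prevalence is members over total spectra, and the
reproducibility rule keeps clusters at >= 80 % prevalence (24 of 30
spectra is in; 23 of 30 is out).

One subtlety the two-group pipeline exposes: a cluster fully present in
controls but absent in cases has *pooled* prevalence near 50 % and is
removed by the 80 % rule before statistics. For case/control contrast
discovery the threshold should sit below the smallest group fraction
(`pipeline_config(min_prevalence = ...)`); the default mirrors the QC
reproducibility setting.

## The neural-network validator

Each candidate peak is described by 62 numbers from a window
`mu * (1 +/- 0.003)`: the OLS quadratic coefficient of the raw trace in
the window (concave-down curvature is what a "healthy" peak looks like;
the raw coefficient is stored unmodified), the mass itself (peak shape
changes with mass, so the validator must be allowed to condition on it),
and 30 + 30 linearly interpolated processed and raw intensities on an
even grid spanning the window exactly. The window width reuses the
clustering tolerance: the visual-inspection zoom (+/- 2 %) is far wider
than a single peak, and a validator should see one candidate at a time.

Features are standardized per dimension with statistics from the
training split only; the scaler rides along with the model and is applied
unchanged to validation, test, and clinical data.

The network is 62–20–1 with sigmoid activations ("63 input nodes, 21
hidden nodes, 1 output, counting biases"), trained by minimizing the
regularized cross-entropy

J = -(1/m) sum[ t log p + (1 - t) log(1 - p) ] + (lambda / 2m) sum(non-bias weights^2)

with probabilities clipped at 1e-12 inside the logs, bias columns
excluded from the penalty, exact backpropagation gradients
(finite-difference-verified at 1e-6 relative), and Polak–Ribière(+)
conjugate gradients under a strong-Wolfe line search, at most 400
iterations. The line search substitutes a standard strong-Wolfe
bracket-and-zoom for the unexplained "slope-ratio" step rule of the
original description; the convergence contract (accepted steps never
increase J; the returned weights are the best encountered) is what the
tests pin down. lambda is selected on the validation split of a random
exact-count 50/25/25 split, over 13 log-spaced points on [0.003, 10],
ties to the smaller lambda. Classification threshold is 0.5 with the
boundary keeping the peak.

Cluster validation then walks the spectra: highest processed-track local
maximum in the window around the cluster m/z (if several maxima exist,
the highest is the candidate — the procedure's "a local peak exists" does
not disambiguate), features at that apex, keep iff the network says
>= 0.5, prevalence = kept / all spectra, heights and areas recorded from
the quantification track for the group analysis.

## Group statistics

Per validated cluster: Welch t (the unpooled variant is the safer
default when the variant is unspecified) and Mann–Whitney U on heights
and areas, and the Fisher exact test with mid-P correction on the
present/absent-by-group 2x2 table. The mid-P one-tail counts half the
observed table's probability plus all strictly more extreme tables in
the observed direction; the two-sided p doubles it, capped at 1. The
doubling convention is used because it reproduces the reference value
0.00707 -> 0.007 for the (3/8 vs 15/16) prevalence table, which the
minimum-likelihood two-sided convention does not; both the value and the
less-conservative-than-exact property are verified by hypergeometric
enumeration. The Mann–Whitney exact branch uses the exact null U
distribution for untied data at min(n) <= 8 (identical to full
enumeration, which remains as the test oracle) and the tie-corrected
normal approximation otherwise. No multiplicity correction is applied;
the report says so in an attribute rather than silently.

## The synthetic world, and what a green suite establishes

Generator defaults: 4,096 points over 3–15 kDa, width_coeff 0.004
(peak sigma 0.4 % of m/z — 4 to 20 grid steps across the range),
baseline 20 exp(-(m - 3000)/4000), QVF (1, 0.05, 0.001) (noise sd ~1 in
the valleys, ~4 under the tallest peaks), 0.1 % jitter, 20 clusters at
heights 40–100 with prevalences in {1, 0.9, 0.85} plus two sub-threshold
decoys (0.5, 0.3), 30 subjects. These were chosen once as a realistic
low-mass profiling analog and are not tuned per test.

What the generator deliberately omits: isotope envelopes and adducts,
detector saturation, correlated (colored) noise, drifting calibration,
spectrum-to-spectrum baseline variation, and biological intensity
covariance between analytes. Consequences worth stating plainly:

* The end-to-end benchmark (sensitivity 1.0 at FDR 0 on the default
  world) shows the pipeline recovers *this* world's reproducible
  clusters; real QC data, with correlated noise and uncalibrated mass
  drift, is harder.
* The validator separates planted apexes from noise maxima essentially
  perfectly (held-out accuracy 1.0 on the synthetic fixture). That
  establishes the training/selection machinery works — not that it would
  reach the ~95 % accuracy of a network trained on thousands of
  expert-annotated real peaks, a strictly harder discrimination.
* Reported operating points on real instruments (e.g. recovering half of
  true clusters at zero FDR) are not reproducible without the original
  spectra and annotations and are not claimed by any test here.

## Known limitations

* The wavelet operator cache stores one sparse matrix per
  (family, n, levels); at n = 2^15 the build takes noticeably longer
  than a cascade transform would — the matrix pays off only when many
  spectra share a grid, which is the intended regime.
* The mzML reader/writer covers the minimal profile the package itself
  emits (64-bit uncompressed arrays, MS1); it is not a general vendor
  -file reader.
* `subtract_baseline()`'s no-increase guarantee presumes a nonnegative
  baseline; on a zero-mean pure-noise trace the opening is negative and
  subtraction raises intensities. Real spectra are nonnegative.
* Replicate averaging happens after baseline/TIC and before denoising;
  the order is fixed, not configurable.
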