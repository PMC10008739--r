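---
title: "Models and methods behind f19mr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind f19mr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(f19mr)
```

`f19mr` implements the analysis chain for fluorine-19 MR detection and
quantification of fluorinated drugs: spectral Voigt fitting with
hardware-artifact subtraction, relaxometry with model selection, radial
ultrashort-echo-time (UTE) reconstruction with off-resonance correction
and SNR-based quantification, and closed-form pulse-sequence optimization.
This vignette records the models, the conventions, the numerical choices,
and what the synthetic validation does and does not establish.

## Spectral model and conventions

A free induction decay (FID) is a multi-channel complex time series
sampled every `dwell_time` seconds. Spectra use the continuous-transform
convention `S(f) = dt * sum_n s_n exp(-2*pi*i f n dt)` on a ppm axis
referenced to CFCl3 (`ppm = f_Hz / f0_MHz + carrier_ppm`), so that peak
heights do not depend on the zero-padding length and Parseval's identity
holds between `integral |s|^2 dt` and `integral |S|^2 df`. Dispersion
(imaginary) parts are negative just above a resonance, the sign a causal
`t >= 0` FID produces.

Each line is a Voigt profile with real-part peak amplitude `a`, centre
`v` (ppm), full width at half maximum `w` (ppm), mixing parameter
`m` in [0, 1] and zeroth-order phase `p`. Two conventions are provided
behind one interface, because the source processing chain names both a
mixing parameter and a Faddeeva evaluation without reconciling them:

* **pseudo-Voigt** (default): `m L(f) + (1-m) G(f)`, the convex
  combination of a unit-height complex Lorentzian and complex Gaussian
  sharing the real-part FWHM `w`. The Gaussian's dispersion part is the
  exact one-sided-FID transform, evaluated through the Faddeeva function.
* **true Voigt** (`convention = "faddeeva"`): the convolution profile
  with Lorentzian FWHM `m*w` and Gaussian FWHM `(1-m)*w`, normalized to
  unit height; validated in the test suite against adaptive quadrature of
  the convolution integral.

`faddeeva()` evaluates `w(z) = exp(-z^2) erfc(-iz)` by Weideman's
rational approximation. The default order 24 keeps the relative error
below 1e-6 everywhere we evaluate (in practice ~1e-10 for moderate
arguments); the lower half-plane uses the reflection identity. Fit
results record the convention used.

The coupled two-line artifact model is
`L(f) = a e^{-i phi f} (r e^{-ip} V1 + (1-r) e^{-iq} V2)`: the
amplitudes are `r*a` and `(1-r)*a` by construction, so the ratio `r` can
carry a prior independent of absolute signal level. The first-order phase
`phi` acts on the raw ppm axis (pivot 0), matching the `e^{-i phi f}`
form; `phase_correct()` by contrast pivots at the carrier, which is the
convenient choice for display phasing.

## Preprocessing choices

The digital receive filter distorts the first few points of an FID; they
are stored as `filter_delay_points` and dropped as an integer left shift
(fractional group-delay correction is out of scope). `truncate_to` is a
raw-sample cutoff, so truncating to fewer samples than the filter delay is
an error. Truncation before transformation is the poor man's matched
filter: for short-T2* signals it removes noise-dominated tail samples and
raises peak SNR, at the cost of sinc ripple when the signal has not
decayed into the noise by the cutoff — the test suite exercises both
regimes.

## Artifact characterization and subtraction

Empty-coil control spectra are fitted per channel with the coupled model;
the sample mean and standard deviation of `(r, v1, w1, m1, v2, w2, m2)`
across control scans form a Gaussian prior. `published_artifact_stats()`
ships the published two-channel statistics as a ready-made prior or as a
generator of synthetic control/tissue spectra.

`constrained_fit()` maximizes a penalized least-squares objective: complex
residuals weighted by the spectrum noise level plus standardized penalty
residuals `sqrt(weight) (theta - mu)/sigma'` on the seven constrained
parameters. The centre-frequency sds are inflated by a field-drift
allowance of 250 Hz (`sigma' = sqrt(sigma^2 + (250 Hz in ppm)^2)`);
amplitude, global phases and the free (drug) peak are unpenalized. The
free peak is bounded to a configurable drug window (default -70..-50 ppm).
With the prior sds inflated toward infinity the fit converges to the
unconstrained three-peak fit, which the tests verify.

Least squares has a failure mode worth naming: an *unmodelled* resonance
(a potential metabolite) overlapping an artifact tail gets partially
absorbed into the artifact parameters and is then subtracted along with
them. `constrained_fit(robust = TRUE)` (the default) therefore performs
one refit in which bins carrying coherent residuals above 4 noise sds,
located outside the artifact line cores and the drug window, are given
zero weight. The remaining, irreducible uncertainty of the artifact tail
underneath an overlapping peak is set by the prior widths — of order a few
percent of a comparable-amplitude peak — which is why downstream
metabolite quantification is done with a *localized* Voigt-plus-baseline
fit (`crop_spectrum()` then `fit_voigt()`): the low-order baseline absorbs
the smooth tail error. The validation suite shows ~1.5% median amplitude
error for a -76.2 ppm test resonance under scan-to-scan artifact
variation at the published prior widths.

`subtract_artifact()` removes only the evaluated coupled component; it is
linear, so subtracting twice over-subtracts exactly once more (tested).

## Relaxometry

Signal equations: `S(TR) = A(1 - exp(-TR/T1))` for saturation recovery
and `S(t) = A(beta exp(-t/T2a) + (1-beta) exp(-t/T2b))` for decays, fitted
by Levenberg-Marquardt least squares (optionally weighted) with the
linearized covariance `V_p = sigma_r^2 (J^T J)^{-1}`; for linear models
this reproduces the exact OLS covariance (tested to numerical precision).
Bi-exponential results are reported in the canonical order `T2a <= T2b`
to resolve label switching.

One estimator decision deserves emphasis: the component fraction `beta`
is *not* clamped to [0, 1] during fitting. Clamping puts the
mono-exponential null on the constraint boundary, where the nested
likelihood-ratio statistic `Lambda = n log(RSS_mono/RSS_bi)` is far from
its chi-square(2) reference and the test becomes severely conservative.
With free component amplitudes the model family is locally regular around
a mono truth and the chi-square(2) reference calibrates well (type-I rate
~0.05 and near-uniform p-values in the 1000-simulation suite). Fits whose
`beta` leaves [0, 1] are flagged, as are fits whose standard errors exceed
the estimates and bi fits collapsing to `T2a = T2b` within 1%. The
multi-start includes nearly-cancelling component pairs because the small
RSS gains available near a mono truth hide in those shallow minima.

Apparent relaxation times summarize a bi-exponential by the unique root
of the normalized decay at `1/e` (bracketed root-finding; the root always
lies between the two time constants). `apparent_t2_mc()` propagates the
fit covariance by sampling `(beta, T2a, T2b)` from a multivariate normal
(5e4 draws by default), rejecting-and-resampling draws that violate the
physical constraints (count reported; more than 50% invalid aborts), and
solving all draws by vectorized bisection.

## Radial UTE simulation and reconstruction

The trajectory model is centre-out radial: spherical-Fibonacci
(golden-angle) directions in 3D, golden-angle increments in 2D; sample
`j` on a spoke sits at radius `(j-1) * 0.5/J` cycles/voxel (2x readout
oversampling at the default `J = matrix_size`) and is acquired at
`TE + (j-1) * dwell`. Phantoms are sums of ellipsoids, whose Fourier
transform is analytic; each object carries its own T2* (applied per
sample time, not per spoke — off-resonance correction tests require this)
and off-resonance `exp(-2*pi*i df t)`. Channel noise is circularly
symmetric complex Gaussian with an arbitrary Hermitian positive-definite
channel covariance; the inter-channel correlation is a free parameter, as
no measured value is available for the two-channel cryoprobe.

Reconstruction is the adjoint non-uniform Fourier transform by
convolution gridding: Kaiser-Bessel kernel of width 5 on a 2x-oversampled
grid with the Beatty beta, wrap-around deposit, inverse FFT, centre crop
and division by the kernel's closed-form transform. Density compensation
uses exact shell (3D) or annulus (2D) areas per sample, which gives the
central sample the innermost half-shell volume — the DC correction.
Correctness is defined against the direct discrete adjoint sum
`x_n = sum_m w_m y_m exp(2*pi*i k_m . r_n)`, not against a particular
kernel: the acceptance suite requires < 1% normalized RMS deviation on a
16^3 grid with 200 spokes (measured ~3e-5).

Off-resonance during a centre-out readout turns a point source into a
ring (each spoke's content shifts radially outward), so PSF width is
measured as the equivalent diameter of the above-half-maximum region,
which is meaningful for both compact and ring-shaped blurs. The
correction multiplies each sample by `exp(2*pi*i (TE+(j-1)t_d) df)` and
restores the on-resonance PSF exactly in the simulation.

## Noise statistics, masking and quantification

Root-sum-of-squares combination of `Nc` channels turns unit-variance
complex Gaussian noise into a chi distribution with `2 Nc` degrees of
freedom; the per-component noise sd is estimated from the mean of an
RSS noise image via `mean / (sqrt(2) Gamma(Nc + 1/2)/Gamma(Nc))`
(`mean/1.2533` for one channel). Prewhitening estimates the channel
covariance from a zero-excitation scan and applies the inverse Cholesky
factor, after which that correction is exact by construction. Cluster
thresholding keeps voxels above an SNR cutoff (defaults 3.5 in vivo /
4.0 ex vivo) in connected components (26-neighbourhood in 3D, 8 in 2D)
of at least `min_cluster = 2` voxels; the cited thresholding protocol's
exact parameters are not restated in the source, so these are exposed in
the configuration.

Concentration maps are voxelwise signal-intensity ratios against a
reference-phantom acquisition times the reference concentration, with an
explicit scale factor for deliberate protocol differences (averages scale
signal linearly). Because single voxels at a hot-spot maximum carry
Gibbs-ringing and noise excursions of order +10%, `hotspot_summary()`
reports a cluster's concentration as the mean over its peak region (the
voxels within 90% of the cluster SNR maximum) — in the validation
scenario this lands within ~6% of a 145 uM ground truth against a
3.9 mM reference. The scan-time-adjusted protocol sensitivity ratio
averages voxelwise SNR ratios over the joint mask `SNR > 10` and
multiplies by `sqrt(ta_b/ta_a)`; any averages-versus-wall-time adjustment
enters as an explicit factor.

## Protocol optimization

Closed forms: Ernst angle `acos(exp(-TR/T1))`; bSSFP optimum
`acos((T1/T2-1)/(T1/T2+1))` (its short-TR validity is cross-checked
numerically against the steady-state signal equations, as is Ernst
optimality); spoiled-GE steady state
`sin(a)(1-E1)/(1-cos(a)E1) exp(-TE/T2*)`. The RARE PSF model assigns
phase-encode lines centre-out (or linearly) to echoes in equal segments
and weights each line by the normalized decay at its echo time; the PSF
is the magnitude of the inverse transform on a 64-fold refined grid and
the ETL selector returns the largest divisor of the line count whose FWHM
stays below 1.5 voxels. The exact segmentation of the two phase
dimensions behind the published ETL choices is not stated, so the
selector's reproduction of those numbers is accurate to one ETL step
(it selects one divisor lower for both temperature conditions at the
published echo spacing), and the published bSSFP angles are not exactly
reproduced by any single tabulated (T1, T2) pair; neither is asserted
exactly.

Sensitivity arithmetic is elementary but worth centralizing:
`SNR_eff = SNR/sqrt(TA in h)`; detection limits scale as
`sqrt(t_ref/t_new)`; atoms per voxel is Avogadro arithmetic; equal
relative spatial resolution across species means the voxel volume scales
with brain volume and the edge with its cube root; an SNR ratio `x` is
worth `x^2` in acquisition time; steady-state tissue levels scale
linearly with dose.

## What the synthetic data do and do not establish

The generators emulate: Voigt line shapes with the published artifact
statistics and scan-to-scan parameter variation, mono/bi-exponential
relaxation at the tabulated time constants, piecewise-constant radial
k-space with per-sample decay/off-resonance, and correlated channel
noise. They do not model B0/B1 field structure, gradient-timing
imperfections, motion, eddy currents, or receive-field inhomogeneity
beyond an optional smooth per-object sensitivity factor — so passing
tests demonstrate the correctness and calibration of the *analysis*, not
robustness to those instrument effects. Quantification against a
reference phantom is validated with matched relaxation properties; in
real tissue, T2*/B1 mismatches between sample and reference add biases
the package does not correct.

Validation design choices, fixed before-hand and sized for a single CPU:
parameter-recovery suites use 200 seeds at 1% *relative* noise with
correspondingly weighted fits (constant-SNR-per-point is the regime in
which all bi-exponential parameters, including a weak slow component,
are identifiable to the percent level; with constant absolute noise the
slow time constant of the strongly-weighted fast-decay condition is
unidentifiable at any realistic level and no estimator meets a 2% bias
bound); the LRT calibration uses 1000 mono-truth simulations at SNR 30;
artifact recovery uses 50 seeds at peak SNR 25 on 8192-bin spectra;
reconstruction oracles use 16^3/200 spokes (3D) and 12^2/50 spokes (2D);
the off-resonance PSF study uses a 64^2 matrix at a 2 kHz offset; noise
statistics use 1e5 samples; the quantification scenario uses the 1 mm /
24^3 brain-protocol geometry with 2-fold angular undersampling, two
channels, and the noise level of a 4-average acquisition.

## Known limitations

Automatic phasing is limited to fit-based zeroth-order estimates; no
eddy-current or lineshape-distortion correction; no stimulated-echo
correction for CPMG trains; at most two artifact lines; no iterative or
compressed-sensing reconstruction; no B1 transmit correction of
concentration maps; NIfTI output stores magnitude only. The weighted
relaxometry path expects the caller to supply weights (for instance
inverse noise sds); it does not estimate heteroscedastic noise itself.
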