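# f19mr — fluorine-19 MR drug imaging analysis

`f19mr` is an R toolbox for detecting and quantifying fluorinated drugs by
¹⁹F magnetic resonance. Fluorine has essentially no endogenous MR-visible
background in tissue, so a CF₃-bearing drug (for example an S1P-receptor
modulator taken by multiple-sclerosis patients) can be localized and
quantified without labels or ionizing radiation — at the price of very low
signal, short transverse relaxation times under protein binding, and
coil-intrinsic ¹⁹F contaminant signals. The package implements the full
analysis chain such studies need, plus the synthetic-data generators to
validate every stage without scanner data:

* **Spectroscopy** — FID preprocessing (digital-filter delay removal,
  truncation, zero-padding), complex Voigt line-shape fitting with
  Weideman's rational approximation of the Faddeeva function
  `w(z) = exp(-z²) erfc(-iz)`, phasing, and pSNR/ANR sensitivity metrics.
* **Artifact subtraction** — characterization of the cryoprobe's two
  contaminant lines (≈ −83 and −147 ppm) from empty-coil control spectra
  via the coupled model
  `L(f) = a e^{-iφf}(r e^{-ip} V(f;v₁,w₁,m₁) + (1-r) e^{-iq} V(f;v₂,w₂,m₂))`,
  then Bayesian-prior-constrained three-peak fitting of tissue spectra with
  a 250 Hz drift allowance on the line centres, and subtraction of the
  artifact component only — unmodelled metabolite resonances survive.
* **Relaxometry** — saturation-recovery T1, mono/bi-exponential T2/T2*
  fits with the linearized covariance `V_p = σ_r²(JᵀJ)⁻¹`, likelihood-ratio
  model selection `Λ = n log(RSS₀/RSS₁)` against χ²₂, and apparent
  relaxation times: the root of
  `β e^{-t/T2a} + (1-β) e^{-t/T2b} = 1/e`, deterministically and by
  Monte-Carlo propagation of the fit covariance (5·10⁴ draws).
* **Radial UTE imaging** — golden-angle radial trajectories, analytic
  ellipsoid k-space simulation with per-sample T2* decay and off-resonance,
  the delay-dependent correction factor `exp(2πi (TE+(j-1)t_d) Δf)`,
  adjoint NUFFT by Kaiser–Bessel gridding with analytic density
  compensation, noise prewhitening by Cholesky factorization, root-sum-of-
  squares combination, chi-corrected SNR maps, cluster-based thresholding,
  and concentration mapping against a reference phantom.
* **Protocol arithmetic** — Ernst angle, bSSFP optimal angle, RARE
  echo-train PSF/ETL selection, SNR efficiency, detection-limit and
  cross-species voxel scaling, dose-proportional concentration estimates.

## Worked example: apparent T2 in serum at body temperature

```r
library(f19mr)
te <- (1:32) * 3.2                       # CPMG echo times, ms
truth <- relax_params("bi_exp", amplitude = 1, beta = 0.405,
                      t2a = 8.0, t2b = 21.7)   # serum, 37 C
series <- simulate_relaxation_series("echo_decay", truth, te,
                                     noise_sd = 0.005, seed = 42)
fit_mono <- fit_decay(series$time, series$signal, "mono")
fit_bi <- fit_decay(series$time, series$signal, "bi")
print(fit_bi)
print(likelihood_ratio_test(fit_mono, fit_bi))
cat(sprintf("apparent T2: %.2f ms\n", apparent_t2(fit_bi)))
mc <- apparent_t2_mc(fit_bi, seed = 1)
cat(sprintf("Monte-Carlo apparent T2: %.2f +/- %.2f ms\n", mc$mean, mc$sd))
```

prints

```
<f19_fit>
  A          1.03132 +- 0.0243
  beta       0.302617 +- 0.0373
  T2a        5.71481 +- 1.1
  T2b        20.0339 +- 0.683
  n = 32, RSS = 0.0009755
<f19_lrt> Lambda = 48 (df = 2), p = 3.777e-11 -> bi-exponential
apparent T2: 14.23 ms
Monte-Carlo apparent T2: 14.27 +/- 0.45 ms
```

The likelihood-ratio test firmly rejects a single-exponential decay, and
the apparent T2 — the time at which the fitted decay reaches 1/e of its
initial value — summarizes the bi-exponential in one number (here 14.2 ms
from one noisy 32-echo series; the noiseless parameters give 14.65 ms).
The individual components are noisier than the apparent time, which is why
the apparent value is the quantity worth reporting.

End-to-end pipelines are `run_spectro_pipeline()` (FID → artifact-cleaned
pSNR/ANR report) and `run_imaging_pipeline()` (k-space → SNR map → mask →
concentration map, written as NIfTI). `inst/scripts/f19mr-cli.R` wraps the
main entry points for shell use. The methods vignette
(`vignettes/f19mr-methods.Rmd`) documents the models, conventions and
validation design.

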