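---
title: "RF-based ultrasound radiomics: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RF-based ultrasound radiomics: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the three RF-derived feature maps, the radiomics vector built on them, the
sparse-representation feature ranking, the SVM evaluation protocol, and the
speckle phantom simulator that stands in for clinical recordings. It also
records every numerical convention that the underlying method descriptions
leave open, and what the synthetic experiments do and do not demonstrate.

## Signals and maps

An RF frame is a matrix of axial fast-time samples by A-lines, sampled at
`fs` (default 32 MHz) with an assumed sound speed `c` (default 1540 m/s),
so one sample corresponds to `c/(2 fs)` ≈ 24 µm of depth. All map
estimators run on the RF inside the lesion ROI only, and a window
placement is valid only when the entire window configuration lies inside
the ROI mask — no padding, so no values are fabricated at lesion borders.

**DEA.** Two gated windows of `win_len = 64` samples, separated by a
`gap = 16` sample interval, slide down each A-line with unit step. The
average spectral energy of a block is the mean squared magnitude of its
DFT (by Parseval, `n·mean(x²)`; the spectral form is kept as the
definition). The estimate `10·log10(E0/E1)` is divided by
`win_len·c/fs/2` = 1.54 mm and assigned `(win_len+gap)/2 = 40` samples
below the upper window's start. Two conventions were open and are fixed
here: the "interval" between windows is read as the *gap* (so the two
windows span 64+16+64 = 144 samples — this makes the assignment point
`(length+interval)/2` land midway between the windows, which a
start-to-start reading would not), and the logarithm is base 10 (the 10·
prefactor is the dB convention). Note a structural property: the energy
ratio is measured across a window *separation* of 80 samples but
normalized by one window *length* of 64, so on a medium with true
amplitude attenuation α the estimator's asymptote is `1.25 α`. The
package keeps the printed formula as-is; parameter-recovery experiments
divide by 80/64 before comparing to the planted value.

**SSD.** Same sliding scheme with `gap = 40` (span 168, assignment offset
52). The two blocks' *magnitude* spectra are subtracted (the method
description does not say magnitude, power or complex; complex differences
would feed complex values into a real skewness, so magnitude is used) and
the population-moment skewness `m3/m2^{3/2}` of the 64-point difference is
the map value. A zero-variance difference (identical blocks) makes the
placement invalid rather than NaN.

**NRD.** A 37 × 8 block slides with unit step both axially and laterally
(the source describes only downward motion but wants a value at "each
point", so the lateral stride is also 1). The block input is the
analytic-signal envelope of the RF (the Rician has support x > 0; raw RF
is signed; `abs(RF)` is available as an option). The Rician density

$$f(x) = I_0\!\left(\frac{x s}{\sigma^2}\right)\frac{x}{\sigma^2}
  \exp\!\left(-\frac{x^2+s^2}{2\sigma^2}\right)$$

is fitted by maximum likelihood; the printed density in the source drops
the exponential factor, an evident typesetting loss, and the standard form
above is used. The fit maximizes the likelihood over `(s, log σ)` with
Nelder–Mead in compiled code; the likelihood is even in `s`, so the
optimizer roams the real line and `|s|` is reported. `log I0` uses the
Abramowitz–Stegun rational approximations (|error| < 2e-7). Two moment
starts (diffuse and coherent) are tried and the better is polished. The
fit agrees with `fitdistrplus::fitdist` to ~4 decimals on shared data;
that package is the independent oracle in the tests, never the
implementation.

A caveat with scientific content: at the Rayleigh boundary `s = 0` the
likelihood is flat in `s²`, so for *exactly* Rayleigh data the MLE of `s`
has `n^{-1/4}`-scale spread rather than concentrating at 0. Simulated
phantom speckle (finite scatterer density, ~6 scatterers per resolution
cell) is slightly sub-Rayleigh and pins `s` to ≈ 0 robustly, which is why
the speckle-only phantom checks are tight while an iid-Rayleigh check
would not be.

## Radiomics features

Per map and per wavelet subband, exactly 69 features: 16 histogram
(population moments, `m4/m2²` kurtosis, energy, RMS, entropy and
uniformity on an equal-width `Ng`-bin histogram, MAD, 10th/90th
percentiles), 13 Haralick GLCM features (symmetric distance-1 matrices in
4 directions, restricted to valid-valid pairs, averaged over directions;
log base 2), 22 GLRLM features (11 base features summarized by mean and
range over 4 directions), 13 GLSZM features (zones are 8-connected
equal-level components), and the 5 Amadasun–King NGTDM features (3 × 3
neighbourhood; flat-region coarseness capped at 1e6). Quantization is
equal-width over the valid values' range with `Ng = 64` by default, which
makes every matrix-family feature exactly invariant to affine rescaling of
the map. Constant regions short-circuit to defined degenerate values (ASM
1, contrast 0, entropy 0, …) with a warning instead of aborting a cohort.

The wavelet decomposition is one separable 2-D analysis level (Haar by
default, db2 available), applied to the bounding-box crop of the valid
region with invalid cells filled from their nearest valid neighbour; each
subband carries a 2×-downsampled validity mask. 69 × 4 subbands = 276
wavelet features, 345 per map, concatenated in the fixed order DEA, SSD,
NRD for 1035 in the three-map model. The individual feature identities
are classical choices matching the published per-family counts; the counts
are the conformance target.

## Feature ranking and classification

Features are z-scored (sample sd; zero-variance features become dead
atoms), unit-normalized, and used as dictionary atoms. OMP greedily
approximates the ±1 label vector: select the atom with maximal
|⟨residual, atom⟩| (ties to the lowest index), least-squares refit on the
active set, update the residual. Beyond the usual caps (`max_atoms` =
number of patients, residual norm ≤ 1e-6), the ranking entry point stops
when the best residual correlation falls below the universal threshold
`sqrt(2 log p / n)·‖r‖` — the expected maximum of p noise correlations.
Without that stop, OMP on n = 40 patients runs to zero residual and pads
the support with noise atoms that would outrank genuinely informative but
redundant features; with it, a planted design (3 informative features
among 100) puts all three in the top ranks in ≥ 18/20 seeds. Features
outside the support are ranked after it by absolute target correlation, so
classifier sweeps can extend past the support.

The classifier is libsvm's C-SVC with RBF kernel, `C = 0.8`, `γ = 1`.
Inside each LOOCV fold the training rows are rescaled feature-wise to
[0, 1] and the held-out row mapped with the training fold's scaling —
the scaling libsvm's own tooling recommends. A per-fold z-score was
rejected for a concrete numerical reason: standardized squared distances
grow like 2k for k features, so at `γ = 1` every held-out kernel value
underflows and all LOOCV scores collapse to the intercept, which tracks
the fold's majority class and *inverts* the AUC. Metrics: threshold-0
ACC/SENS/SPEC (label 1 positive), Mann–Whitney AUC with a stratified
bootstrap 95% CI (2000 resamples), precision–recall curve with the
break-even point interpolated at the precision = recall crossing, and a
two-group ANOVA (with two groups, exactly t²) plus Tukey HSD on the
radiomics scores. The best k in a sweep maximizes AUC, ties broken by
ACC then smaller k.

## The phantom simulator

Each A-line is a sparse train of Gaussian-amplitude scatterers (density
0.1 per sample) convolved with a Gaussian-envelope pulse at 3.5 MHz
(fractional −6 dB bandwidth 0.6, inside a 1–5 MHz curved-array band),
multiplied by the depth decay `10^{-α f z/20}` with α in dB/(m·MHz), plus
an optional coherent carrier of amplitude `coherent_amp` inside the
elliptical lesion. There is no lateral point-spread function, no spectral
downshift with depth, no motion and no scan-conversion physics: the
simulator produces exactly the statistical structure the three estimators
measure (energy decay, spectral fluctuation, Rayleigh→Rician envelope),
so passing tests demonstrate estimator correctness and pipeline behaviour,
not clinical performance. Cohorts default to 20 phantoms per class — the
scale of a small single-center study — with moderate planted deltas
(attenuation 50 vs 53 dB/(m·MHz), coherent amplitude 0 vs 0.25) chosen
once so that the single-map model sits in a realistic 0.8–0.9 AUC band
instead of at ceiling; per-patient seeds are `base_seed + i`, making every
cohort bit-reproducible.

Desk-scale problem sizes used by the tests and the acceptance script:
property tests run phantoms of 256–640 axial samples; attenuation-recovery
experiments use 1200 × 64 frames (per-placement DEA speckle noise is
~3 × 10³ dB/m, so hundreds of independent A-line placements are needed per
estimate); end-to-end cohort experiments use 40 phantoms of 320 × 14 with
`Ng = 16` and k = 10 features, and 20 replicate cohorts for the map-count
trend.

## Known limitations

* **Selection bias of the global ranking.** The feature ranking is
  computed once on the full cohort, as in the original workflow; only the
  SVM scaling and training are fold-internal. With p = 345 features and
  n = 40 patients this leaks label information: zero-delta (null) cohorts
  score LOOCV AUC ≈ 0.75 rather than 0.5, at any k from 3 to 20. The
  package therefore also provides `loocv_scores(refit_ranking = TRUE)`,
  which re-ranks inside every fold and restores the null to AUC ≈ 0.50;
  the acceptance script reports both numbers. Absolute performance figures
  from the global-ranking protocol should be read as optimistic; *between*
  variant comparisons (all equally leaky) remain informative, and the
  DSNM ≥ DM trend holds in 20/20 replicate cohorts.
* **DEA scale and noise.** The estimator's asymptote is 1.25× the true
  attenuation (separation 80 vs normalization 64), and its per-placement
  variance on speckle is enormous; single small maps are class features,
  not attenuation measurements.
* **Rician boundary.** Near `s = 0` the noncentrality MLE is ill
  conditioned (flat ridge in s²); NRD values well below the map's σ̂ scale
  should be read as "no detectable coherent component", not as precise
  estimates. Planted coherent amplitudes are recovered within ~20% only
  when `s/σ` is comfortably above 1.
* **GM on phantoms is not a grayscale-vs-RF verdict.** The grayscale
  variant reconstructs B-mode from the same simulated RF (clinical
  workflows use separately saved scanner images). Log compression with
  per-frame max normalization preserves a planted attenuation contrast
  almost losslessly, so on simple phantoms GM can classify as well as the
  RF variants — unlike clinical grayscale, which is post-processed by the
  scanner. Only the RF-map variants' relative ordering is a meaningful
  synthetic readout.
* **Quantization and wavelet identities.** `Ng`, the wavelet family, and
  the exact 69-feature identities are package conventions that reproduce
  the published counts; other choices would change feature values (not
  counts) and, with them, selected-feature lists.
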