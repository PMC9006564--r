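# rfrad — radiomics on ultrasound radiofrequency multifeature maps

`rfrad` implements a quantitative-ultrasound radiomics workflow for binary
tissue classification from **raw RF echo frames** — the signal as it exists
before envelope detection and display processing, which still carries phase
and spectral content that B-mode images discard. The intended users are
ultrasound/QUS researchers who want to test whether parametric maps computed
from RF data classify lesions better than grayscale images, without access
to a clinical scanner: the package ships a speckle phantom simulator so the
entire chain runs on synthetic cohorts with known ground truth.

## The method

From the RF data inside a lesion ROI, three parametric **feature maps** are
computed with sliding gated windows:

* **DEA** (direct energy attenuation, dB/m). Two 64-sample gated windows,
  16 samples apart, slide down each A-line; at each placement

  `DEA = 10 log10(E0 / E1) / (D c / fs / 2)`,

  where `E0`, `E1` are the mean squared DFT magnitudes of the upper and
  lower window, `D = 64` samples, `c = 1540` m/s, `fs = 32` MHz (the
  denominator is 1.54 mm, one window's depth span).
* **SSD** (skewness of spectrum difference, dimensionless). Magnitude
  spectra of two 64-sample windows 40 samples apart are subtracted and the
  population-moment skewness `m3 / m2^(3/2)` of the difference is the map
  value.
* **NRD** (Rician noncentrality, amplitude units). A 37 × 8 block slides
  over the envelope; at each placement the Rician density
  `f(x) = I0(x s/σ²) (x/σ²) exp(−(x²+s²)/(2σ²))` is fitted by maximum
  likelihood and `s` — the coherent-scattering amplitude — is the map
  value. `s = 0` is the Rayleigh limit of fully developed speckle.

Each map (and its four single-level Haar wavelet subbands) yields **69
texture features** — 16 histogram, 13 GLCM (Haralick), 22 GLRLM
(11 base features × mean/range over 4 directions), 13 GLSZM, 5 NGTDM —
for **345 features per map** and **1035** for the three-map model.
Features are ranked by their **sparse representation coefficients**:
orthogonal matching pursuit solves `label ≈ Φ β` over the standardized
feature dictionary, and `|β|` orders the features. An RBF-kernel SVM
(`C = 0.8`, `γ = 1`, libsvm via e1071) is trained on the top-k features
under **leave-one-out cross-validation**; reported metrics are AUC (with
stratified-bootstrap CI), ACC/SENS/SPEC, the precision–recall break-even
point, and an ANOVA/Tukey comparison of the per-patient radiomics scores.

Four model variants mirror the comparison of interest: `GM` (grayscale
B-mode radiomics), `DM` (DEA only), `DSM` (DEA + SSD), `DSNM`
(DEA + SSD + NRD).

## Worked example

```r
library(rfrad)
set.seed(7)

# a phantom with 50 dB/(m·MHz) attenuation and a coherent lesion component
sim <- simulate_rf(phantom_spec(shape = c(1200L, 64L), attenuation = 50,
                                coherent_amp = 1.2, seed = 7,
                                lesion = list(center = c(0.5, 0.5),
                                              semi_axes = c(0.46, 0.49))))
cr  <- crop_roi(sim$frame$samples, sim$roi)
dea <- compute_dea_map(cr$values, cr$mask)
nrd <- compute_nrd_map(cr$values, cr$mask)
dea
#> <feature_map:DEA> 1105 x 63, 45418 valid cells [dB/m]
mean(dea$values[dea$valid]) * 64/80 / 3.5
#> [1] 54.6
```

The mean DEA, rescaled by the window/separation ratio 64/80 and divided by
the 3.5 MHz pulse frequency, recovers the planted attenuation
(54.6 vs 50 dB/(m·MHz)); `median(nrd$values[nrd$valid])` is 0.84 against a
planted coherent amplitude of 1.2 reduced by ~2 dB of depth attenuation.
`extract_map_features(dea)` then returns the 345-row feature tibble, and
the full cohort pipeline is one call:

```r
run <- run_pipeline(list(
  data = list(source = "synthetic", n_per_class = 6L, shape = c(320L, 14L)),
  variants = c("DM", "DSNM"), ng = 16L, k_max = 5L, n_boot = 200L, seed = 7))
run
#> <pipeline_run> 12 patients, config 159b1e29
#>   model n_features k auc auc_ci_lo auc_ci_hi    acc   sens spec bep   anova_p
#> 1    DM        345 3 100         1         1 100.00 100.00  100   1 3.825e-05
#> 2  DSNM       1035 5 100         1         1  91.67  83.33  100   1 1.947e-05
```

(a 12-phantom demo cohort with the default planted class effects is
trivially separable; the acceptance script below uses 40-phantom cohorts
with moderate effects, where the variants spread apart). `glance(run)`,
`tidy()` and `autoplot()` work on the run, the sweeps and the per-variant
reports; `inst/cli/rfrad` exposes the same stages as a command-line tool.

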