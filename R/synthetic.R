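#' Phantom specification
#'
#' Parameters of one simulated RF frame. The simulator draws sparse random
#' scatterers along each A-line, convolves them with a Gaussian-envelope
#' pulse, applies depth-dependent attenuation at the pulse centre
#' frequency, and optionally adds a coherent (specular) component inside
#' the lesion, which drives the envelope from Rayleigh towards Rician
#' statistics.
#'
#' Defaults emulate an abdominal acquisition at desk scale: a 3.5 MHz
#' pulse (inside a 1-5 MHz curved-array band) sampled at 32 MHz, soft
#' tissue attenuation 50 dB/(m*MHz) (0.5 dB/(cm*MHz)), and an elliptical
#' lesion ROI large enough for all three map window schemes.
#'
#' @param shape Frame size `(axial samples, A-lines)` (default 640 x 24).
#' @param fs Sampling rate, Hz.
#' @param c Sound speed, m/s.
#' @param pulse_center Pulse centre frequency, Hz (default 3.5 MHz).
#' @param pulse_bandwidth Fractional -6 dB bandwidth (default 0.6).
#' @param attenuation Amplitude attenuation, dB/(m*MHz) (default 50).
#' @param scatterer_density Expected scatterers per axial sample (default 0.1).
#' @param scatterer_sigma Scatterer amplitude scale (default 1).
#' @param coherent_amp Amplitude of the coherent component added inside the
#'   lesion (default 0 = fully developed speckle).
#' @param lesion List: `center` (row/col fractions of the frame) and
#'   `semi_axes` (fractions of the frame extent) of the elliptical ROI.
#' @param seed RNG seed for this frame.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(640L, 24L), fs = 3.2e7, c = 1540,
                         pulse_center = 3.5e6, pulse_bandwidth = 0.6,
                         attenuation = 50, scatterer_density = 0.1,
                         scatterer_sigma = 1, coherent_amp = 0,
                         lesion = list(center = c(0.5, 0.5), semi_axes = c(0.42, 0.48)),
                         seed = 1L) {
  stopifnot(length(shape) == 2L, shape[1] >= 200L, attenuation >= 0,
            scatterer_density > 0, fs > 0, c > 0, coherent_amp >= 0)
  structure(list(shape = as.integer(shape), fs = fs, c = c,
                 pulse_center = pulse_center, pulse_bandwidth = pulse_bandwidth,
                 attenuation = attenuation, scatterer_density = scatterer_density,
                 scatterer_sigma = scatterer_sigma, coherent_amp = coherent_amp,
                 lesion = lesion, seed = as.integer(seed)),
            class = "phantom_spec")
}

gaussian_pulse <- function(fs, f0, frac_bw) {
  # -6 dB fractional bandwidth of the Gaussian spectral envelope
  sigma_f <- frac_bw * f0 / (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- ceiling(3 * sigma_t * fs)
  t <- (-half:half) / fs
  exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * f0 * t)
}

lesion_mask <- function(shape, lesion) {
  H <- shape[1]; W <- shape[2]
  cr <- lesion$center[1] * H; cc <- lesion$center[2] * W
  ar <- lesion$semi_axes[1] * H; ac <- lesion$semi_axes[2] * W
  r <- row(matrix(0, H, W)); cl <- col(matrix(0, H, W))
  ((r - cr) / ar)^2 + ((cl - cc) / ac)^2 <= 1
}

#' Simulate one RF phantom frame
#'
#' Per A-line: sparse Gaussian-amplitude scatterers convolved with the
#' pulse, times the depth attenuation profile
#' `10^(-attenuation * f0[MHz] * z / 20)` with `z = row * c / (2 fs)`
#' metres; inside the lesion a coherent carrier of amplitude
#' `coherent_amp` (also attenuated) is added. Deterministic for a fixed
#' `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return List with `frame` ([rf_frame()]), `roi` ([roi_mask()]) and
#'   `spec`.
#' @export
simulate_rf <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$shape[1]; W <- spec$shape[2]
  pulse <- gaussian_pulse(spec$fs, spec$pulse_center, spec$pulse_bandwidth)
  half <- (length(pulse) - 1L) %/% 2L
  z <- (seq_len(H) - 1L) * spec$c / (2 * spec$fs)
  decay <- 10^(-spec$attenuation * (spec$pulse_center / 1e6) * z / 20)
  roi <- lesion_mask(spec$shape, spec$lesion)
  withr::with_seed(spec$seed, {
    rf <- matrix(0, H, W)
    t_idx <- seq_len(H)
    for (j in seq_len(W)) {
      hit <- stats::runif(H) < spec$scatterer_density
      amp <- numeric(H)
      amp[hit] <- stats::rnorm(sum(hit), sd = spec$scatterer_sigma)
      line <- stats::convolve(amp, rev(pulse), type = "open")
      line <- line[(half + 1L):(half + H)]
      if (spec$coherent_amp > 0 && any(roi[, j])) {
        carrier <- spec$coherent_amp * cos(2 * pi * spec$pulse_center * (t_idx - 1L) / spec$fs)
        line <- line + ifelse(roi[, j], carrier, 0)
      }
      rf[, j] <- line * decay
    }
    list(frame = rf_frame(rf, fs = spec$fs, c = spec$c), roi = roi_mask(roi),
         spec = spec)
  })
}

#' Cohort specification
#'
#' A two-class cohort: `n_per_class` phantoms per label, with selected
#' [phantom_spec()] fields taking class-specific values. The default
#' deltas plant a moderate class difference in both depth attenuation
#' (50 vs 53 dB/(m*MHz), a 6% shift) and coherent amplitude (0 vs 0.25) —
#' one effect visible to the DEA map and one to the NRD map, each weak
#' enough that single-map classifiers stay well below perfect separation.
#'
#' @param n_per_class Phantoms per class (default 20, a 40-patient cohort).
#' @param class_deltas Named list; each element is a length-2 vector
#'   `(class 0 value, class 1 value)` for a `phantom_spec` field.
#' @param base_seed Seed; patient `i` uses `base_seed + i`.
#' @param ... Overrides for the shared [phantom_spec()] fields.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = 20L,
                        class_deltas = list(attenuation = c(50, 53),
                                            coherent_amp = c(0, 0.25)),
                        base_seed = 1L, ...) {
  stopifnot(n_per_class >= 3L, length(class_deltas) >= 1L)
  structure(list(n_per_class = as.integer(n_per_class),
                 class_deltas = class_deltas,
                 base_seed = as.integer(base_seed),
                 base_args = list(...)),
            class = "cohort_spec")
}

#' Simulate a labelled cohort of RF phantoms
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with one row per phantom: `patient_id`, `label`, `seed`
#'   and list-columns `frame`, `roi`. Reproducible for a fixed spec.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- 2L * spec$n_per_class
  labels <- rep(c(0L, 1L), each = spec$n_per_class)
  rows <- purrr::map(seq_len(n), function(i) {
    args <- spec$base_args
    for (nm in names(spec$class_deltas)) {
      args[[nm]] <- spec$class_deltas[[nm]][labels[i] + 1L]
    }
    args$seed <- spec$base_seed + i
    sim <- simulate_rf(do.call(phantom_spec, args))
    tibble::tibble(patient_id = sprintf("P%03d", i), label = labels[i],
                   seed = args$seed, frame = list(sim$frame), roi = list(sim$roi))
  })
  dplyr::bind_rows(rows)
}

#' Write a simulated cohort to disk
#'
#' One HDF5 RF container per phantom plus a `manifest.csv`
#' (`patient_id`, `path`, `label`).
#'
#' @param cohort A [simulate_cohort()] tibble.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map_chr(seq_len(nrow(cohort)), function(i) {
    p <- file.path(dir, paste0(cohort$patient_id[i], ".h5"))
    write_rf_frame(cohort$frame[[i]], p, roi = cohort$roi[[i]])
    p
  })
  manifest <- tibble::tibble(patient_id = cohort$patient_id, path = paths,
                             label = cohort$label)
  mp <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, mp)
  invisible(mp)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest_path Path to `manifest.csv`.
#' @return Tibble in the [simulate_cohort()] layout.
#' @export
read_cohort <- function(manifest_path) {
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
  base <- dirname(manifest_path)
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(base, basename(p))
    fr <- read_rf_frame(p)
    tibble::tibble(patient_id = as.character(manifest$patient_id[i]),
                   label = as.integer(manifest$label[i]),
                   seed = NA_integer_, frame = list(fr$frame), roi = list(fr$roi))
  })
  dplyr::bind_rows(rows)
}
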