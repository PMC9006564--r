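#' Ultrasound feature maps
#'
#' A `feature_map` holds one parametric image computed from ROI RF data by a
#' sliding gated-window estimator, together with a validity mask: a cell is
#' valid only where the full window configuration fit inside the ROI (no
#' padding, so no values are fabricated at the lesion border).
#'
#' Kinds and units:
#' * `DEA` — direct energy attenuation, dB/m. Ratio of the average spectral
#'   energies of two axial gated windows, converted to decay per metre of
#'   depth travelled.
#' * `SSD` — skewness of spectrum difference, dimensionless.
#' * `NRD` — noncentrality parameter s of a Rician fit to the envelope,
#'   amplitude units. Indexes coherent-to-diffuse scattering.
#' * `GRAYSCALE` — B-mode pixel values in `[0, 1]` (comparison variant).
#'
#' @param values Numeric matrix; finite wherever `valid`.
#' @param valid Logical matrix congruent with `values`.
#' @param kind One of `"DEA"`, `"SSD"`, `"NRD"`, `"GRAYSCALE"`.
#' @param units Unit string.
#' @param params Named list of the window parameters that produced the map.
#' @return An object of class `feature_map`.
#' @export
feature_map <- function(values, valid, kind, units = "", params = list()) {
  kind <- match.arg(kind, c("DEA", "SSD", "NRD", "GRAYSCALE"))
  values <- as.matrix(values); valid <- as.matrix(valid)
  stopifnot(identical(dim(values), dim(valid)), is.logical(valid))
  if (any(valid & !is.finite(values))) {
    stop("feature_map: non-finite values flagged valid", call. = FALSE)
  }
  structure(list(values = values, valid = valid, kind = kind,
                 units = units, params = params),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map:%s> %d x %d, %d valid cells%s\n",
              x$kind, nrow(x$values), ncol(x$values), sum(x$valid),
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' Map-value tibble
#'
#' @param x A [feature_map()].
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `value` for valid cells.
#' @exportS3Method generics::tidy
tidy.feature_map <- function(x, ...) {
  idx <- which(x$valid, arr.ind = TRUE)
  tibble::tibble(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]),
                 value = x$values[idx], kind = x$kind)
}

#' @exportS3Method ggplot2::autoplot
autoplot.feature_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = object$units) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste(object$kind, "feature map"), x = "A-line", y = "axial sample") +
    ggplot2::theme_minimal()
}

#' Average spectral energy of a gated RF block
#'
#' Mean squared magnitude of the block's discrete Fourier transform. By
#' Parseval's identity this equals `length(block) * mean(block^2)`, but the
#' spectral form is kept as the definition.
#'
#' @param block Numeric vector, length >= 2.
#' @return Non-negative scalar.
#' @export
block_energy <- function(block) {
  if (length(block) < 2L) stop("`block` must have length >= 2", call. = FALSE)
  mean(Mod(stats::fft(block))^2)
}

#' Sample skewness (population-moment form)
#'
#' Third central moment over the 3/2 power of the second, both with `1/n`
#' normalization. Returns `NaN` for zero-variance input.
#'
#' @param x Numeric vector, length >= 2.
#' @return Dimensionless scalar (or `NaN`).
#' @export
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 2L) stop("`x` must have length >= 2", call. = FALSE)
  cx <- x - mean(x)
  m2 <- mean(cx^2)
  if (m2 == 0) return(NaN)
  mean(cx^3) / m2^1.5
}

# Resolve (matrix | rf_frame) + optional mask into a values/mask pair.
resolve_roi <- function(x, mask) {
  m <- if (inherits(x, "rf_frame")) x$samples else as.matrix(x)
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(m), ncol(m))
  } else {
    mask <- as.matrix(mask)
    if (is.numeric(mask)) mask <- mask != 0
    check_congruent(dim(m), mask)
  }
  list(values = m, mask = unclass(mask))
}

# columns of sliding windows: out[, k] = v[starts[k] + (0:(len-1))]
sliding_windows <- function(v, starts, len) {
  idx <- outer(0:(len - 1L), starts, `+`)
  matrix(v[idx], nrow = len)
}

#' Direct energy attenuation (DEA) map
#'
#' Two axial gated windows of `win_len` samples separated by a `gap` slide
#' down each A-line one sample at a time. At each placement the ratio of
#' their average spectral energies is converted to an attenuation rate
#'
#'   `DEA = 10 * log10(E0 / E1) / (win_len * c / fs / 2)`   (dB/m),
#'
#' where the denominator is the depth distance spanned by one window
#' (1.54e-3 m at the defaults 64 samples, 1540 m/s, 32 MHz). The value is
#' assigned `(win_len + gap) / 2` samples below the upper window's start.
#'
#' @param x ROI RF data: numeric matrix or [rf_frame()].
#' @param mask Optional logical matrix gating valid placements (default all).
#' @param win_len Gated window length in samples (default 64).
#' @param gap Samples between the two windows (default 16).
#' @param c Sound speed in m/s (default 1540).
#' @param fs Sampling rate in Hz (default 32 MHz).
#' @return A [feature_map()] of kind `"DEA"`.
#' @export
compute_dea_map <- function(x, mask = NULL, win_len = 64L, gap = 16L,
                            c = 1540, fs = 3.2e7) {
  rr <- resolve_roi(x, mask)
  v <- rr$values; msk <- rr$mask
  span <- 2L * win_len + gap
  H <- nrow(v); W <- ncol(v)
  if (H < span) stop(sprintf("ROI too small: need >= %d rows, got %d", span, H), call. = FALSE)
  depth_m <- win_len * c / fs / 2
  offset <- (win_len + gap) %/% 2L
  vals <- matrix(NA_real_, H, W); valid <- matrix(FALSE, H, W)
  starts <- seq_len(H - span + 1L)
  for (j in seq_len(W)) {
    col_ok <- vapply(starts, function(i) all(msk[i:(i + span - 1L), j]), logical(1))
    if (!any(col_ok)) next
    st <- starts[col_ok]
    E0 <- colMeans(Mod(stats::mvfft(sliding_windows(v[, j], st, win_len)))^2)
    E1 <- colMeans(Mod(stats::mvfft(sliding_windows(v[, j], st + win_len + gap, win_len)))^2)
    ok <- E0 > 0 & E1 > 0
    vals[st[ok] + offset, j] <- 10 * log10(E0[ok] / E1[ok]) / depth_m
    valid[st[ok] + offset, j] <- TRUE
  }
  feature_map(vals, valid, "DEA", units = "dB/m",
              params = list(win_len = win_len, gap = gap, c = c, fs = fs))
}

#' Skewness of spectrum difference (SSD) map
#'
#' At each axial placement the magnitude spectra of two gated windows
#' (`win_len` samples each, `gap` samples apart) are subtracted elementwise
#' (upper minus lower) and the sample skewness of the difference vector is
#' the map value, assigned `(win_len + gap) / 2` samples below the upper
#' window's start. Zero-variance differences (e.g. identical blocks) make
#' the placement invalid.
#'
#' @inheritParams compute_dea_map
#' @param gap Samples between the two windows (default 40).
#' @return A [feature_map()] of kind `"SSD"`.
#' @export
compute_ssd_map <- function(x, mask = NULL, win_len = 64L, gap = 40L) {
  rr <- resolve_roi(x, mask)
  v <- rr$values; msk <- rr$mask
  span <- 2L * win_len + gap
  H <- nrow(v); W <- ncol(v)
  if (H < span) stop(sprintf("ROI too small: need >= %d rows, got %d", span, H), call. = FALSE)
  offset <- (win_len + gap) %/% 2L
  vals <- matrix(NA_real_, H, W); valid <- matrix(FALSE, H, W)
  starts <- seq_len(H - span + 1L)
  for (j in seq_len(W)) {
    col_ok <- vapply(starts, function(i) all(msk[i:(i + span - 1L), j]), logical(1))
    if (!any(col_ok)) next
    st <- starts[col_ok]
    S0 <- Mod(stats::mvfft(sliding_windows(v[, j], st, win_len)))
    S1 <- Mod(stats::mvfft(sliding_windows(v[, j], st + win_len + gap, win_len)))
    D <- S0 - S1
    Dc <- sweep(D, 2L, colMeans(D))
    m2 <- colMeans(Dc^2); m3 <- colMeans(Dc^3)
    ok <- m2 > 0
    vals[st[ok] + offset, j] <- m3[ok] / m2[ok]^1.5
    valid[st[ok] + offset, j] <- TRUE
  }
  feature_map(vals, valid, "SSD", units = "",
              params = list(win_len = win_len, gap = gap))
}

#' Maximum-likelihood Rician fit
#'
#' Fits the Rician density
#' `f(x) = I0(x s / sigma^2) * (x / sigma^2) * exp(-(x^2 + s^2) / (2 sigma^2))`
#' (`I0` the zero-order modified Bessel function of the first kind) to
#' positive samples by numerical likelihood maximization (Nelder-Mead on
#' `(s, log sigma)` with moment-based starts). At `s = 0` the Rician reduces
#' to the Rayleigh distribution of fully developed speckle.
#'
#' @param x Positive numeric vector, length >= 8.
#' @return List with `s` (noncentrality, >= 0), `sigma` (scale), `loglik`
#'   and `converged`.
#' @seealso [drice()] for the density, [compute_nrd_map()] for the sliding
#'   map built on this fit.
#' @export
fit_rician <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 8L) stop("need at least 8 samples", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("Rician support is x > 0: all samples must be positive and finite", call. = FALSE)
  }
  fit <- rician_mle_cpp(x)
  if (!isTRUE(fit$converged)) {
    stop(sprintf("Rician MLE did not converge (last s = %.3g, sigma = %.3g)",
                 fit$s, fit$sigma), call. = FALSE)
  }
  fit
}

#' Rician density, distribution and random generation
#'
#' @param x,n Sample values (positive) / number of draws.
#' @param s Noncentrality parameter, >= 0.
#' @param sigma Scale parameter, > 0.
#' @param log Return log-density?
#' @return `drice`: (log-)density values; `rrice`: `n` random deviates
#'   (magnitude of a bivariate normal offset by `s`).
#' @export
drice <- function(x, s, sigma, log = FALSE) {
  sig2 <- sigma^2
  z <- x * s / sig2
  ld <- ifelse(x > 0,
               log(besselI(z, 0, expon.scaled = TRUE)) + z +
                 log(x) - log(sig2) - (x^2 + s^2) / (2 * sig2),
               -Inf)
  if (log) ld else exp(ld)
}

#' @rdname drice
#' @export
rrice <- function(n, s, sigma) {
  sqrt((s + stats::rnorm(n, sd = sigma))^2 + stats::rnorm(n, sd = sigma)^2)
}

#' Rician noncentrality (NRD) map
#'
#' A 2-D block (default 37 x 8 samples, i.e. 296 envelope values) slides
#' over the ROI with unit step in both directions. Wherever the block lies
#' fully inside the ROI, a Rician distribution is fitted to the envelope
#' values by maximum likelihood and the noncentrality parameter s is
#' assigned to the block midpoint. Blocks whose fit fails are left invalid.
#'
#' @param x ROI RF data (matrix or [rf_frame()]); transformed per
#'   `input_transform` before fitting. Pass `input_transform = "none"` if
#'   `x` is already an envelope image.
#' @param mask Optional logical gating mask.
#' @param block_rows,block_cols Block extent in samples (default 37 x 8).
#' @param input_transform `"envelope"` (analytic-signal magnitude, default),
#'   `"abs"` (rectified RF), or `"none"`.
#' @return A [feature_map()] of kind `"NRD"`.
#' @export
compute_nrd_map <- function(x, mask = NULL, block_rows = 37L, block_cols = 8L,
                            input_transform = c("envelope", "abs", "none")) {
  input_transform <- match.arg(input_transform)
  rr <- resolve_roi(x, mask)
  v <- rr$values; msk <- rr$mask
  if (nrow(v) < block_rows || ncol(v) < block_cols) {
    stop(sprintf("ROI too small: need >= %d x %d, got %d x %d",
                 block_rows, block_cols, nrow(v), ncol(v)), call. = FALSE)
  }
  env <- switch(input_transform,
                envelope = envelope(v),
                abs = abs(v),
                none = v)
  res <- rician_map_cpp(env, msk, as.integer(block_rows), as.integer(block_cols))
  feature_map(res$values, res$valid, "NRD", units = "amplitude",
              params = list(block_rows = block_rows, block_cols = block_cols,
                            input_transform = input_transform,
                            sigma = res$sigma))
}

#' Grayscale feature map from a B-mode ROI
#'
#' Wraps a B-mode pixel crop as a `feature_map` so the same radiomics
#' extraction runs on display-processed images (the grayscale comparison
#' variant).
#'
#' @param pixels Matrix in `[0, 1]` (e.g. a [reconstruct_bmode()] crop).
#' @param mask Optional logical validity mask.
#' @return A [feature_map()] of kind `"GRAYSCALE"`.
#' @export
grayscale_map <- function(pixels, mask = NULL) {
  pixels <- as.matrix(pixels)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  feature_map(pixels, as.matrix(mask), "GRAYSCALE", units = "intensity")
}

#' Persist / load feature maps (HDF5)
#'
#' One group per map kind holding `values` (float64, NaN outside validity),
#' `valid` (uint8) and the window parameters as attributes.
#'
#' @param maps Named list of [feature_map()] objects.
#' @param path HDF5 file path.
#' @return `path` (write) or the list of maps (read), invisibly for write.
#' @export
write_feature_maps <- function(maps, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  for (m in maps) {
    g <- m$kind
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(m$values, path, paste0(g, "/values"))
    rhdf5::h5write(matrix(as.integer(m$valid), nrow(m$valid)), path, paste0(g, "/valid"))
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, g)
    rhdf5::h5writeAttribute(m$units, gid, "units")
    rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_feature_maps
#' @export
read_feature_maps <- function(path) {
  contents <- rhdf5::h5ls(path)
  kinds <- contents$name[contents$group == "/" & contents$otype == "H5I_GROUP"]
  maps <- lapply(kinds, function(g) {
    vals <- rhdf5::h5read(path, paste0(g, "/values"))
    valid <- rhdf5::h5read(path, paste0(g, "/valid")) != 0
    units <- tryCatch(as.character(rhdf5::h5readAttributes(path, g)$units),
                      error = function(e) "")
    feature_map(vals, valid, g, units = units)
  })
  rhdf5::h5closeAll()
  stats::setNames(maps, kinds)
}
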