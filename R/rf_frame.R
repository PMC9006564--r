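#' RF frame objects
#'
#' An `rf_frame` wraps one 2-D block of raw ultrasound radiofrequency (RF)
#' samples: rows are axial fast-time samples, columns are A-lines (one
#' transmit/receive event each). Amplitudes are in arbitrary linear units and
#' keep their sign — envelope detection comes later.
#'
#' @param samples Numeric matrix, axial samples x A-lines. At least 2 rows
#'   and 1 column; all finite.
#' @param fs Sampling rate in Hz (default 32 MHz).
#' @param c Assumed speed of sound in m/s (default 1540, soft tissue).
#' @param geometry `"linear"` or `"sector"`. Sector frames additionally carry
#'   `probe_radius` (m) and `angular_pitch` (rad) used during scan conversion.
#' @param probe_radius,angular_pitch Sector geometry parameters; ignored for
#'   linear frames.
#' @return An object of class `rf_frame`.
#' @examples
#' fr <- rf_frame(matrix(rnorm(512), 256, 2))
#' dim(fr$samples)
#' @export
rf_frame <- function(samples, fs = 3.2e7, c = 1540, geometry = c("linear", "sector"),
                     probe_radius = NULL, angular_pitch = NULL) {
  geometry <- match.arg(geometry)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 2L || ncol(samples) < 1L) {
    stop("`samples` must have at least 2 rows and 1 column", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("`samples` must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("`fs` must be a positive scalar", call. = FALSE)
  if (!is.numeric(c) || length(c) != 1L || c <= 0) stop("`c` must be a positive scalar", call. = FALSE)
  if (geometry == "sector") {
    if (is.null(probe_radius) || is.null(angular_pitch)) {
      stop("sector geometry needs `probe_radius` and `angular_pitch`", call. = FALSE)
    }
  }
  structure(
    list(samples = samples, fs = fs, c = c, geometry = geometry,
         probe_radius = probe_radius, angular_pitch = angular_pitch),
    class = "rf_frame"
  )
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d axial samples x %d A-lines, fs = %.3g MHz, c = %g m/s, %s\n",
              nrow(x$samples), ncol(x$samples), x$fs / 1e6, x$c, x$geometry))
  invisible(x)
}

#' @export
dim.rf_frame <- function(x) dim(x$samples)

#' Region-of-interest mask
#'
#' A logical matrix congruent with an [rf_frame()]'s samples, `TRUE` inside
#' the delineated lesion. Every map and feature computation is gated on it.
#'
#' @param mask Logical (or 0/1) matrix; at least one `TRUE` cell.
#' @return Logical matrix of class `roi_mask`.
#' @export
roi_mask <- function(mask) {
  mask <- as.matrix(mask)
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.logical(mask)) stop("`mask` must be logical or 0/1", call. = FALSE)
  if (anyNA(mask)) stop("`mask` must not contain NA", call. = FALSE)
  if (!any(mask)) stop("`mask` must contain at least one TRUE cell", call. = FALSE)
  structure(mask, class = c("roi_mask", "matrix", "array"))
}

check_congruent <- function(frame_dim, mask) {
  if (!identical(as.integer(frame_dim), as.integer(dim(mask)))) {
    stop(sprintf("ROI mask shape (%d x %d) does not match frame (%d x %d)",
                 nrow(mask), ncol(mask), frame_dim[1], frame_dim[2]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write an RF frame (and optional ROI) to an HDF5 container
#'
#' Layout: dataset `/rf` (float64, axial x lateral) with attributes `fs`
#' (Hz), `c` (m/s) and `geometry`; optional dataset `/roi` (uint8 0/1) of
#' the same shape. [read_rf_frame()] round-trips samples bit-exactly.
#'
#' @param frame An [rf_frame()].
#' @param path Output file path (overwritten if present).
#' @param roi Optional [roi_mask()] congruent with the frame.
#' @return `path`, invisibly.
#' @export
write_rf_frame <- function(frame, path, roi = NULL) {
  stopifnot(inherits(frame, "rf_frame"))
  if (!is.null(roi)) check_congruent(dim(frame$samples), roi)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(frame$samples, path, "rf")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "rf")
  rhdf5::h5writeAttribute(frame$fs, did, "fs")
  rhdf5::h5writeAttribute(frame$c, did, "c")
  rhdf5::h5writeAttribute(frame$geometry, did, "geometry")
  if (frame$geometry == "sector") {
    rhdf5::h5writeAttribute(frame$probe_radius, did, "probe_radius")
    rhdf5::h5writeAttribute(frame$angular_pitch, did, "angular_pitch")
  }
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  if (!is.null(roi)) {
    rhdf5::h5write(matrix(as.integer(roi), nrow(roi), ncol(roi)), path, "roi")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read an RF frame from an HDF5 container
#'
#' @param path Path to a container written by [write_rf_frame()] (or any
#'   HDF5 file with the documented `/rf` layout).
#' @return A list with elements `frame` ([rf_frame()]) and `roi`
#'   ([roi_mask()] or `NULL` when the container has no `/roi` dataset).
#' @export
read_rf_frame <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  contents <- rhdf5::h5ls(path)
  if (!"rf" %in% contents$name) {
    stop("not an RF container: dataset '/rf' is missing in ", path, call. = FALSE)
  }
  samples <- rhdf5::h5read(path, "rf")
  at <- rhdf5::h5readAttributes(path, "rf")
  if (is.null(at$fs) || is.null(at$c)) {
    stop("RF container is missing the 'fs'/'c' attributes", call. = FALSE)
  }
  geometry <- if (is.null(at$geometry)) "linear" else as.character(at$geometry)
  frame <- rf_frame(samples, fs = as.numeric(at$fs), c = as.numeric(at$c),
                    geometry = geometry,
                    probe_radius = if (!is.null(at$probe_radius)) as.numeric(at$probe_radius),
                    angular_pitch = if (!is.null(at$angular_pitch)) as.numeric(at$angular_pitch))
  roi <- NULL
  if ("roi" %in% contents$name) {
    m <- rhdf5::h5read(path, "roi")
    check_congruent(dim(frame$samples), m)
    roi <- roi_mask(m != 0)
  }
  rhdf5::h5closeAll()
  list(frame = frame, roi = roi)
}

#' Envelope of the RF signal
#'
#' Magnitude of the per-A-line analytic signal (FFT-based Hilbert
#' transform). Under fully developed speckle the envelope is
#' Rayleigh-distributed; a coherent scattering component makes it Rician.
#'
#' @param x An [rf_frame()] or a numeric matrix (columns = A-lines).
#' @return Non-negative matrix of the same shape.
#' @export
envelope <- function(x) {
  m <- if (inherits(x, "rf_frame")) x$samples else as.matrix(x)
  n <- nrow(m)
  # analytic signal: zero out negative frequencies, double positive ones
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  analytic <- stats::mvfft(stats::mvfft(m) * h, inverse = TRUE) / n
  Mod(analytic)
}

# moving average of odd length with edge replication (unit DC gain everywhere)
moving_average <- function(v, len) {
  if (len <= 1L) return(v)
  half <- (len - 1L) %/% 2L
  padded <- c(rep(v[1L], half), v, rep(v[length(v)], half))
  as.numeric(stats::filter(padded, rep(1 / len, len), sides = 2L))[(half + 1L):(half + length(v))]
}

#' Reconstruct a B-mode image from an RF frame
#'
#' Display pipeline: per-A-line moving-average smoothing, envelope
#' detection, logarithmic compression `20*log10(env/max(env))`, clipping to
#' `[-dynamic_range_db, 0]`, affine mapping to `[0, 1]`, and nearest
#' neighbour polar-to-Cartesian scan conversion for sector frames (linear
#' frames keep their geometry).
#'
#' @param frame An [rf_frame()].
#' @param smooth_len Odd moving-average length in samples (default 5).
#' @param dynamic_range_db Displayed dynamic range in dB (default 60).
#' @return A `bmode_image`: list with `pixels` (matrix in `[0, 1]`),
#'   `dynamic_range_db` and `converted` (whether scan conversion ran).
#' @export
reconstruct_bmode <- function(frame, smooth_len = 5L, dynamic_range_db = 60) {
  stopifnot(inherits(frame, "rf_frame"))
  smooth_len <- as.integer(smooth_len)
  if (smooth_len < 1L || smooth_len %% 2L == 0L) {
    stop("`smooth_len` must be a positive odd integer", call. = FALSE)
  }
  if (dynamic_range_db <= 0) stop("`dynamic_range_db` must be > 0", call. = FALSE)
  sm <- apply(frame$samples, 2L, moving_average, len = smooth_len)
  env <- envelope(sm)
  peak <- max(env)
  if (peak <= 0) stop("all-zero frame: log compression is undefined", call. = FALSE)
  db <- 20 * log10(pmax(env / peak, 10^(-dynamic_range_db / 20 - 2)))
  db <- pmin(pmax(db, -dynamic_range_db), 0)
  px <- (db + dynamic_range_db) / dynamic_range_db
  converted <- FALSE
  if (frame$geometry == "sector") {
    px <- scan_convert(px, frame)
    converted <- TRUE
  }
  structure(list(pixels = px, dynamic_range_db = dynamic_range_db, converted = converted),
            class = "bmode_image")
}

# nearest-neighbour polar-to-Cartesian resampling on the axial pixel pitch
scan_convert <- function(px, frame) {
  H <- nrow(px); W <- ncol(px)
  dz <- frame$c / (2 * frame$fs)
  r0 <- frame$probe_radius
  r <- r0 + (seq_len(H) - 1L) * dz
  theta <- (seq_len(W) - (W + 1) / 2) * frame$angular_pitch
  xs <- outer(r, sin(theta)); ys <- outer(r, cos(theta))
  gx <- seq(min(xs), max(xs), by = dz)
  gy <- seq(min(ys), max(ys), by = dz)
  out <- matrix(0, length(gy), length(gx))
  gxm <- matrix(gx, length(gy), length(gx), byrow = TRUE)
  gym <- matrix(gy, length(gy), length(gx))
  rr <- sqrt(gxm^2 + gym^2)
  tt <- atan2(gxm, gym)
  ri <- round((rr - r0) / dz) + 1L
  ci <- round(tt / frame$angular_pitch + (W + 1) / 2)
  ok <- ri >= 1L & ri <= H & ci >= 1L & ci <= W
  out[ok] <- px[cbind(ri[ok], ci[ok])]
  out
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image> %d x %d, dynamic range %g dB%s\n",
              nrow(x$pixels), ncol(x$pixels), x$dynamic_range_db,
              if (x$converted) ", scan-converted" else ""))
  invisible(x)
}

#' Export a B-mode image as an 8-bit grayscale PNG
#'
#' @param bmode A [reconstruct_bmode()] result.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_bmode_png <- function(bmode, path) {
  stopifnot(inherits(bmode, "bmode_image"))
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export", call. = FALSE)
  }
  png::writePNG(bmode$pixels, path)
  invisible(path)
}

#' Crop an array to the bounding box of an ROI mask
#'
#' Values outside the mask but inside the bounding box are kept in the crop
#' and flagged `FALSE` in the returned mask, so downstream windows can be
#' gated on true ROI membership.
#'
#' @param array Numeric matrix congruent with `roi`.
#' @param roi An [roi_mask()].
#' @return List with `values` (the crop), `mask` (cropped logical mask) and
#'   `origin` (0-based `(row, col)` of the crop inside the frame).
#' @export
crop_roi <- function(array, roi) {
  array <- as.matrix(array)
  check_congruent(dim(array), roi)
  rows <- which(rowSums(roi) > 0)
  cols <- which(colSums(roi) > 0)
  rr <- range(rows); cc <- range(cols)
  list(values = array[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE],
       mask = unclass(roi)[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE],
       origin = c(rr[1] - 1L, cc[1] - 1L))
}
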