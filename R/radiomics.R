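#' Gray-level quantization of a feature map
#'
#' Equal-width binning of the valid values into `Ng` levels over
#' `[min, max]`; the maximum maps to level `Ng`. Equal-width binning is
#' invariant to affine rescaling `v -> a + b*v` (b > 0), which makes every
#' downstream texture matrix affine-invariant too.
#'
#' @param map A [feature_map()] or numeric matrix.
#' @param Ng Number of gray levels (default 64).
#' @param mask Optional logical mask when `map` is a plain matrix.
#' @return List of class `quantized_map`: `levels` (integer matrix, `NA`
#'   outside validity), `Ng`, `valid`, `bin_edges`.
#' @export
quantize <- function(map, Ng = 64L, mask = NULL) {
  if (inherits(map, "feature_map")) {
    values <- map$values; valid <- map$valid
  } else {
    values <- as.matrix(map)
    valid <- if (is.null(mask)) matrix(TRUE, nrow(values), ncol(values)) else as.matrix(mask)
  }
  Ng <- as.integer(Ng)
  if (Ng < 2L) stop("`Ng` must be >= 2", call. = FALSE)
  v <- values[valid]
  rng <- range(v)
  if (diff(rng) == 0) {
    stop("constant map: quantization is undefined; callers should short-circuit ",
         "texture features to their degenerate values", call. = FALSE)
  }
  lv <- pmin(floor((values - rng[1]) / diff(rng) * Ng) + 1L, Ng)
  lv[!valid] <- NA_integer_
  storage.mode(lv) <- "integer"
  structure(list(levels = lv, Ng = Ng, valid = valid,
                 bin_edges = seq(rng[1], rng[2], length.out = Ng + 1L)),
            class = "quantized_map")
}

# degenerate single-level quantization used for constant inputs
constant_quantization <- function(values, valid) {
  lv <- matrix(NA_integer_, nrow(values), ncol(values))
  lv[valid] <- 1L
  structure(list(levels = lv, Ng = 1L, valid = valid, bin_edges = range(values[valid])),
            class = "quantized_map")
}

xlogx <- function(p, base = 2) ifelse(p > 0, p * log(p, base = base), 0)

#' First-order (histogram) features
#'
#' The fixed 16-feature list: mean, median, minimum, maximum, range,
#' variance and standard deviation (population, `1/n`), skewness, kurtosis
#' (`m4/m2^2`, not excess), energy (sum of squares), root mean square,
#' entropy and uniformity on an `Ng`-bin equal-width histogram, mean
#' absolute deviation, and the 10th and 90th percentiles. Constant input
#' yields skewness and kurtosis 0 (sentinels), entropy 0, uniformity 1.
#'
#' @param map [feature_map()] or numeric matrix.
#' @param mask Optional logical mask for plain matrices.
#' @param Ng Histogram bins for entropy/uniformity (default 64).
#' @return Named numeric vector of length 16.
#' @export
histogram_features <- function(map, mask = NULL, Ng = 64L) {
  if (inherits(map, "feature_map")) { v <- map$values[map$valid] }
  else {
    m <- as.matrix(map)
    v <- if (is.null(mask)) as.numeric(m) else m[as.matrix(mask)]
  }
  n <- length(v)
  mu <- mean(v)
  cv <- v - mu
  m2 <- mean(cv^2)
  skew <- if (m2 > 0) mean(cv^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean(cv^4) / m2^2 else 0
  if (diff(range(v)) > 0) {
    h <- tabulate(pmin(floor((v - min(v)) / diff(range(v)) * Ng) + 1L, Ng), nbins = Ng)
    p <- h / n
  } else p <- 1
  c(mean = mu, median = stats::median(v), minimum = min(v), maximum = max(v),
    range = diff(range(v)), variance = m2, sd = sqrt(m2),
    skewness = skew, kurtosis = kurt, energy = sum(v^2), rms = sqrt(mean(v^2)),
    entropy = -sum(xlogx(p)), uniformity = sum(p^2), mad = mean(abs(cv)),
    p10 = unname(stats::quantile(v, 0.10)), p90 = unname(stats::quantile(v, 0.90)))
}

# co-occurrence counts for one offset, valid-valid pairs, symmetric
glcm_counts <- function(q, dr, dc) {
  lv <- q$levels; Ng <- q$Ng
  H <- nrow(lv); W <- ncol(lv)
  r1 <- max(1L, 1L - dr):min(H, H - dr)
  c1 <- max(1L, 1L - dc):min(W, W - dc)
  a <- lv[r1, c1, drop = FALSE]
  b <- lv[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  cnt <- tabulate(a[ok] + (b[ok] - 1L) * Ng, nbins = Ng * Ng)
  P <- matrix(cnt, Ng, Ng)
  P + t(P)
}

haralick_from_p <- function(P) {
  Ng <- nrow(P)
  p <- P / sum(P)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  lv <- seq_len(Ng)
  mux <- sum(lv * px); muy <- sum(lv * py)
  sdx <- sqrt(sum((lv - mux)^2 * px)); sdy <- sqrt(sum((lv - muy)^2 * py))
  # p_{x+y} over k = 2..2Ng, p_{x-y} over d = 0..Ng-1
  pxy_sum <- vapply(2:(2 * Ng), function(k) sum(p[i + j == k]), numeric(1))
  pxy_dif <- vapply(0:(Ng - 1), function(d) sum(p[abs(i - j) == d]), numeric(1))
  ks <- 2:(2 * Ng); ds <- 0:(Ng - 1)
  asm <- sum(p^2)
  contrast <- sum(ds^2 * pxy_dif)
  correlation <- if (sdx > 0 && sdy > 0) (sum(i * j * p) - mux * muy) / (sdx * sdy) else 0
  variance <- sum((i - mux)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  sum_avg <- sum(ks * pxy_sum)
  sum_var <- sum((ks - sum_avg)^2 * pxy_sum)
  sum_ent <- -sum(xlogx(pxy_sum))
  entropy <- -sum(xlogx(p))
  dif_avg <- sum(ds * pxy_dif)
  dif_var <- sum((ds - dif_avg)^2 * pxy_dif)
  dif_ent <- -sum(xlogx(pxy_dif))
  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  pxpy <- outer(px, py)
  hxy1 <- -sum(ifelse(pxpy > 0, p * log2(pxpy), 0))
  hxy2 <- -sum(xlogx(pxpy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  arg <- 1 - exp(-2 * (hxy2 - entropy))
  imc2 <- sqrt(max(arg, 0))
  c(asm = asm, contrast = contrast, correlation = correlation,
    sum_squares_variance = variance, idm = idm, sum_average = sum_avg,
    sum_variance = sum_var, sum_entropy = sum_ent, entropy = entropy,
    difference_variance = dif_var, difference_entropy = dif_ent,
    imc1 = imc1, imc2 = imc2)
}

#' Gray-level co-occurrence (GLCM) features
#'
#' Symmetric, normalized co-occurrence matrices at distance 1 in the four
#' directions 0, 45, 90 and 135 degrees, restricted to valid-valid pixel
#' pairs; the 13 Haralick features of each direction are averaged over
#' directions (directions with no co-occurring pair are dropped from the
#' average).
#'
#' @param q A [quantize()]d map.
#' @return Named numeric vector of length 13.
#' @export
glcm_features <- function(q) {
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  per_dir <- purrr::compact(purrr::map(offsets, function(o) {
    P <- glcm_counts(q, o[1], o[2])
    if (is.null(P)) NULL else haralick_from_p(P)
  }))
  if (length(per_dir) == 0L) {
    stop("no co-occurring valid pairs in any direction", call. = FALSE)
  }
  out <- rowMeans(do.call(cbind, per_dir))
  stats::setNames(out, paste0("glcm_", names(out)))
}

# lines of a level matrix along a direction; NA (invalid) breaks runs
direction_lines <- function(lv, direction) {
  H <- nrow(lv); W <- ncol(lv)
  switch(direction,
    "0"   = lapply(seq_len(H), function(r) lv[r, ]),
    "90"  = lapply(seq_len(W), function(cc) lv[, cc]),
    "45"  = { idx <- row(lv) + col(lv); split(lv[order(idx, -row(lv))], sort(idx)) },
    "135" = { idx <- row(lv) - col(lv); split(lv[order(idx, row(lv))], sort(idx)) })
}

rlm_for_direction <- function(q, direction) {
  lines <- direction_lines(q$levels, direction)
  Ng <- q$Ng
  Lmax <- max(lengths(lines))
  cnt <- numeric(Ng * Lmax)
  for (ln in lines) {
    r <- rle(as.integer(ln))
    keep <- !is.na(r$values)
    if (!any(keep)) next
    idx <- r$values[keep] + (r$lengths[keep] - 1L) * Ng
    for (k in idx) cnt[k] <- cnt[k] + 1
  }
  matrix(cnt, Ng, Lmax)
}

glrlm_base <- function(R, Np) {
  Nr <- sum(R)
  if (Nr == 0) return(stats::setNames(numeric(11), c(
    "sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
    "srlge", "srhge", "lrlge", "lrhge")))
  i <- row(R); r <- col(R)
  c(sre = sum(R / r^2) / Nr, lre = sum(R * r^2) / Nr,
    gln = sum(rowSums(R)^2) / Nr, rln = sum(colSums(R)^2) / Nr,
    rp = Nr / Np,
    lgre = sum(R / i^2) / Nr, hgre = sum(R * i^2) / Nr,
    srlge = sum(R / (i^2 * r^2)) / Nr, srhge = sum(R * i^2 / r^2) / Nr,
    lrlge = sum(R * r^2 / i^2) / Nr, lrhge = sum(R * i^2 * r^2) / Nr)
}

#' Gray-level run-length (GLRLM) features
#'
#' Run-length matrices in the four principal directions; 11 base features
#' (short/long-run emphasis, gray-level and run-length nonuniformity, run
#' percentage, low/high gray-level emphasis and the four joint emphases),
#' each summarized by its mean and its range (max minus min) over the four
#' directions, giving 22 values.
#'
#' @param q A [quantize()]d map.
#' @return Named numeric vector of length 22.
#' @export
glrlm_features <- function(q) {
  Np <- sum(q$valid)
  per_dir <- vapply(c("0", "45", "90", "135"),
                    function(d) glrlm_base(rlm_for_direction(q, d), Np),
                    numeric(11))
  means <- rowMeans(per_dir)
  ranges <- apply(per_dir, 1L, function(v) diff(range(v)))
  stats::setNames(c(means, ranges),
                  c(paste0("glrlm_", names(means), "_mean"),
                    paste0("glrlm_", names(means), "_range")))
}

# 8-connected zones of constant level among valid cells
glszm_zones <- function(q) {
  lv <- q$levels
  H <- nrow(lv); W <- ncol(lv)
  cells <- which(!is.na(lv))
  if (length(cells) == 0L) return(NULL)
  id <- matrix(NA_integer_, H, W)
  id[cells] <- seq_along(cells)
  edges <- integer(0)
  for (o in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    dr <- o[1]; dc <- o[2]
    r1 <- max(1L, 1L - dr):min(H, H - dr)
    c1 <- max(1L, 1L - dc):min(W, W - dc)
    a <- lv[r1, c1, drop = FALSE]; b <- lv[r1 + dr, c1 + dc, drop = FALSE]
    ia <- id[r1, c1, drop = FALSE]; ib <- id[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b) & a == b
    if (any(ok)) edges <- c(edges, rbind(ia[ok], ib[ok]))
  }
  g <- igraph::make_graph(edges = edges, n = length(cells), directed = FALSE)
  comp <- igraph::components(g)
  data.frame(level = lv[cells], zone = comp$membership)
}

#' Gray-level size-zone (GLSZM) features
#'
#' Zones are 8-connected components of equal gray level among valid cells.
#' Thirteen features: small/large-area emphasis, gray-level nonuniformity,
#' zone-size nonuniformity, zone percentage, low/high gray-level zone
#' emphasis, the four joint emphases, and gray-level / zone-size variance.
#'
#' @param q A [quantize()]d map.
#' @return Named numeric vector of length 13.
#' @export
glszm_features <- function(q) {
  zs <- glszm_zones(q)
  Np <- sum(q$valid)
  z <- as.numeric(tabulate(zs$zone))                      # size of each zone
  i <- as.numeric(vapply(split(zs$level, zs$zone), `[`, integer(1), 1L))
  Nz <- length(z)
  p <- rep(1 / Nz, Nz)
  mu_i <- mean(i); mu_z <- mean(z)
  stats::setNames(c(
    sum(1 / z^2) / Nz, sum(z^2) / Nz,
    sum(tapply(rep(1, Nz), i, sum)^2) / Nz, sum(tapply(rep(1, Nz), z, sum)^2) / Nz,
    Nz / Np,
    sum(1 / i^2) / Nz, sum(i^2) / Nz,
    sum(1 / (i^2 * z^2)) / Nz, sum(i^2 / z^2) / Nz,
    sum(z^2 / i^2) / Nz, sum(i^2 * z^2) / Nz,
    sum(p * (i - mu_i)^2), sum(p * (z - mu_z)^2)),
    paste0("glszm_", c("sae", "lae", "gln", "zsn", "zp", "lgze", "hgze",
                       "salge", "sahge", "lalge", "lahge",
                       "gl_variance", "zs_variance")))
}

# shift a matrix by (dr, dc), zero-filling
shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  rs <- max(1L, 1L + dr):min(H, H + dr)
  cs <- max(1L, 1L + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Neighbourhood gray-tone difference (NGTDM) features
#'
#' For each valid cell, the absolute difference between its level and the
#' mean level of its valid 8-neighbours accumulates into `s(i)` for its
#' level `i`. The five Amadasun-King features follow: coarseness (inverse
#' of `sum(p_i s_i)`, capped at 1e6 for flat regions), contrast, busyness,
#' complexity and strength.
#'
#' @param q A [quantize()]d map.
#' @return Named numeric vector of length 5.
#' @export
ngtdm_features <- function(q) {
  lv <- q$levels; Ng <- q$Ng
  V <- ifelse(is.na(lv), 0, lv)
  C <- (!is.na(lv)) * 1
  nb_sum <- 0; nb_cnt <- 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb_sum <- nb_sum + shift_mat(V, dr, dc)
    nb_cnt <- nb_cnt + shift_mat(C, dr, dc)
  }
  use <- !is.na(lv) & nb_cnt > 0
  A <- nb_sum[use] / nb_cnt[use]
  li <- lv[use]
  N <- length(li)
  ni <- tabulate(li, nbins = Ng)
  pi_ <- ni / N
  si <- numeric(Ng)
  acc <- tapply(abs(li - A), li, sum)
  si[as.integer(names(acc))] <- acc
  present <- which(pi_ > 0)
  Ngp <- length(present)
  den <- sum(pi_ * si)
  coarseness <- if (den > 0) min(1 / den, 1e6) else 1e6
  contrast <- if (Ngp > 1) {
    g <- outer(present, present, function(a, b) (a - b)^2)
    pp <- outer(pi_[present], pi_[present])
    sum(pp * g) / (Ngp * (Ngp - 1)) * sum(si) / N
  } else 0
  ipi <- present * pi_[present]
  bus_den <- sum(abs(outer(ipi, ipi, `-`)))
  busyness <- if (bus_den > 0) den / bus_den else 0
  cmplx <- 0; strength <- 0
  if (Ngp > 0) {
    for (a in present) for (b in present) {
      if (a == b) next
      cmplx <- cmplx + abs(a - b) * (pi_[a] * si[a] + pi_[b] * si[b]) / (N * (pi_[a] + pi_[b]))
      strength <- strength + (pi_[a] + pi_[b]) * (a - b)^2
    }
    strength <- if (sum(si) > 0) strength / sum(si) else 0
  }
  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = cmplx,
    ngtdm_strength = strength)
}

# ---- wavelet decomposition ------------------------------------------------

wavelet_filters <- function(family = c("haar", "db2")) {
  family <- match.arg(family)
  if (family == "haar") {
    lo <- c(1, 1) / sqrt(2)
  } else {
    s3 <- sqrt(3)
    lo <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  }
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)  # quadrature mirror
  list(lo = lo, hi = hi)
}

# analysis step along a vector: periodic extension, downsample by 2
dwt_step <- function(x, f) {
  n <- length(x)
  if (n %% 2L == 1L) { x <- c(x, x[n]); n <- n + 1L }
  starts <- seq(1L, n, by = 2L)
  idx <- outer(seq_along(f) - 1L, starts, `+`)
  idx <- (idx - 1L) %% n + 1L
  as.numeric(f %*% matrix(x[idx], nrow = length(f)))
}

dwt2_level1 <- function(m, family = "haar") {
  flt <- wavelet_filters(family)
  Hh <- ceiling(nrow(m) / 2); Wh <- ceiling(ncol(m) / 2)
  row_pass <- function(f) {
    t(matrix(vapply(seq_len(nrow(m)), function(r) dwt_step(m[r, ], f), numeric(Wh)),
             nrow = Wh))
  }
  col_pass <- function(mm, f) {
    matrix(vapply(seq_len(ncol(mm)), function(cc) dwt_step(mm[, cc], f), numeric(Hh)),
           nrow = Hh)
  }
  rows_lo <- row_pass(flt$lo); rows_hi <- row_pass(flt$hi)
  list(LL = col_pass(rows_lo, flt$lo), LH = col_pass(rows_lo, flt$hi),
       HL = col_pass(rows_hi, flt$lo), HH = col_pass(rows_hi, flt$hi))
}

# nearest-valid-neighbour fill (grid distance)
fill_invalid <- function(values, valid) {
  if (all(valid)) return(values)
  idx_valid <- which(valid, arr.ind = TRUE)
  idx_bad <- which(!valid, arr.ind = TRUE)
  vv <- values[valid]
  for (k in seq_len(nrow(idx_bad))) {
    d <- (idx_valid[, 1] - idx_bad[k, 1])^2 + (idx_valid[, 2] - idx_bad[k, 2])^2
    values[idx_bad[k, 1], idx_bad[k, 2]] <- vv[which.min(d)]
  }
  values
}

#' Single-level 2-D wavelet subbands of a feature map
#'
#' The valid region's bounding-box crop is filled at invalid cells with the
#' nearest valid neighbour, then decomposed by a one-level separable 2-D
#' discrete wavelet transform (Haar by default) into the LL, LH, HL and HH
#' frequency components. Each subband carries a 2x-downsampled validity
#' mask (a subband cell is valid when any input cell under it was).
#'
#' @param map A [feature_map()].
#' @param family Wavelet family: `"haar"` (default) or `"db2"`.
#' @return Named list of four [feature_map()]s (`LL`, `LH`, `HL`, `HH`).
#' @export
wavelet_subbands <- function(map, family = "haar") {
  stopifnot(inherits(map, "feature_map"))
  cr <- crop_roi(map$values, roi_mask(map$valid))
  vals <- cr$values; msk <- cr$mask
  if (nrow(vals) < 2L || ncol(vals) < 2L) {
    stop("valid region must be at least 2 x 2 for a wavelet decomposition", call. = FALSE)
  }
  vals[!msk] <- 0  # replaced below; keeps NAs out of the fill
  vals <- fill_invalid(vals, msk)
  sb <- dwt2_level1(vals, family)
  Hs <- nrow(sb$LL); Ws <- ncol(sb$LL)
  down_valid <- matrix(FALSE, Hs, Ws)
  ridx <- pmin((row(msk) + 1L) %/% 2L, Hs)
  cidx <- pmin((col(msk) + 1L) %/% 2L, Ws)
  hit <- unique(cbind(ridx[msk], cidx[msk]))
  down_valid[hit] <- TRUE
  purrr::imap(sb, function(m, nm) {
    feature_map(m, down_valid, map$kind, units = map$units,
                params = c(map$params, list(subband = nm, family = family)))
  })
}

# ---- full extraction ------------------------------------------------------

subband_features <- function(map, Ng) {
  v <- map$values[map$valid]
  hist_f <- histogram_features(map, Ng = Ng)
  q <- if (length(unique(v)) < 2L) {
    warning("constant map region: texture features take their degenerate values",
            call. = FALSE)
    constant_quantization(map$values, map$valid)
  } else {
    quantize(map, Ng = Ng)
  }
  c(stats::setNames(hist_f, paste0("hist_", names(hist_f))),
    glcm_features(q), glrlm_features(q), glszm_features(q), ngtdm_features(q))
}

feature_family <- function(name) sub("_.*", "", name)

#' Extract the 345-feature radiomics vector of one feature map
#'
#' 69 texture features (16 histogram + 13 GLCM + 22 GLRLM + 13 GLSZM +
#' 5 NGTDM) on the original map, plus the same 69 on each of its four
#' single-level wavelet subbands: 276 wavelet-based features and 345 in
#' total. Name order is deterministic:
#' `<kind>_<subband>_<family>_<feature>` with subbands in the order
#' `orig, LL, LH, HL, HH`.
#'
#' @param map A [feature_map()].
#' @param Ng Gray levels for quantization (default 64).
#' @param wavelet Wavelet family for the subbands (default `"haar"`).
#' @return A tibble with columns `name`, `value`, `map`, `subband`,
#'   `family`; exactly 345 rows.
#' @export
extract_map_features <- function(map, Ng = 64L, wavelet = "haar") {
  stopifnot(inherits(map, "feature_map"))
  sbs <- c(list(orig = map), wavelet_subbands(map, family = wavelet))
  rows <- purrr::imap(sbs, function(m, sb) {
    f <- subband_features(m, Ng = Ng)
    tibble::tibble(
      name = paste(map$kind, sb, names(f), sep = "_"),
      value = unname(f),
      map = map$kind, subband = sb, family = feature_family(names(f)))
  })
  out <- dplyr::bind_rows(rows)
  stopifnot(nrow(out) == 345L)
  out
}

#' Concatenate per-map radiomics vectors for one patient
#'
#' Maps are ordered DEA, SSD, NRD (then GRAYSCALE) regardless of input
#' order; names stay map-kind-prefixed, so 1, 2 and 3 RF maps give 345,
#' 690 and 1035 features.
#'
#' @param maps List of [feature_map()]s with distinct kinds.
#' @param Ng,wavelet Passed to [extract_map_features()].
#' @return Tibble of `name`/`value` (+ provenance columns), `345 * length(maps)` rows.
#' @export
extract_patient_features <- function(maps, Ng = 64L, wavelet = "haar") {
  kinds <- vapply(maps, function(m) m$kind, character(1))
  if (anyDuplicated(kinds)) stop("duplicate map kinds", call. = FALSE)
  ord <- order(match(kinds, c("DEA", "SSD", "NRD", "GRAYSCALE")))
  dplyr::bind_rows(lapply(maps[ord], extract_map_features, Ng = Ng, wavelet = wavelet))
}
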