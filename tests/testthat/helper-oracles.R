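# Independent brute-force oracles. Everything here is written as plain
# loops over definitions, deliberately sharing no code with the package
# internals it checks.

# naive O(n^2) DFT magnitude (no FFT)
naive_dft_mod <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k) {
    Mod(sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)))
  }, numeric(1))
}

naive_block_energy <- function(x) mean(naive_dft_mod(x)^2)

naive_skewness <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m3 / m2^1.5
}

# single-placement DEA at 1-based start i of column v
oracle_dea_value <- function(v, i, win_len = 64, gap = 16, c = 1540, fs = 3.2e7) {
  e0 <- naive_block_energy(v[i:(i + win_len - 1)])
  e1 <- naive_block_energy(v[(i + win_len + gap):(i + 2 * win_len + gap - 1)])
  10 * log10(e0 / e1) / (win_len * c / fs / 2)
}

# single-placement SSD at 1-based start i of column v
oracle_ssd_value <- function(v, i, win_len = 64, gap = 40) {
  s0 <- naive_dft_mod(v[i:(i + win_len - 1)])
  s1 <- naive_dft_mod(v[(i + win_len + gap):(i + 2 * win_len + gap - 1)])
  naive_skewness(s0 - s1)
}

# co-occurring pair counts (symmetric) by explicit cell loops
oracle_glcm_counts <- function(lv, dr, dc, Ng) {
  P <- matrix(0, Ng, Ng)
  for (r in seq_len(nrow(lv))) for (cc in seq_len(ncol(lv))) {
    r2 <- r + dr; c2 <- cc + dc
    if (r2 < 1 || r2 > nrow(lv) || c2 < 1 || c2 > ncol(lv)) next
    a <- lv[r, cc]; b <- lv[r2, c2]
    if (is.na(a) || is.na(b)) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P
}

# multiset of (level, run length) found by walking each line
oracle_runs <- function(lv, direction) {
  H <- nrow(lv); W <- ncol(lv)
  step <- switch(direction, "0" = c(0, 1), "45" = c(-1, 1),
                 "90" = c(1, 0), "135" = c(1, 1))
  starts <- list()
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    pr <- r - step[1]; pc <- cc - step[2]
    if (pr < 1 || pr > H || pc < 1 || pc > W) starts <- c(starts, list(c(r, cc)))
  }
  runs <- NULL
  for (st in starts) {
    r <- st[1]; cc <- st[2]
    cur <- NA; len <- 0
    while (r >= 1 && r <= H && cc >= 1 && cc <= W) {
      v <- lv[r, cc]
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        if (!is.na(cur)) runs <- rbind(runs, c(cur, len))
        cur <- v; len <- if (is.na(v)) 0 else 1
      }
      r <- r + step[1]; cc <- cc + step[2]
    }
    if (!is.na(cur)) runs <- rbind(runs, c(cur, len))
  }
  runs[order(runs[, 1], runs[, 2]), , drop = FALSE]
}

# multiset of (level, zone size) by recursive 8-connected flood fill
oracle_zones <- function(lv) {
  H <- nrow(lv); W <- ncol(lv)
  seen <- matrix(FALSE, H, W)
  zones <- NULL
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    if (seen[r, cc] || is.na(lv[r, cc])) next
    level <- lv[r, cc]
    stack <- list(c(r, cc)); seen[r, cc] <- TRUE; size <- 0
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        nr <- cur[1] + dr; nc <- cur[2] + dc
        if (nr < 1 || nr > H || nc < 1 || nc > W) next
        if (seen[nr, nc] || is.na(lv[nr, nc]) || lv[nr, nc] != level) next
        seen[nr, nc] <- TRUE
        stack <- c(stack, list(c(nr, nc)))
      }
    }
    zones <- rbind(zones, c(level, size))
  }
  zones[order(zones[, 1], zones[, 2]), , drop = FALSE]
}

# NGTDM s-vector by explicit neighbourhood loops
oracle_ngtdm_s <- function(lv, Ng) {
  H <- nrow(lv); W <- ncol(lv)
  s <- numeric(Ng)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    if (is.na(lv[r, cc])) next
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nr <- r + dr; nc <- cc + dc
      if (nr < 1 || nr > H || nc < 1 || nc > W) next
      if (!is.na(lv[nr, nc])) nb <- c(nb, lv[nr, nc])
    }
    if (length(nb) > 0) s[lv[r, cc]] <- s[lv[r, cc]] + abs(lv[r, cc] - mean(nb))
  }
  s
}

# O(n^2) concordant-pair AUC
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# build a quantized_map object directly (bypasses quantize() validation)
make_qmap <- function(levels, Ng) {
  levels <- as.matrix(levels)
  storage.mode(levels) <- "integer"
  structure(list(levels = levels, Ng = as.integer(Ng),
                 valid = !is.na(levels),
                 bin_edges = seq(0, 1, length.out = Ng + 1)),
            class = "quantized_map")
}

# small uniform feature map
make_map <- function(values, kind = "DEA", valid = NULL) {
  values <- as.matrix(values)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(values), ncol(values))
  feature_map(values, valid, kind)
}

# quick speckle ROI matrix (white Gaussian RF)
speckle_roi <- function(H, W, seed = 1) {
  withr::with_seed(seed, matrix(stats::rnorm(H * W), H, W))
}
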