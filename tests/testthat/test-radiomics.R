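test_that("quantization is equal-width, affine-invariant, and guards degenerates", {
  v <- matrix(0:63, 8, 8)
  q <- quantize(v, Ng = 64)
  expect_identical(q$levels, matrix(as.integer(0:63 + 1), 8, 8))

  withr::with_seed(1, m <- matrix(rnorm(100), 10, 10))
  q1 <- quantize(m, Ng = 32)
  q2 <- quantize(3 + 2 * m, Ng = 32)
  expect_identical(q1$levels, q2$levels)

  two <- matrix(rep(c(1, 9), 8), 4, 4)
  expect_setequal(unique(as.vector(quantize(two, Ng = 2)$levels)), c(1L, 2L))

  expect_error(quantize(matrix(5, 4, 4), Ng = 8), "constant")
})

test_that("histogram features match hand arithmetic and degenerate rules", {
  f <- histogram_features(matrix(c(1, 2, 3, 4), 2, 2))
  expect_length(f, 16L)
  expect_equal(f[["mean"]], 2.5)
  expect_equal(f[["variance"]], 1.25)   # population moments
  expect_equal(f[["range"]], 3)
  expect_equal(f[["energy"]], 30)
  expect_equal(f[["rms"]], sqrt(30 / 4))
  expect_equal(f[["skewness"]], 0)

  fc <- histogram_features(matrix(7, 3, 3))
  expect_equal(fc[["mean"]], 7); expect_equal(fc[["median"]], 7)
  expect_equal(fc[["range"]], 0); expect_equal(fc[["variance"]], 0)
  expect_equal(fc[["uniformity"]], 1); expect_equal(fc[["entropy"]], 0)
  expect_equal(fc[["skewness"]], 0); expect_equal(fc[["kurtosis"]], 0)
})

test_that("GLCM matches brute-force pair enumeration and hand examples", {
  # [[1,2],[1,2]] at 0 degrees: P(1,2) = P(2,1) = 1/2, contrast 1
  q <- make_qmap(rbind(c(1, 2), c(1, 2)), Ng = 2)
  P <- rfrad:::glcm_counts(q, 0L, 1L)
  expect_equal(P / sum(P), rbind(c(0, 0.5), c(0.5, 0)))
  h <- rfrad:::haralick_from_p(P)
  expect_equal(h[["contrast"]], 1)

  f <- glcm_features(q)
  expect_length(f, 13L)

  # constant map: ASM 1, contrast 0, entropy 0
  fcst <- glcm_features(make_qmap(matrix(1, 4, 4), Ng = 1))
  expect_equal(fcst[["glcm_asm"]], 1)
  expect_equal(fcst[["glcm_contrast"]], 0)
  expect_equal(fcst[["glcm_entropy"]], 0)

  # oracle equivalence on random small maps, all 4 offsets, with holes
  withr::with_seed(2, {
    for (rep in 1:10) {
      lv <- matrix(sample.int(4, 30, replace = TRUE), 5, 6)
      lv[sample.int(30, 4)] <- NA
      qq <- make_qmap(lv, Ng = 4)
      for (o in list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))) {
        expect_equal(rfrad:::glcm_counts(qq, o[1], o[2]),
                     oracle_glcm_counts(lv, o[1], o[2], 4L))
      }
    }
  })
})

test_that("GLRLM run extraction matches a walking oracle; features match hand values", {
  # single row of four equal levels: one run of length 4
  q <- make_qmap(matrix(c(1, 1, 1, 1), 1, 4), Ng = 1)
  R <- rfrad:::rlm_for_direction(q, "0")
  expect_equal(sum(R), 1)
  b <- rfrad:::glrlm_base(R, Np = 4)
  expect_equal(b[["sre"]], 1 / 16)
  expect_equal(b[["lre"]], 16)
  expect_equal(b[["rp"]], 1 / 4)

  # constant N x N map: N runs of length N horizontally
  qc <- make_qmap(matrix(1, 5, 5), Ng = 1)
  Rc <- rfrad:::rlm_for_direction(qc, "0")
  expect_equal(Rc[1, 5], 5)

  expect_length(glrlm_features(q), 22L)

  # oracle equivalence of the run multiset in all directions
  withr::with_seed(3, {
    for (rep in 1:10) {
      lv <- matrix(sample.int(3, 36, replace = TRUE), 6, 6)
      lv[sample.int(36, 5)] <- NA
      qq <- make_qmap(lv, Ng = 3)
      for (d in c("0", "45", "90", "135")) {
        R <- rfrad:::rlm_for_direction(qq, d)
        got <- cbind(row(R)[R > 0], col(R)[R > 0])[rep(seq_len(sum(R > 0)),
                                                       R[R > 0]), , drop = FALSE]
        got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
        expect_equal(unname(got), unname(oracle_runs(lv, d)))
      }
    }
  })
})

test_that("GLSZM zones are 8-connected equal-level components", {
  # constant map: one zone covering everything
  q <- make_qmap(matrix(1, 4, 4), Ng = 1)
  f <- glszm_features(q)
  expect_length(f, 13L)
  expect_equal(f[["glszm_zp"]], 1 / 16)

  # checkerboard: diagonal neighbours join, two zones of size 2
  chk <- rbind(c(1, 2), c(2, 1))
  zs <- rfrad:::glszm_zones(make_qmap(chk, Ng = 2))
  sizes <- sort(as.numeric(table(zs$zone)))
  expect_equal(sizes, c(2, 2))
  expect_equal(unname(oracle_zones(chk)[, 2]), c(2, 2))

  # oracle equivalence of (level, size) multisets on random maps
  withr::with_seed(4, {
    for (rep in 1:10) {
      lv <- matrix(sample.int(3, 30, replace = TRUE), 5, 6)
      lv[sample.int(30, 3)] <- NA
      zz <- rfrad:::glszm_zones(make_qmap(lv, Ng = 3))
      got <- cbind(tapply(zz$level, zz$zone, `[`, 1), table(zz$zone))
      got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
      expect_equal(unname(got), unname(oracle_zones(lv)))
    }
  })
})

test_that("NGTDM matches a loop oracle and caps flat-region coarseness", {
  # centre cell differing from 8 identical neighbours: s(centre level) = d
  lv <- matrix(1, 3, 3); lv[2, 2] <- 3   # d = 2
  s_or <- oracle_ngtdm_s(lv, 3L)
  expect_equal(s_or[3], 2)
  f <- ngtdm_features(make_qmap(lv, Ng = 3))
  expect_length(f, 5L)
  # contrast recomputed independently from the oracle s-vector
  ni <- tabulate(lv, 3); p <- ni / 9; pres <- which(p > 0)
  con <- sum(outer(p[pres], p[pres]) * outer(pres, pres, `-`)^2) /
    (length(pres) * (length(pres) - 1)) * sum(s_or) / 9
  expect_equal(f[["ngtdm_contrast"]], con)

  fcst <- ngtdm_features(make_qmap(matrix(2, 4, 4), Ng = 2))
  expect_equal(fcst[["ngtdm_coarseness"]], 1e6)
  expect_equal(fcst[["ngtdm_contrast"]], 0)

  # random-map oracle equivalence of the s-vector via busyness numerator
  withr::with_seed(5, {
    lvr <- matrix(sample.int(4, 36, replace = TRUE), 6, 6)
    fr <- ngtdm_features(make_qmap(lvr, Ng = 4))
    s_or <- oracle_ngtdm_s(lvr, 4L)
    p_or <- tabulate(lvr, 4) / 36
    expect_equal(fr[["ngtdm_coarseness"]], min(1 / sum(p_or * s_or), 1e6))
  })
})

test_that("single-level Haar decomposition matches hand evaluation", {
  m <- rbind(c(3, 5), c(7, 1))  # a=3 b=5 c=7 d=1
  sb <- rfrad:::dwt2_level1(m, "haar")
  expect_equal(sb$LL[1, 1], (3 + 5 + 7 + 1) / 2)
  expect_equal(sb$HH[1, 1], (3 - 5 - 7 + 1) / 2)

  cst <- make_map(matrix(4, 8, 8))
  sbs <- wavelet_subbands(cst)
  expect_named(sbs, c("LL", "LH", "HL", "HH"))
  expect_equal(unique(as.vector(sbs$LL$values)), 8)  # 2c
  expect_equal(max(abs(sbs$LH$values), abs(sbs$HL$values), abs(sbs$HH$values)),
               0, tolerance = 1e-12)

  # db2 subbands also reconstruct constants into LL only
  sbd <- wavelet_subbands(make_map(matrix(2, 9, 9)), family = "db2")
  expect_equal(unique(round(as.vector(sbd$HH$values), 10)), 0)
})

test_that("extraction yields exactly 345 features per map with Table-style family counts", {
  withr::with_seed(6, mp <- make_map(matrix(rnorm(30 * 12), 30, 12)))
  fv <- extract_map_features(mp, Ng = 16)
  expect_identical(nrow(fv), 345L)
  counts <- dplyr::count(fv, subband, family)
  expect_setequal(unique(counts$subband), c("orig", "LL", "LH", "HL", "HH"))
  for (sb in unique(counts$subband)) {
    cc <- counts[counts$subband == sb, ]
    expect_equal(cc$n[match(c("hist", "glcm", "glrlm", "glszm", "ngtdm"),
                            cc$family)], c(16, 13, 22, 13, 5))
  }
  expect_identical(sum(fv$subband != "orig"), 276L)
  expect_true(all(is.finite(fv$value)))
})

test_that("patient-level concatenation gives 345/690/1035 in fixed map order", {
  withr::with_seed(7, {
    dea <- make_map(matrix(rnorm(400), 25, 16), kind = "DEA")
    ssd <- make_map(matrix(rnorm(400), 25, 16), kind = "SSD")
    nrd <- make_map(matrix(rexp(400), 25, 16), kind = "NRD")
  })
  expect_identical(nrow(extract_patient_features(list(dea), Ng = 8)), 345L)
  expect_identical(nrow(extract_patient_features(list(ssd, dea), Ng = 8)), 690L)
  fv <- extract_patient_features(list(nrd, ssd, dea), Ng = 8)
  expect_identical(nrow(fv), 1035L)
  expect_identical(unique(fv$map), c("DEA", "SSD", "NRD"))  # reordered
  expect_true(startsWith(fv$name[1], "DEA_orig_"))
  expect_error(extract_patient_features(list(dea, dea)), "duplicate")
})

test_that("matrix-family features are invariant to affine rescaling; extraction is deterministic", {
  withr::with_seed(8, v <- matrix(rnorm(24 * 10), 24, 10))
  a <- extract_map_features(make_map(v), Ng = 16)
  b <- extract_map_features(make_map(5 + 2 * v), Ng = 16)
  mat_fam <- a$family %in% c("glcm", "glrlm", "glszm", "ngtdm")
  expect_equal(b$value[mat_fam], a$value[mat_fam], tolerance = 1e-12)

  a2 <- extract_map_features(make_map(v), Ng = 16)
  expect_identical(a$value, a2$value)
})

test_that("constant maps short-circuit to defined degenerate feature values", {
  expect_warning(rfrad:::subband_features(make_map(matrix(3, 4, 4)), Ng = 8),
                 "degenerate")
  fv <- suppressWarnings(extract_map_features(make_map(matrix(3, 10, 10)), Ng = 8))
  expect_identical(nrow(fv), 345L)
  expect_true(all(is.finite(fv$value)))
  expect_equal(fv$value[fv$name == "DEA_orig_glcm_asm"], 1)
  expect_equal(fv$value[fv$name == "DEA_orig_hist_uniformity"], 1)
})
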