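# Texture matrices and features: hand-computed examples plus brute-force
# oracle equivalence on small random volumes (the full 20-volume sweep runs
# in the acceptance suite).

test_that("GLCM on a 2x2 slice matches the hand-enumerated matrix", {
  # [[1,1],[2,2]] (x = row): vertical pairs are (1,1) and (2,2); horizontal
  # pairs are (1,2) twice. After symmetrization along the x direction:
  # P(1,1) = P(2,2) = 1/4 and contrast = 0; along y: P(1,2) = P(2,1) = 1/2,
  # contrast = 1; hand-check via the internal single-direction path.
  dvol <- array(c(1L, 1L, 2L, 2L), c(2, 2, 1))
  attr(dvol, "n_levels") <- 2L
  ctx <- vsgrowth:::ctx_from_dvol(dvol)
  lev <- vsgrowth:::levels_from_dvol(dvol, ctx)
  offs <- vsgrowth:::offsets_13()
  # direction (1,0,0): pairs (1,1) and (2,2)
  kx <- which(offs[, 1] == 1 & offs[, 2] == 0 & offs[, 3] == 0)
  pr <- ctx$pairs[[kx]]
  counts <- tabulate((lev[pr[, 1]] - 1L) * 2L + lev[pr[, 2]], 4)
  P <- matrix(counts, 2, 2, byrow = TRUE); P <- (P + t(P)) / sum(P + t(P))
  expect_equal(P, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(vsgrowth:::glcm_features_single(P)[["contrast"]], 0)
  # direction (0,1,0): both pairs cross levels
  ky <- which(offs[, 1] == 0 & offs[, 2] == 1 & offs[, 3] == 0)
  pr <- ctx$pairs[[ky]]
  counts <- tabulate((lev[pr[, 1]] - 1L) * 2L + lev[pr[, 2]], 4)
  P2 <- matrix(counts, 2, 2, byrow = TRUE); P2 <- (P2 + t(P2)) / sum(P2 + t(P2))
  expect_equal(P2, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  f <- vsgrowth:::glcm_features_single(P2)
  expect_equal(f[["contrast"]], 1)
  # 4-cell symmetric matrix of the spec example: contrast 0.5
  P3 <- matrix(c(0.25, 0.25, 0.25, 0.25), 2, 2)
  expect_equal(vsgrowth:::glcm_features_single(P3)[["contrast"]], 0.5)
})

test_that("a constant volume is degenerate-safe for GLCM", {
  d <- array(1L, c(3, 3, 3))
  attr(d, "n_levels") <- 1L
  f <- glcm_features(d)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["id"]], 1)
  expect_equal(f[["correlation"]], 1)  # limit convention
  expect_equal(f[["mcc"]], 1)
  expect_equal(f[["max_probability"]], 1)
})

test_that("cluster prominence of a 2-level checkerboard matches direct summation", {
  d <- array(0L, c(4, 4, 1))
  co <- as.matrix(expand.grid(1:4, 1:4))
  d[cbind(co, 1)] <- 1L + (co[, 1] + co[, 2]) %% 2L
  attr(d, "n_levels") <- 2L
  got <- glcm_features(d)[["cluster_prominence"]]
  # direct summation oracle over all 13 direction matrices
  acc <- c()
  for (off in oracle_offsets_13()) {
    P <- oracle_glcm_matrix(d, 2, off)
    if (is.null(P)) next
    mux <- sum(row(P) * P); muy <- sum(col(P) * P)
    acc <- c(acc, sum((row(P) + col(P) - mux - muy)^4 * P))
  }
  expect_equal(got, mean(acc), tolerance = 1e-12)
})

test_that("GLRLM runs on a 1D row match hand enumeration", {
  d <- array(c(1L, 1L, 1L, 2L), c(4, 1, 1))
  attr(d, "n_levels") <- 2L
  # single direction (1,0,0): runs (level 1, len 3) and (level 2, len 1)
  P <- oracle_glrlm_matrix(d, 2, c(1, 0, 0))
  expect_equal(P[1, 3], 1)
  expect_equal(P[2, 1], 1)
  expect_equal(sum(P), 2)
  f <- oracle_glrlm_features(P, 4)
  expect_equal(f[["rln"]], (1^2 + 1^2) / 2)
  # SRLGLE on [1,1,2]: runs (1, len2), (2, len1)
  d2 <- array(c(1L, 1L, 2L), c(3, 1, 1))
  P2 <- oracle_glrlm_matrix(d2, 2, c(1, 0, 0))
  srlgle_hand <- (1 / (1^2 * 2^2) + 1 / (2^2 * 1^2)) / 2
  expect_equal(oracle_glrlm_features(P2, 3)[["srlgle"]], srlgle_hand)
})

test_that("constant volume yields one maximal run per line in every direction", {
  d <- array(1L, c(3, 3, 3))
  attr(d, "n_levels") <- 1L
  P <- oracle_glrlm_matrix(d, 1, c(1, 0, 0))
  expect_equal(unname(P[1, ]), c(0, 0, 9))  # nine lines of length 3
  f <- glrlm_features(d)
  expect_true(all(is.finite(f)))
})

test_that("GLSZM zones match hand examples and the flood-fill oracle", {
  # two disjoint single-voxel zones of different levels -> GLNN = 0.5
  d <- array(NA_integer_, c(3, 3, 1))
  d[1, 1, 1] <- 1L; d[3, 3, 1] <- 2L
  attr(d, "n_levels") <- 2L
  f <- glszm_features(d)
  expect_equal(f[["glnn"]], 0.5)
  expect_equal(f[["zone_percentage"]], 1)  # 2 zones / 2 voxels
  # one zone -> GLNN 1
  d1 <- array(1L, c(2, 2, 1)); attr(d1, "n_levels") <- 1L
  expect_equal(glszm_features(d1)[["glnn"]], 1)
  # zone decomposition equals flood fill on random volumes
  for (s in 1:20) {
    dv <- random_dvol(seed = 100 + s, ng = 3)
    P_o <- oracle_glszm_matrix(dv, 3)
    f_imp <- glszm_features(dv, 3)
    expect_equal(f_imp[["zone_percentage"]],
                 sum(P_o) / sum(!is.na(dv)), tolerance = 1e-12)
  }
})

test_that("NGTDM neighbourhood sums match a hand-computed 3x3 example", {
  # single slice, levels: row1 = 1 1 1, row2 = 1 2 1, row3 = 1 1 1
  d <- array(1L, c(3, 3, 1)); d[2, 2, 1] <- 2L
  attr(d, "n_levels") <- 2L
  st <- oracle_ngtdm(d, 2)
  # center voxel: all 8 neighbours are level 1 -> s(2) = |2 - 1| = 1
  expect_equal(st$s[2], 1)
  # corner voxels (level 1): neighbours include the center
  # e.g. (1,1): neighbours (2,1),(1,2),(2,2) -> mean (1+1+2)/3
  expect_equal(st$nvp, 9)
  f <- ngtdm_features(d)
  o <- oracle_ngtdm_features(d, 2)
  expect_equal(f, o, tolerance = 1e-12)
})

test_that("NGTDM of a constant volume caps coarseness and zeroes contrast", {
  d <- array(1L, c(3, 3, 3)); attr(d, "n_levels") <- 1L
  f <- ngtdm_features(d)
  expect_equal(f[["coarseness"]], 1e6)
  expect_equal(f[["contrast"]], 0)
})

test_that("difference-based NGTDM features are invariant to relabeling by +1", {
  # coarseness/contrast/complexity/strength depend on levels only through
  # differences, so a +1 relabel leaves them unchanged (busyness depends on
  # the absolute levels through |i p_i - j p_j| and is only approximately
  # stable)
  dv <- random_dvol(seed = 77, ng = 3)
  f1 <- ngtdm_features(dv, 3)
  dv2 <- dv + 1L
  attr(dv2, "n_levels") <- 4L
  f2 <- ngtdm_features(dv2, 4)
  for (nm in c("coarseness", "contrast", "complexity", "strength")) {
    expect_equal(f1[[nm]], f2[[nm]], tolerance = 1e-12)
  }
  expect_lt(abs(f1[["busyness"]] / f2[["busyness"]] - 1), 0.05)
})

test_that("GLDM dependence counts follow the neighbourhood definition", {
  # constant 3x3x3: every voxel's dependence = its neighbour count
  d <- array(1L, c(3, 3, 3)); attr(d, "n_levels") <- 1L
  P <- oracle_gldm_matrix(d, 1)
  # corner 7 nb (8 voxels), edge 11 (12), face 17 (6), center 26 (1)
  expect_equal(P[1, 8], 8)
  expect_equal(P[1, 12], 12)
  expect_equal(P[1, 18], 6)
  expect_equal(P[1, 27], 1)
  f <- gldm_features(d)
  o <- oracle_gldm_features(P)
  expect_equal(f, o, tolerance = 1e-12)
  # single voxel: dependence 0 -> one entry in column 1
  d1 <- array(1L, c(1, 1, 1)); attr(d1, "n_levels") <- 1L
  f1 <- gldm_features(d1)
  expect_equal(f1[["sde"]], 1)
  expect_equal(f1[["lde"]], 1)
})

test_that("all texture families agree with the oracles on random volumes", {
  for (s in 1:5) {
    dv <- random_dvol(seed = 200 + s, ng = 4)
    o <- oracle_texture_all(dv, 4)
    rel <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)
    expect_lt(max(rel(glcm_features(dv, 4), o$glcm)), 1e-10)
    expect_lt(max(rel(glrlm_features(dv, 4), o$glrlm)), 1e-10)
    expect_lt(max(rel(glszm_features(dv, 4), o$glszm)), 1e-10)
    expect_lt(max(rel(ngtdm_features(dv, 4), o$ngtdm)), 1e-10)
    expect_lt(max(rel(gldm_features(dv, 4), o$gldm)), 1e-10)
  }
})

test_that("feature extraction is deterministic and complete", {
  pat <- one_patient()
  w <- setNames(rep(0.05, 4), c("t2", "ktrans", "ve", "vp"))
  v1 <- extract_features(pat$channels, pat$mask, w, spacing = 1.5)
  v2 <- extract_features(pat$channels, pat$mask, w, spacing = 1.5)
  expect_identical(v1, v2)
  expect_equal(ncol(v1), 404)
  expect_true(all(is.finite(as.matrix(v1))))
  expect_error(extract_features(pat$channels[c("t2", "ve")], pat$mask, w),
               "ktrans")
})
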