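const_patch <- function(value, dims = c(3, 3, 3)) {
  array(value, dim = dims)
}

test_that("fixed-bin-width quantization anchors at the clip floor", {
  cfg <- quantization_config()
  q <- quantize(const_patch(-120), cfg)
  expect_equal(unique(as.vector(q$levels)), 1L)
  expect_equal(q$n_levels, 17L)  # [-120, 300] at 25 HU per bin
  # top edge of the range falls into the last bin
  expect_equal(unique(as.vector(quantize(const_patch(300), cfg)$levels)),
               17L)
  expect_equal(unique(as.vector(quantize(const_patch(-50), cfg)$levels)),
               3L)  # floor((-50+120)/25)+1
  # a constant patch occupies one level in fixed-bin-count mode too
  qc <- quantize(const_patch(-50),
                 quantization_config(mode = "fixed_bin_count", n_bins = 8))
  expect_equal(unique(as.vector(qc$levels)), 1L)
})

test_that("first-order features handle constant and two-valued patches", {
  f <- first_order_features(const_patch(-50))
  expect_equal(unname(f["firstorder.variance"]), 0)
  expect_equal(unname(f["firstorder.entropy"]), 0)
  expect_equal(unname(f["firstorder.uniformity"]), 1)
  expect_equal(unname(f["firstorder.skewness"]), 0)
  two <- array(c(rep(-120, 4), rep(300, 4)), dim = c(2, 2, 2))
  f2 <- first_order_features(two)
  expect_equal(unname(f2["firstorder.mean"]), 90)
  expect_equal(unname(f2["firstorder.entropy"]), 1)  # two equal-mass bins
  for (rep in 1:20) {
    v <- withr::with_seed(rep, array(runif(24, -120, 300),
                                     dim = c(4, 3, 2)))
    f3 <- first_order_features(v)
    expect_lte(f3[["firstorder.minimum"]], f3[["firstorder.median"]])
    expect_lte(f3[["firstorder.median"]], f3[["firstorder.maximum"]])
    expect_false(any(is.na(f3)))
  }
})

test_that("GLCM matrix matches hand enumeration on the 2x2 two-row grid", {
  # rows [1,1] / [2,2]; in-row neighbor offset (0,1,0) pairs (1,1),(2,2)
  lv <- array(c(1L, 2L, 1L, 2L), dim = c(2, 2, 1))
  q <- as_qpatch(lv, 2)
  mats <- glcm_matrices(q)
  dirs <- oracle_directions()
  inrow <- which(apply(dirs, 1, function(d) all(d == c(0, 1, 0))))
  P <- mats[[inrow]]
  expect_equal(unclass(P)[1:2, 1:2], matrix(c(0.5, 0, 0, 0.5), 2),
               ignore_attr = TRUE)
  # checkerboard: all mass off-diagonal for in-plane axis offsets
  cb <- array(1L + (outer(1:4, 1:4, "+") %% 2L), dim = c(4, 4, 1))
  qcb <- as_qpatch(cb, 2)
  mcb <- glcm_matrices(qcb)
  for (d in which(apply(dirs, 1, function(d) d[3] == 0 &&
                          sum(abs(d)) == 1))) {
    expect_equal(sum(diag(mcb[[d]])), 0)
  }
})

test_that("GLCM features evaluate correctly on known matrices", {
  P <- matrix(c(0.5, 0, 0, 0.5), 2)
  attr(P, "n_pairs") <- 8
  f <- glcm_features(list(P))
  expect_equal(unname(f["glcm.contrast"]), 0)
  expect_equal(unname(f["glcm.energy"]), 0.5)
  expect_equal(unname(f["glcm.joint_entropy"]), 1)
  # constant patch: contrast 0, energy 1, entropy 0, IDM 1
  fc <- glcm_features(glcm_matrices(as_qpatch(const_patch(1L), 3)))
  expect_equal(unname(fc["glcm.contrast"]), 0)
  expect_equal(unname(fc["glcm.energy"]), 1)
  expect_equal(unname(fc["glcm.joint_entropy"]), 0)
  expect_equal(unname(fc["glcm.inverse_difference_moment"]), 1)
  expect_equal(unname(fc["glcm.correlation"]), 0)
  # product-form matrix p(i,j) = p(i) p(j): correlation 0
  p <- c(0.2, 0.3, 0.5)
  Pp <- outer(p, p)
  attr(Pp, "n_pairs") <- 100
  expect_equal(unname(glcm_features(list(Pp))["glcm.correlation"]), 0,
               tolerance = 1e-12)
})

test_that("constant-cube texture counts match hand enumeration", {
  q <- as_qpatch(const_patch(1L), 2)
  # GLRLM, axis direction: 9 lines of one 3-run each -> RP = 9/27
  R <- radlung:::cpp_glrlm_counts(as.integer(q$levels), c(3L, 3L, 3L),
                                  2)[[1]]
  expect_equal(sum(R), 9)
  expect_equal(R[1, 3], 9)
  expect_equal(sum(R) / 27, 1 / 3)
  # GLSZM: one 26-connected zone covering the cube, zone pct 1/27
  f <- texture_family_features(q, "GLSZM")
  expect_equal(unname(f["glszm.zone_percentage"]), 1 / 27)
  expect_equal(unname(f["glszm.large_area_emphasis"]), 27^2)
  # NGTDM contrast vanishes on a flat patch
  expect_equal(unname(texture_family_features(q, "NGTDM")["ngtdm.contrast"]),
               0)
  # one deviant voxel creates a second zone
  lv <- const_patch(1L)
  lv[2, 2, 2] <- 2L
  expect_equal(nrow(radlung:::cpp_glszm_zones(as.integer(lv),
                                              c(3L, 3L, 3L))), 2)
  expect_error(texture_family_features(q, "GLXX"), "unknown")
})

test_that("run and zone percentages stay in (0, 1]", {
  for (rep in 1:20) {
    lv <- withr::with_seed(rep, random_level_patch(c(4, 3, 3), 3))
    q <- as_qpatch(lv, 3)
    rp <- texture_family_features(q, "GLRLM")[["glrlm.run_percentage"]]
    zp <- texture_family_features(q, "GLSZM")[["glszm.zone_percentage"]]
    expect_gt(rp, 0); expect_lte(rp, 1)
    expect_gt(zp, 0); expect_lte(zp, 1)
  }
})

test_that("GLCM entropy and energy are invariant to gray-level relabeling", {
  for (rep in 1:10) {
    lv <- withr::with_seed(rep, random_level_patch(c(4, 4, 3), 4))
    perm <- withr::with_seed(rep + 100, sample(4))
    lv2 <- array(perm[lv], dim = dim(lv))
    f1 <- glcm_features(glcm_matrices(as_qpatch(lv, 4)))
    f2 <- glcm_features(glcm_matrices(as_qpatch(lv2, 4)))
    expect_equal(f1["glcm.joint_entropy"], f2["glcm.joint_entropy"],
                 tolerance = 1e-12)
    expect_equal(f1["glcm.energy"], f2["glcm.energy"], tolerance = 1e-12)
  }
})

test_that("every family matches its brute-force oracle on random patches", {
  dirs <- oracle_directions()
  for (rep in 1:15) {
    dims <- withr::with_seed(rep, sample(2:4, 3, replace = TRUE))
    ng <- withr::with_seed(rep + 50, sample(2:4, 1))
    lv <- withr::with_seed(rep + 99, random_level_patch(dims, ng))
    q <- as_qpatch(lv, ng)
    np <- prod(dims)
    # GLCM: matrices and features
    impl <- radlung:::cpp_glcm_counts(as.integer(lv), dim(lv), ng)
    for (d in seq_len(nrow(dirs))) {
      expect_equal(unclass(impl[[d]]), oracle_glcm_counts(lv, ng, dirs[d, ]),
                   ignore_attr = TRUE)
    }
    # GLRLM
    implr <- radlung:::cpp_glrlm_counts(as.integer(lv), dim(lv), ng)
    orc <- lapply(seq_len(nrow(dirs)), function(d) {
      oracle_glrlm_counts(lv, ng, dirs[d, ])
    })
    for (d in seq_len(nrow(dirs))) {
      expect_equal(unclass(implr[[d]])[, seq_len(ncol(orc[[d]]))],
                   orc[[d]], ignore_attr = TRUE)
    }
    fr <- texture_family_features(q, "GLRLM")
    fro <- rowMeans(vapply(orc, oracle_glrlm_features, numeric(5),
                           np = np))
    expect_equal(unname(fr), unname(fro), tolerance = 1e-9)
    # GLSZM (zone multiset)
    zi <- radlung:::cpp_glszm_zones(as.integer(lv), dim(lv))
    zo <- oracle_glszm_zones(lv)
    expect_equal(zi[order(zi[, 1], zi[, 2]), , drop = FALSE],
                 zo[order(zo[, 1], zo[, 2]), , drop = FALSE],
                 ignore_attr = TRUE)
    fz <- texture_family_features(q, "GLSZM")
    expect_equal(unname(fz), unname(oracle_glszm_features(zo, np, ng)),
                 tolerance = 1e-9)
    # GLDM
    di <- radlung:::cpp_gldm_counts(as.integer(lv), dim(lv), ng, 0L)
    do <- oracle_gldm_counts(lv, ng, 0)
    expect_equal(unclass(di), do, ignore_attr = TRUE)
    fd <- texture_family_features(q, "GLDM")
    expect_equal(unname(fd), unname(oracle_gldm_features(do)),
                 tolerance = 1e-9)
    # NGTDM
    ni <- radlung:::cpp_ngtdm(as.integer(lv), dim(lv), ng)
    no <- oracle_ngtdm(lv, ng)
    expect_equal(ni$s, no$s, tolerance = 1e-9)
    expect_equal(ni$n, no$n)
    fn <- texture_family_features(q, "NGTDM")
    expect_equal(unname(fn),
                 unname(oracle_ngtdm_features(no$s, no$n, ng)),
                 tolerance = 1e-9)
  }
})

test_that("extract_patch_features returns the requested names in order", {
  patch <- withr::with_seed(4, array(runif(80, -120, 300),
                                     dim = c(4, 4, 5)))
  full <- extract_patch_features(patch)
  expect_identical(names(full), default_feature_spec())
  expect_false(any(!is.finite(full)))
  one <- extract_patch_features(patch, feature_spec = "glcm.contrast")
  expect_identical(names(one), "glcm.contrast")
  expect_equal(one[["glcm.contrast"]], full[["glcm.contrast"]])
  expect_error(extract_patch_features(patch, feature_spec = "glcm.bogus"),
               "glcm.bogus")
})
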