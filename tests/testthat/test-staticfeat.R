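test_that("registry defines 91 stable, uniquely named features", {
  reg <- feature_registry()
  expect_length(reg$names, 91)
  expect_equal(anyDuplicated(reg$names), 0)
  expect_length(reg$groups$first_order, 19)
  expect_length(reg$groups$binary_texture, 28)
  expect_length(reg$groups$glcm, 44)
  expect_identical(reg$names, feature_registry()$names)
})

test_that("quantization bins uniformly over the global range", {
  m <- matrix(c(0, 255, 100, 200), 2, 2)
  msk <- matrix(TRUE, 2, 2)
  q <- quantize_roi(m, msk, 2, c(0, 255))
  expect_equal(sort(unique(as.vector(q))), c(0L, 1L))
  expect_equal(q[1, 1], 0L)
  expect_equal(q[2, 1], 1L)
  # constant ROI maps to level 0
  expect_true(all(quantize_roi(matrix(7, 3, 3), matrix(TRUE, 3, 3), 32,
                               c(7, 7)) == 0L))
  # any ROI stays within [0, levels-1]
  r <- random_roi(12, 12, 3)
  q2 <- quantize_roi(r, matrix(TRUE, 12, 12), 32, range(r))
  expect_true(all(q2 >= 0 & q2 <= 31))
  expect_error(quantize_roi(m, matrix(FALSE, 2, 2), 32, c(0, 255)),
               "degenerate ROI")
})

test_that("first-order features match hand values and conventions", {
  v <- first_order_features(rep(7, 20))
  expect_equal(v[["fo_mean"]], 7)
  expect_equal(v[["fo_variance"]], 0)
  expect_equal(v[["fo_skewness"]], 0)
  expect_equal(v[["fo_kurtosis"]], 0)
  expect_equal(v[["fo_uniformity"]], 1)
  expect_equal(v[["fo_entropy"]], 0)
  expect_equal(v[["fo_cv"]], 0)
  w <- first_order_features(c(1, 2, 3, 4))
  expect_equal(w[["fo_mean"]], 2.5)
  expect_equal(w[["fo_range"]], 3)
  expect_equal(w[["fo_rms"]], sqrt(7.5))
  expect_error(first_order_features(numeric(0)), "degenerate ROI")
})

test_that("first-order features agree with the direct-definition oracle", {
  for (s in 1:100) {
    set.seed(s)
    x <- runif(100, 0, 255)
    expect_equal(first_order_features(x), oracle_first_order(x),
                 tolerance = 1e-10)
  }
})

test_that("GLCM matches the hand-enumerated 1x4 example", {
  reg <- feature_registry(levels = 2)
  q <- matrix(c(0L, 0L, 1L, 1L), 1, 4)
  v <- glcm_features(q, reg)
  expect_equal(v[["glcm_contrast_a000"]], 1 / 3)
  expect_equal(v[["glcm_asm_a000"]], 10 / 36)
  # constant ROI: single co-occurrence cell for every offset
  qc <- matrix(0L, 5, 5)
  vc <- glcm_features(qc, feature_registry(levels = 8))
  for (a in c("a000", "a045", "a090", "a135")) {
    expect_equal(vc[[paste0("glcm_contrast_", a)]], 0)
    expect_equal(vc[[paste0("glcm_asm_", a)]], 1)
    expect_equal(vc[[paste0("glcm_max_prob_", a)]], 1)
    expect_equal(vc[[paste0("glcm_correlation_", a)]], 0)
  }
})

test_that("GLCM features agree with the pair-enumeration oracle", {
  reg <- feature_registry(levels = 8)
  for (s in 1:100) {
    set.seed(s)
    q <- matrix(sample(0:7, 64, replace = TRUE), 8, 8)
    # irregular mask on some instances
    if (s %% 3 == 0) q[sample(64, 10)] <- NA
    expect_equal(glcm_features(q, reg),
                 oracle_glcm(q, 8, reg$offsets), tolerance = 1e-10)
  }
})

test_that("GLCM co-occurrence matrices are symmetric with unit mass", {
  reg <- feature_registry()
  r <- random_roi(16, 16, 11)
  q <- quantize_roi(r, matrix(TRUE, 16, 16), 32, range(r))
  for (off in reg$offsets) {
    P <- vidradiomics:::glcm_matrix(q, off, 32)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(P, t(P), tolerance = 1e-15)
  }
  v <- glcm_features(q, reg)
  for (a in c("a000", "a045", "a090", "a135"))
    expect_equal(v[[paste0("glcm_energy_", a)]]^2,
                 v[[paste0("glcm_asm_", a)]], tolerance = 1e-12)
})

test_that("LBP histograms: constant ROI, normalisation, rotation invariance", {
  msk <- matrix(TRUE, 12, 12)
  h <- lbp_features(matrix(5, 12, 12), msk)
  # constant region: every code is the all-ones uniform pattern (P ones)
  expect_equal(h[["lbp_p8r1_b08"]], 1)
  expect_equal(sum(h[1:10]), 1, tolerance = 1e-12)
  expect_equal(h[["lbp_p16r2_b16"]], 1)
  r <- random_roi(14, 14, 21)
  h2 <- lbp_features(r, matrix(TRUE, 14, 14))
  expect_equal(sum(h2[1:10]), 1, tolerance = 1e-12)
  expect_equal(sum(h2[11:28]), 1, tolerance = 1e-12)
  # rotating the image by 90 degrees leaves the P=8 histogram unchanged
  r90 <- t(r)[ncol(r):1, ]
  h90 <- lbp_features(r90, matrix(TRUE, 14, 14))
  expect_equal(h2[1:10], h90[1:10], tolerance = 1e-10)
  # an ROI too small for any full neighbourhood yields an all-zero histogram
  tiny <- matrix(TRUE, 2, 2)
  expect_true(all(lbp_features(matrix(1, 2, 2), tiny) == 0))
})

test_that("LBP agrees with the neighbourhood-loop oracle", {
  reg <- feature_registry()
  for (s in 1:20) {
    r <- random_roi(12, 12, 100 + s)
    msk <- matrix(TRUE, 12, 12)
    if (s %% 2 == 0) msk[sample(144, 20)] <- FALSE
    got <- lbp_features(r, msk, reg)
    expect_equal(unname(got[1:10]), oracle_lbp_hist(r, msk, 8, 1),
                 tolerance = 1e-10)
    expect_equal(unname(got[11:28]), oracle_lbp_hist(r, msk, 16, 2),
                 tolerance = 1e-10)
  }
})

test_that("static extraction yields a finite frames-by-91 matrix in registry order", {
  cfg <- tiny_config(n_cases = 2, seed = 4)
  cs <- generate_cohort(cfg)[[1]]
  reg <- feature_registry()
  sfm <- extract_static_features(cs$frames, cs$truth_masks, reg,
                                 case_id = cs$case_id)
  expect_equal(dim(sfm), c(cfg$frame_count, 93))
  expect_identical(names(sfm)[-(1:2)], reg$names)
  expect_false(anyNA(sfm))
  expect_true(all(vapply(sfm[-1], function(cc) all(is.finite(cc)) ||
                           is.character(cc), logical(1))))
  # identical frames give identical rows
  sfm2 <- extract_static_features(cs$frames[c(1, 1)],
                                  cs$truth_masks[c(1, 1)], reg)
  expect_equal(as.numeric(sfm2[1, -(1:2)]), as.numeric(sfm2[2, -(1:2)]))
})

test_that("degenerate ROIs (single pixel, constant) still produce finite rows", {
  f <- matrix(100, 8, 8)
  m1 <- matrix(FALSE, 8, 8); m1[4, 4] <- TRUE
  sfm <- extract_static_features(list(f), list(m1))
  expect_false(anyNA(sfm))
  expect_true(all(is.finite(as.numeric(sfm[1, -(1:2)]))))
  mc <- matrix(TRUE, 8, 8)
  sfm2 <- extract_static_features(list(f), list(mc))
  expect_true(all(is.finite(as.numeric(sfm2[1, -(1:2)]))))
})
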