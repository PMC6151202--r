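test_that("co-occurrence matrices are normalized symmetric probability tables", {
  for (s in 1:3) {
    g <- rand_gray(24, 24, seed = s)
    for (a in c(0, 45, 90, 135)) {
      P <- compute_glcm(g, d = 4, theta = a)
      expect_true(all(P >= 0))
      expect_equal(sum(P), 1, tolerance = 1e-12)
      expect_equal(unclass(P), t(unclass(P)), ignore_attr = TRUE)
    }
  }
})

test_that("degenerate images give degenerate co-occurrence structure", {
  # constant image: single diagonal entry 1
  P <- compute_glcm(matrix(100, 16, 16), d = 2, theta = 0)
  expect_equal(sum(diag(unclass(P))), 1)
  expect_equal(max(P), 1)
  # period-2 vertical stripes at d = 2, 0 degrees: offset lands on the same
  # phase, so all co-occurring pairs are equal-valued
  stripes <- matrix(c(0, 255), 16, 16, byrow = TRUE)
  P2 <- unclass(compute_glcm(stripes, d = 2, theta = 0))
  expect_equal(sum(P2 * (row(P2) != col(P2))), 0)
})

test_that("co-occurrence matrices match exhaustive pair enumeration", {
  m <- matrix(c(0, 40, 80, 120,
                160, 200, 240, 0,
                40, 80, 120, 160,
                200, 240, 0, 40), 4, 4, byrow = TRUE)
  expect_equal(unclass(compute_glcm(m, 2, 45)), naive_glcm(m, 2, 45),
               tolerance = 1e-12, ignore_attr = TRUE)
  for (s in 1:3) {
    g <- rand_gray(16, 16, seed = 10 + s)
    for (a in c(0, 45, 90, 135)) {
      expect_equal(unclass(compute_glcm(g, 4, a)), naive_glcm(g, 4, a),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("Haralick statistics agree with the double-loop oracle", {
  for (s in 1:5) {
    g <- rand_gray(8, 8, seed = 20 + s)
    P <- compute_glcm(g, 2, 45, levels = 8)
    expect_equal(glcm_statistics(P), naive_glcm_stats(unclass(P)),
                 tolerance = 1e-10)
  }
})

test_that("Haralick statistics have the known closed forms on tiny matrices", {
  # single-entry diagonal matrix (constant image)
  P1 <- matrix(0, 8, 8); P1[3, 3] <- 1
  expect_equal(glcm_statistics(P1),
               c(contrast = 0, correlation = 0, energy = 1, homogeneity = 1))
  # two-level checker: mass split equally on the two extreme off-diagonal cells
  L <- 8
  P2 <- matrix(0, L, L); P2[1, L] <- 0.5; P2[L, 1] <- 0.5
  s <- glcm_statistics(P2)
  expect_equal(s[["contrast"]], (L - 1)^2)
  expect_equal(s[["energy"]], 0.5)
  expect_equal(s[["homogeneity"]], 1 / (1 + (L - 1)^2))
  expect_equal(s[["correlation"]], -1)
})

test_that("unnormalized or invalid matrices are rejected", {
  expect_error(glcm_statistics(matrix(1, 4, 4)), "normalized")
  expect_error(compute_glcm(matrix(0, 4, 4), d = 8, theta = 0), "too small")
  expect_error(compute_glcm(matrix(0, 16, 16), 2, 30), "theta")
  expect_error(quantize_gray(matrix(0, 4, 4), levels = 1), "at least 2")
})

test_that("the 64-feature block has fixed order and rotation symmetry", {
  g <- rand_gray(32, 32, seed = 7)
  blk <- glcm_feature_block(g)
  expect_length(blk, 64)
  expect_identical(names(blk)[1:4],
                   paste0("glcm_d2_a0_",
                          c("contrast", "correlation", "energy",
                            "homogeneity")))
  # constant image: contrast 0, energy 1 everywhere
  cb <- glcm_feature_block(matrix(42, 32, 32))
  expect_true(all(cb[grepl("contrast", names(cb))] == 0))
  expect_true(all(cb[grepl("energy", names(cb))] == 1))
  # 90-degree rotation of a square image permutes orientations exactly:
  # 0 <-> 90 and 45 <-> 135 under symmetric counting
  blk_rot <- glcm_feature_block(rot90_mat(g))
  swap <- function(nm) {
    nm <- sub("_a0_", "_aX_", nm); nm <- sub("_a90_", "_a0_", nm)
    nm <- sub("_aX_", "_a90_", nm)
    nm <- sub("_a45_", "_aY_", nm); nm <- sub("_a135_", "_a45_", nm)
    sub("_aY_", "_a135_", nm)
  }
  expect_equal(unname(blk_rot[swap(names(blk))]), unname(blk),
               tolerance = 1e-12)
})
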