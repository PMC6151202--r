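test_that("the NCA objective matches a brute-force double loop on a tiny instance", {
  set.seed(1)
  x <- matrix(rnorm(12), 6, 2)
  y <- rnorm(6)
  lambda <- 1 / 6
  for (w in list(c(1, 1), c(0.5, 2), c(0, 1.3))) {
    A <- lapply(1:2, function(m) abs(outer(x[, m], x[, m], `-`)))
    Lmat <- abs(outer(y, y, `-`))
    expect_equal(aestex:::nca_objective(w, A, Lmat, lambda),
                 naive_nca_objective(w, x, y, lambda), tolerance = 1e-12)
  }
})

test_that("fitting is deterministic, monotone, and inert for constant responses", {
  set.seed(2)
  x <- matrix(rnorm(40), 20, 2)
  y <- x[, 1] + rnorm(20, sd = 0.2)
  f1 <- nca_fit(x, y)
  f2 <- nca_fit(x, y)
  expect_identical(f1$weights, f2$weights)
  expect_true(all(diff(f1$trace) <= 1e-12))
  expect_lte(f1$trace[length(f1$trace)], f1$trace[1])
  expect_true(all(f1$weights >= 0))
  # constant response: zero gradient, weights stay at initialization
  expect_message(fc <- nca_fit(x, rep(3, 20)), "constant")
  expect_equal(unname(fc$weights), c(1, 1))
  expect_error(nca_fit(x[1:2, ], y[1:2]), "at least 3")
  expect_error(nca_fit(rbind(x, NA), c(y, 1)), "non-finite")
})

test_that("an informative feature dominates the learned weights", {
  wins <- 0L
  for (s in 1:20) {
    set.seed(500 + s)
    x <- matrix(rnorm(200 * 5), 200, 5)
    y <- 3 * x[, 1] + rnorm(200, sd = 0.1)
    fit <- nca_fit(x, y)
    if (which.max(fit$weights) == 1L) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("standardization protects the ranking from arbitrary column scales", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(600 + s)
    x <- matrix(rnorm(150 * 6), 150, 6)
    y <- 3 * x[, 1] - 2 * x[, 2] + rnorm(150, sd = 0.2)
    x[, 6] <- x[, 6] * 100          # pure-noise column, inflated scale
    sel <- rank_and_select(nca_fit(x, y), k = 2)
    if (!(6L %in% sel$index)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("ranking orders by weight with index tie-breaks", {
  sel <- rank_and_select(c(a = 0.1, b = 0.9, c = 0.5), k = 2)
  expect_equal(sel$index, c(2L, 3L))
  expect_equal(sel$f_label, c("f1", "f2"))
  tie <- rank_and_select(c(x = 1, y = 1, z = 1), k = 2)
  expect_equal(tie$index, c(1L, 2L))
  expect_error(rank_and_select(c(1, 2), k = 3), "between 1 and")
  # the published weight column reproduces the published ordering
  ref <- reference_catalog()
  shuffled <- sample(seq_len(10))
  w <- stats::setNames(ref$weight[shuffled], ref$id[shuffled])
  sel10 <- rank_and_select(w, k = 10)
  expect_identical(sel10$id, ref$id)
  expect_equal(sel10$weight, ref$weight)
})

test_that("the frozen catalog maps f1..f10 onto the documented features", {
  ref <- reference_catalog()
  expect_equal(nrow(ref), 10)
  expect_identical(ref$f_label, paste0("f", 1:10))
  expect_identical(ref$id[ref$f_label == "f7"], "tam_coarseness")
  expect_identical(ref$category[ref$f_label == "f7"], "tamura")
  f10 <- ref[ref$f_label == "f10", ]
  expect_identical(f10$category, "wavelet")
  expect_match(f10$parameter, "Vertical subband at level 1")
  expect_match(f10$name, "L1 norm")
  expect_identical(ref$id[ref$f_label == "f1"], "col_mean_s")
  # all ids exist in the 106-feature catalog
  expect_true(all(ref$id %in% feature_catalog()$id))
})

test_that("informative features reach the top of a 20-feature pool", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(700 + s)
    x <- matrix(rnorm(300 * 20), 300, 20)
    y <- 2 * x[, 1] + 2 * x[, 2] - 2 * x[, 3] + rnorm(300, sd = 0.5)
    sel <- rank_and_select(nca_fit(x, y, max_iter = 60), k = 5)
    if (all(c(1L, 2L, 3L) %in% sel$index)) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.9)
})
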