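test_that("preprocessing transforms are exactly replayable and robust", {
  d <- tibble::tibble(a = c(0, 10), b = c(5, 5))
  pp <- suppressMessages(preprocess_features(d, winsorize = FALSE))
  # population-SD z-scoring: (0, 10) -> (-1, +1); constant column -> 0
  expect_equal(pp$data$a, c(-1, 1))
  expect_equal(pp$data$b, c(0, 0))
  # replay reproduces the transformed table bit-exactly
  expect_identical(apply_transform(pp$transform, d), pp$data)
  # winsorization caps an isolated spike before scaling
  set.seed(3)
  d2 <- tibble::tibble(x = c(rnorm(30), 1000))
  pp2 <- preprocess_features(d2)
  expect_lt(max(abs(pp2$data$x)), 5)
  expect_error(preprocess_features(d2[1, ]), "at least 2")
})

test_that("the train/test split is seeded, disjoint and 90/10 by default", {
  sp <- split_train_test(151, seed = 4)
  expect_length(sp$train, 136)
  expect_length(sp$test, 15)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:151)
  expect_identical(sp, split_train_test(151, seed = 4))
  expect_false(identical(sp$train, split_train_test(151, seed = 5)$train))
  expect_equal(length(split_train_test(10, seed = 1)$train), 9)
  expect_error(split_train_test(9), "at least 10")
})

test_that("the candidate basis enumerates the documented term family", {
  b <- build_basis(data.frame(x1 = 1:4, x2 = 5:8))
  expect_setequal(b$name, c("1", "x1", "x2", "x1^2", "x2^2", "x1*x2"))
  b10 <- build_basis(as.data.frame(matrix(rnorm(50), 5, 10,
                                          dimnames = list(NULL, paste0("f", 1:10)))))
  expect_equal(nrow(b10), 1 + 10 + 10 + choose(10, 2))
  # domain screening drops log/sqrt candidates on negative columns
  neg <- data.frame(x1 = c(-1, 1, 2), x2 = c(1, 2, 3))
  expect_message(bn <- build_basis(neg, unaries = c("log", "sqrt")),
                 "domain-violating")
  expect_false(any(c("log(x1)", "sqrt(x1)") %in% bn$name))
  expect_true(all(c("log(x2)", "sqrt(x2)") %in% bn$name))
  expect_error(build_basis(data.frame()), "at least one column")
})

test_that("greedy selection recovers exact targets and respects the penalty", {
  set.seed(6)
  d <- tibble::tibble(x1 = rnorm(50), x2 = rnorm(50))
  # realizable noiseless target: recovered to machine precision, few terms
  lf <- fit_layer(d, 2 + 3 * d$x1, config = fit_config(unaries = character()))
  expect_lte(lf$metrics$mae, 1e-9)
  expect_true("x1" %in% expr_vars(lf$expression))
  expect_lte(length(lf$expression$terms), 3)
  # constant response: constant-only expression of complexity 1
  lc <- fit_layer(d, rep(4, 50), config = fit_config())
  expect_equal(length(lc$expression$terms), 1)
  expect_equal(expr_complexity(lc$expression), 1)
  expect_equal(lc$metrics$mae, 0)
  # objective trace is non-increasing
  ln <- fit_layer(d, d$x1 - d$x2 + rnorm(50, sd = 0.1),
                  config = fit_config())
  expect_true(all(diff(ln$objective_trace) <= 1e-12))
  # a large penalty collapses the fit to the constant model
  lbig <- fit_layer(d, 2 + 3 * d$x1, config = fit_config(alpha = 1e6))
  expect_equal(length(lbig$expression$terms), 1)
})

test_that("an interaction term is found quickly when it drives the response", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(800 + s)
    d <- tibble::tibble(x1 = rnorm(200), x2 = rnorm(200), x3 = rnorm(200))
    y <- d$x1 * d$x2 + rnorm(200, sd = 0.01)
    lf <- fit_layer(d, y, config = fit_config(max_terms = 3,
                                              unaries = character()))
    nms <- vapply(lf$expression$terms, aestex:::term_name, character(1))
    if ("x1*x2" %in% nms) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("a noiseless realizable hierarchy is recovered on held-out samples", {
  # bounded synthetic feature values keep the unclamped planted model strictly
  # on the rating scale, so the target stays exactly realizable in the basis
  feats <- rand_f_tbl(60, seed = 12)
  feats$texture_id <- sprintf("t%03d", 1:60)
  cfg <- study_config(noise_sd = 0, outlier_prob = 0, clip = FALSE, seed = 12)
  truth <- plant_hierarchy(feats, seed = 12, clip = FALSE, clamp = FALSE)
  expect_true(all(abs(truth$values) < 100))
  study <- gen_annotation_study(feats["texture_id"], cfg, features = feats,
                                truth = truth)
  agg <- aggregate_ratings(study$ratings)
  hf <- suppressMessages(
    fit_hierarchy(feats, agg, fit_config(seed = 12, winsorize = FALSE,
                                         unaries = character())))
  expect_true(all(hf$metrics$mae_test <= 1e-6))
  expect_equal(hf$stage_widths, c(10L, 13L, 17L))
})

test_that("held-out rows cannot influence preprocessing or term selection", {
  suite <- gen_texture_suite(40, seed = 13)
  feats <- select_features(extract_features_tbl(suite$image,
                                                ids = suite$texture_id))
  study <- gen_annotation_study(suite, study_config(seed = 13),
                                features = feats)
  agg <- aggregate_ratings(study$ratings)
  cfg <- fit_config(seed = 13)
  hf1 <- suppressMessages(fit_hierarchy(feats, agg, cfg))
  # scramble the held-out rows' features and ratings
  test_ids <- feats$texture_id[hf1$split$test]
  feats2 <- feats
  feats2[feats2$texture_id %in% test_ids, -1] <-
    feats2[feats2$texture_id %in% test_ids, -1] * 3 + 1
  agg2 <- dplyr::mutate(agg, rating = ifelse(texture_id %in% test_ids,
                                             -rating / 2, rating))
  hf2 <- suppressMessages(fit_hierarchy(feats2, agg2, cfg))
  for (p in property_schema()$property) {
    expect_equal(hf2$model$expressions[[p]], hf1$model$expressions[[p]])
  }
  expect_equal(hf2$model$thresholds, hf1$model$thresholds)
  # thresholds are the layer-wise training-rating minima
  wide <- tidyr::pivot_wider(agg[, c("texture_id", "property", "rating")],
                             names_from = "property", values_from = "rating")
  wide <- wide[match(feats$texture_id, wide$texture_id), ]
  expect_equal(unname(hf1$model$thresholds["R0"]),
               min(as.matrix(wide[hf1$split$train, c("G1", "G2", "G3")])))
})

test_that("fitted hierarchies predict, tidy and summarise coherently", {
  suite <- gen_texture_suite(40, seed = 14)
  feats <- select_features(extract_features_tbl(suite$image,
                                                ids = suite$texture_id))
  study <- gen_annotation_study(suite, study_config(seed = 14),
                                features = feats)
  hf <- suppressMessages(
    fit_hierarchy(feats, aggregate_ratings(study$ratings),
                  fit_config(seed = 14)))
  pr <- predict(hf, feats)
  expect_identical(names(pr), c("texture_id", property_schema()$property))
  # predict() replays the stored pipeline: matches stored predictions
  expect_equal(pr$Q, hf$predictions$Q, tolerance = 1e-9)
  td <- tidy(hf)
  expect_equal(nrow(td), 8)
  expect_true(all(c("expression", "complexity", "mae_test", "r_test")
                  %in% names(td)))
  gl <- glance(hf)
  expect_equal(gl$n_train + gl$n_test, 40)
  p <- autoplot(hf)
  expect_s3_class(p, "ggplot")
})
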