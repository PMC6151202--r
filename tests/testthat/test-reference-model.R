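test_that("constant terms survive zero features exactly", {
  G <- eval_affective(f_zeros)
  expect_equal(G$G1, -8094.8087)
  expect_equal(G$G2, -2.4097)
  expect_equal(G$G3, -17383.3439)
  # zero features put f1 = f3 = 0 in the T1 ratio denominator
  expect_error(eval_judgment(f_zeros, G), "denominator")
})

test_that("judgment and emotional constants follow hand arithmetic", {
  m <- reference_model()
  t4 <- eval_expr(m$expressions$T4,
                  c(as.list(f_zeros), list(G2 = -2.4097)))
  expect_equal(t4, 4.3881e3 + 1.8217 * (-2.4097))
  q0 <- eval_expr(m$expressions$Q,
                  c(as.list(f_zeros), list(G1 = 0, T3 = 0)))
  expect_equal(q0, 38.4474)
  q1 <- eval_expr(m$expressions$Q,
                  list(f1 = 1, f2 = 0, f3 = 0, f4 = 0, f5 = 0, f6 = 0,
                       f7 = 0, f8 = 0, f9 = 0, f10 = 0, G1 = 0, T3 = 0))
  expect_equal(q1, 38.4474 - 10.7260)
})

test_that("all-ones features reproduce the term-by-term oracle through every layer", {
  G <- eval_affective(f_ones)
  oG <- oracle_affective(f_ones)
  expect_equal(unlist(G), oG, tolerance = 1e-12, ignore_attr = TRUE)
  T_ <- eval_judgment(f_ones, G)
  oT <- oracle_judgment(f_ones, oG)
  expect_equal(unlist(T_), oT, tolerance = 1e-12, ignore_attr = TRUE)
  Q <- eval_emotional(f_ones, G, T_)
  expect_equal(Q$Q, unname(oracle_emotional(f_ones, oG, oT)),
               tolerance = 1e-12)
})

test_that("full-layer evaluation matches the oracle at 100 random feature points", {
  f <- rand_f_tbl(100, seed = 99)   # positive features keep Eq-domain valid
  pred <- predict_layers(f)
  orc <- t(apply(as.matrix(f), 1, oracle_layers))
  for (p in colnames(orc)) {
    expect_equal(pred[[p]], unname(orc[, p]), tolerance = 1e-9)
  }
})

test_that("the hierarchy is strictly feed-forward with the printed dependencies", {
  m <- reference_model()
  expect_setequal(expr_vars(m$expressions$Q), c("f1", "f8", "T3", "G1"))
  expect_setequal(expr_vars(m$expressions$G2), "f7")
  # affective expressions consume features only
  for (p in c("G1", "G2", "G3")) {
    expect_true(all(grepl("^f[0-9]+$", expr_vars(m$expressions[[p]]))))
  }
  # judgment expressions consume features and G only
  for (p in c("T1", "T2", "T3", "T4")) {
    expect_true(all(grepl("^f[0-9]+$|^G[123]$", expr_vars(m$expressions[[p]]))))
  }
  # perturbing judgment values never changes affective outputs
  f <- rand_f_tbl(5, seed = 3)
  expect_identical(eval_affective(f), eval_affective(f))
  G <- eval_affective(f)
  T1 <- eval_judgment(f, G)
  Q_a <- eval_emotional(f, G, T1)
  T2 <- dplyr::mutate(T1, T1 = T1 + 100, T2 = T2 - 50, T4 = 0)
  Q_b <- eval_emotional(f, G, T2)
  expect_identical(Q_a, Q_b)  # Q reads only T3
})

test_that("non-finite inputs and the ambiguous-term toggle are handled", {
  bad <- f_ones; bad["f4"] <- NaN
  expect_error(eval_affective(bad), "non-finite")
  f <- rand_f_tbl(3, seed = 8)
  G <- eval_affective(f)
  alt <- reference_model(eq7 = "product")
  t1_ratio <- eval_judgment(f, G)$T1
  t1_prod <- eval_judgment(f, G, model = alt)$T1
  expect_false(isTRUE(all.equal(t1_ratio, t1_prod)))
})

test_that("the shipped JSON asset reproduces the built-in reference model", {
  path <- system.file("extdata", "reference_model.json", package = "aestex")
  skip_if(path == "", "asset not installed")
  m <- read_model(path)
  f <- rand_f_tbl(10, seed = 21)
  expect_equal(predict_layers(f, m), predict_layers(f), tolerance = 1e-15)
})

test_that("metrics follow the textbook formulas and the node-count convention", {
  expect_equal(model_metrics(c(1, 2, 3), c(1, 2, 3))$mae, 0)
  expect_equal(model_metrics(c(1, 2, 3), c(1, 2, 3))$r, 1)
  expect_equal(model_metrics(c(0, 0), c(1, -1))$mae, 1)
  set.seed(5)
  a <- rnorm(50); b <- rnorm(50)
  mm <- model_metrics(a, b)
  expect_equal(mm$mae, sum(abs(a - b)) / 50, tolerance = 1e-12)
  expect_equal(mm$r,
               sum((a - mean(a)) * (b - mean(b))) /
                 sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)),
               tolerance = 1e-12)
  expect_error(model_metrics(1, 1), "at least 2")
  expect_error(model_metrics(c(1, 2), c(3, 3)), "zero variance")
  # node-count: c0 + c1*f7 -> 5 (two constants, one variable, one product,
  # one sum), the value the published complexity table reports for the same
  # equation shape
  m <- reference_model()
  expect_equal(expr_complexity(m$expressions$G2), 5)
  expect_equal(model_metrics(a, b, m$expressions$G2)$complexity, 5)
})
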