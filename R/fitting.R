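# Staged fitting of the three-layer hierarchy: robust feature preprocessing,
# a seeded 90/10 split, and greedy forward selection of basis terms with
# least-squares coefficient refits under a complexity penalty.

#' Robust feature preprocessing (smoothing + normalization)
#'
#' Per column: winsorize at median +/- 3 MAD (the smoothing step, suppressing
#' isolated extreme values), then z-score using the mean and population
#' standard deviation (divisor `n`) of the winsorized column. Statistics are
#' computed only from the rows given here (the training rows); the returned
#' transform record replays the identical affine clamp + scale on any other
#' table. Columns with zero variance are centered to 0 and noted. Columns
#' whose MAD is 0 while the variance is not skip the winsorization clamp.
#'
#' @param data Data frame with at least 2 rows.
#' @param cols Columns to transform (default: all numeric columns).
#' @param winsorize Apply the +/- 3 MAD clamp (default TRUE).
#' @return List with `data` (transformed tibble, untouched columns preserved)
#'   and `transform` (record for [apply_transform()]).
#' @export
preprocess_features <- function(data, cols = NULL, winsorize = TRUE) {
  if (nrow(data) < 2L) stop("need at least 2 rows", call. = FALSE)
  if (is.null(cols)) {
    cols <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  rec <- purrr::map(cols, function(cn) {
    v <- data[[cn]]
    lo <- -Inf; hi <- Inf
    if (winsorize) {
      md <- stats::median(v); mad <- stats::mad(v)
      if (mad > 0) { lo <- md - 3 * mad; hi <- md + 3 * mad }
    }
    w <- pmin(pmax(v, lo), hi)
    mu <- mean(w)
    sdev <- sqrt(mean((w - mu)^2))
    if (sdev == 0) {
      rlang::inform(paste0("feature `", cn, "` has zero variance; set to 0"))
    }
    list(col = cn, lo = lo, hi = hi, mu = mu, sd = sdev)
  })
  names(rec) <- cols
  transform <- structure(list(records = rec), class = "aes_transform")
  list(data = apply_transform(transform, data), transform = transform)
}

#' Replay a recorded feature transform
#'
#' @param transform An `aes_transform` from [preprocess_features()].
#' @param data Data frame holding the recorded columns.
#' @return Tibble with the recorded columns transformed, others untouched.
#' @export
apply_transform <- function(transform, data) {
  stopifnot(inherits(transform, "aes_transform"))
  out <- tibble::as_tibble(data)
  for (r in transform$records) {
    v <- pmin(pmax(out[[r$col]], r$lo), r$hi)
    out[[r$col]] <- if (r$sd == 0) v - r$mu else (v - r$mu) / r$sd
  }
  out
}

#' Seeded train/test partition
#'
#' Random, disjoint and exhaustive; the training share is
#' `round(train_frac * n)`, 90% by default, mirroring the evaluation
#' protocol of the study design.
#'
#' @param n Number of samples (`n >= 10`).
#' @param train_frac Training fraction in (0, 1); default 0.9.
#' @param seed Integer seed making the partition reproducible.
#' @return List with integer index vectors `train` and `test`.
#' @examples
#' split_train_test(151, seed = 1)$train |> length()  # 136
#' @export
split_train_test <- function(n, train_frac = 0.9, seed = 1L) {
  if (n < 10L) stop("need at least 10 samples to split", call. = FALSE)
  if (train_frac <= 0 || train_frac >= 1) {
    stop("`train_frac` must be in (0, 1)", call. = FALSE)
  }
  n_train <- round(train_frac * n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  train <- sort(sample.int(n, n_train))
  list(train = train, test = setdiff(seq_len(n), train))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Fitting configuration
#'
#' @param train_frac Training fraction (default 0.9).
#' @param alpha Complexity penalty: a candidate term is only accepted if it
#'   lowers `MAE + alpha * complexity` (default 0.01 rating units per node).
#' @param max_terms Maximum number of terms per expression, constant included
#'   (default 7).
#' @param degree,unaries,ratios Basis options, see [build_basis()].
#' @param winsorize Preprocessing clamp, see [preprocess_features()].
#' @param seed Seed for the train/test split.
#' @return List of class `aes_fit_config`.
#' @export
fit_config <- function(train_frac = 0.9, alpha = 0.01, max_terms = 7L,
                       degree = 2L, unaries = c("sin", "cos", "exp"),
                       ratios = FALSE, winsorize = TRUE, seed = 1L) {
  stopifnot(alpha >= 0, max_terms >= 1L)
  structure(list(train_frac = train_frac, alpha = alpha,
                 max_terms = as.integer(max_terms), degree = degree,
                 unaries = unaries, ratios = ratios, winsorize = winsorize,
                 seed = seed),
            class = "aes_fit_config")
}

# least-squares refit of the active term set; returns NULL on rank deficiency
ls_refit <- function(M, y) {
  fit <- stats::lm.fit(M, y)
  beta <- fit$coefficients
  if (anyNA(beta)) return(NULL)
  list(beta = beta, fitted = as.vector(M %*% beta))
}

active_expr <- function(basis, active, beta) {
  aes_expr(purrr::map2(basis$term[active], beta, function(tm, b) {
    expr_term(unname(b), tm$factors)
  }))
}

#' Greedy forward fit of one activation expression
#'
#' Starts from the constant term and, at each step, adds the candidate term
#' that most reduces `MAE + alpha * complexity` on the training data, with a
#' full least-squares refit of all coefficients after each addition. Stops
#' when no candidate improves the objective or `max_terms` is reached.
#' Candidates whose addition makes the design singular are skipped.
#'
#' @param data Data frame of input columns (training rows).
#' @param y Numeric response (training rows).
#' @param basis Optional precomputed [build_basis()] result; built from
#'   `data` by default.
#' @param config An [fit_config()].
#' @return List of class `aes_layer_fit`: `expression` (`aes_expr`),
#'   `metrics` (training [model_metrics()]), `objective_trace`
#'   (non-increasing).
#' @export
fit_layer <- function(data, y, basis = NULL, config = fit_config()) {
  if (length(y) < 2L) stop("need at least 2 training rows", call. = FALSE)
  if (is.null(basis)) {
    basis <- build_basis(data, degree = config$degree,
                         unaries = config$unaries, ratios = config$ratios)
  }
  if (nrow(basis) < 1L) stop("empty candidate basis", call. = FALSE)
  M <- basis_matrix(basis, data)
  const_idx <- match("1", basis$name)
  if (is.na(const_idx)) stop("basis must contain the constant term",
                             call. = FALSE)
  active <- const_idx
  fit <- ls_refit(M[, active, drop = FALSE], y)
  expr <- active_expr(basis, active, fit$beta)
  obj <- mean(abs(fit$fitted - y)) + config$alpha * expr_complexity(expr)
  trace <- obj
  best <- list(active = active, fit = fit, expr = expr)
  while (length(active) < config$max_terms) {
    cand <- setdiff(seq_len(nrow(basis)), active)
    step_best <- NULL
    for (ci in cand) {
      idx <- c(active, ci)
      f <- ls_refit(M[, idx, drop = FALSE], y)
      if (is.null(f)) next                     # singular design: skip
      ex <- active_expr(basis, idx, f$beta)
      o <- mean(abs(f$fitted - y)) + config$alpha * expr_complexity(ex)
      if (is.null(step_best) || o < step_best$obj) {
        step_best <- list(obj = o, active = idx, fit = f, expr = ex)
      }
    }
    if (is.null(step_best) || step_best$obj >= obj - 1e-12) break
    active <- step_best$active
    obj <- step_best$obj
    best <- step_best
    trace <- c(trace, obj)
  }
  pred <- as.vector(M[, active, drop = FALSE] %*% best$fit$beta)
  metrics <- if (stats::var(y) > 0) {
    model_metrics(pred, y, best$expr)
  } else {
    tibble::tibble(mae = mean(abs(pred - y)), r = NA_real_,
                   complexity = expr_complexity(best$expr))
  }
  structure(list(expression = best$expr, metrics = metrics,
                 objective_trace = trace),
            class = "aes_layer_fit")
}

#' Fit the full three-layer hierarchy
#'
#' Stage 1 fits the affective activations G1-G3 from the selected features;
#' stage 2 fits the judgment activations T1-T4 from the features plus the
#' *fitted* affective outputs (13 inputs); stage 3 fits the emotional
#' activation Q from features, fitted G and fitted T (17 inputs). Each
#' layer's emotion threshold (R0, R1, R2) is the minimum training rating of
#' that layer's properties, and expressions are fitted to the threshold-
#' subtracted ratings. Preprocessing statistics, thresholds and term
#' selection use training rows only.
#'
#' @param features Tibble with `texture_id` and feature columns `f1` ..
#'   `f10` (see [select_features()]).
#' @param ratings Aggregated ratings from [aggregate_ratings()]
#'   (`texture_id`, `property`, `rating`), all 8 properties present.
#' @param config An [fit_config()].
#' @return Object of class `aes_hierarchy_fit`: the fitted `aes_hmodel`
#'   (`model`), per-property train/test metrics (`metrics`), the feature
#'   `transform`, the index `split`, stored `predictions` (train and test),
#'   and `stage_widths` (10, 13, 17).
#' @export
fit_hierarchy <- function(features, ratings, config = fit_config()) {
  schema <- property_schema()
  wide <- ratings |>
    dplyr::select("texture_id", "property", "rating") |>
    tidyr::pivot_wider(names_from = "property", values_from = "rating")
  missing_p <- setdiff(schema$property, names(wide))
  if (length(missing_p)) {
    stop("missing property rating(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  dat <- dplyr::inner_join(features, wide, by = "texture_id")
  if (nrow(dat) < nrow(features)) {
    rlang::inform(sprintf("%d texture(s) lack ratings and were dropped",
                          nrow(features) - nrow(dat)))
  }
  f_cols <- grep("^f[0-9]+$", names(features), value = TRUE)
  split <- split_train_test(nrow(dat), config$train_frac, config$seed)

  prep <- preprocess_features(dat[split$train, ], cols = f_cols,
                              winsorize = config$winsorize)
  X <- apply_transform(prep$transform, dat)[, f_cols]

  layer_props <- split(schema$property, schema$layer)[c("affective",
                                                        "judgment",
                                                        "emotional")]
  thresholds <- c(R0 = 0, R1 = 0, R2 = 0)
  exprs <- list()
  fits <- list()
  inputs <- X
  stage_widths <- integer(3)
  for (li in 1:3) {
    props <- layer_props[[li]]
    thr <- min(as.matrix(dat[split$train, props]))
    thresholds[li] <- thr
    stage_widths[li] <- ncol(inputs)
    basis <- build_basis(inputs[split$train, , drop = FALSE],
                         degree = config$degree, unaries = config$unaries,
                         ratios = config$ratios)
    preds <- list()
    for (p in props) {
      lf <- fit_layer(inputs[split$train, , drop = FALSE],
                      dat[[p]][split$train] - thr,
                      basis = basis, config = config)
      exprs[[p]] <- lf$expression
      fits[[p]] <- lf
      preds[[p]] <- eval_expr(lf$expression, inputs) + thr
    }
    inputs <- dplyr::bind_cols(inputs, tibble::as_tibble(preds))
  }

  model <- structure(list(expressions = exprs[schema$property],
                          thresholds = thresholds),
                     class = "aes_hmodel")
  pred_tbl <- tibble::as_tibble(inputs[, schema$property]) |>
    dplyr::mutate(texture_id = dat$texture_id, .before = 1)
  # correlation is NA (not an error) when a fold is too small or degenerate
  safe_metrics <- function(pred, obs) {
    tibble::tibble(
      mae = if (length(obs)) mean(abs(pred - obs)) else NA_real_,
      r = if (length(obs) >= 2L && stats::var(obs) > 0) {
        stats::cor(pred, obs)
      } else NA_real_
    )
  }
  metrics <- purrr::map_dfr(schema$property, function(p) {
    pr <- inputs[[p]]; ob <- dat[[p]]
    dplyr::bind_cols(
      tibble::tibble(property = p,
                     layer = schema$layer[schema$property == p]),
      stats::setNames(safe_metrics(pr[split$train], ob[split$train]),
                      c("mae_train", "r_train")),
      tibble::tibble(complexity = expr_complexity(exprs[[p]])),
      stats::setNames(safe_metrics(pr[split$test], ob[split$test]),
                      c("mae_test", "r_test"))
    )
  })
  structure(list(model = model, metrics = metrics,
                 transform = prep$transform, split = split,
                 predictions = pred_tbl,
                 observed = tibble::as_tibble(dat[, c("texture_id",
                                                      schema$property)]),
                 stage_widths = stage_widths, config = config),
            class = "aes_hierarchy_fit")
}

#' @export
print.aes_hierarchy_fit <- function(x, ...) {
  cat(sprintf("<aes_hierarchy_fit> %d train / %d test textures\n",
              length(x$split$train), length(x$split$test)))
  print(x$metrics)
  invisible(x)
}

#' Predict layer values for new textures from a fitted hierarchy
#'
#' @param object An `aes_hierarchy_fit`.
#' @param newdata Tibble with `texture_id` and the feature columns used in
#'   fitting (raw scale; the stored transform is replayed).
#' @param ... Unused.
#' @return Tibble: `texture_id` plus predicted `G1`..`Q`.
#' @export
predict.aes_hierarchy_fit <- function(object, newdata, ...) {
  f_cols <- vapply(object$transform$records, `[[`, character(1), "col")
  X <- apply_transform(object$transform, newdata)[, f_cols]
  schema <- property_schema()
  thr <- stats::setNames(object$model$thresholds[
    c("affective" = 1, "judgment" = 2, "emotional" = 3)[schema$layer]],
    schema$property)
  inputs <- X
  for (p in schema$property) {
    inputs[[p]] <- eval_expr(object$model$expressions[[p]], inputs) +
      unname(thr[p])
  }
  dplyr::bind_cols(tibble::tibble(texture_id = newdata$texture_id),
                   tibble::as_tibble(inputs[, schema$property]))
}
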