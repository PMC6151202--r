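# Procedural textures and simulated rating studies with known ground truth.
# These stand in for a photographic texture database: they span hue,
# saturation, contrast, orientation and scale, but are statistically much
# simpler than real material photographs (see the methods vignette).

#' Describe a procedural texture
#'
#' @param kind One of `"grating"`, `"checkerboard"`, `"filtered-noise"`,
#'   `"blobs"`, `"constant"`.
#' @param orientation Stripe direction in degrees (0 = horizontal stripes,
#'   i.e. intensity varies down the rows); used by gratings.
#' @param freq Grating frequency in cycles per image.
#' @param block Characteristic scale in pixels (checker square, noise
#'   correlation length, blob radius).
#' @param contrast Peak-to-peak luminance contrast in `[0, 1]`; 0 gives a
#'   constant image for every kind.
#' @param hue,saturation HSV color of the texture, each in `[0, 1]`.
#' @param size `c(H, W)` in pixels (default 64 x 64).
#' @param seed Seed for the stochastic kinds (noise, blobs).
#' @return List of class `aes_recipe`.
#' @export
texture_recipe <- function(kind = c("grating", "checkerboard",
                                    "filtered-noise", "blobs", "constant"),
                           orientation = 0, freq = 8, block = 8,
                           contrast = 1, hue = 0.5, saturation = 0.5,
                           size = c(64L, 64L), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(contrast >= 0, contrast <= 1, hue >= 0, hue <= 1,
            saturation >= 0, saturation <= 1, length(size) == 2L,
            all(size >= 32L), freq > 0, block >= 1)
  structure(list(kind = kind, orientation = orientation, freq = freq,
                 block = block, contrast = contrast, hue = hue,
                 saturation = saturation, size = as.integer(size),
                 seed = as.integer(seed)),
            class = "aes_recipe")
}

hsv_to_rgb255 <- function(h, s, v) {
  # vectorized HSV -> RGB, all inputs on [0,1], outputs on [0,255]; scalars
  # are broadcast against the value matrix
  dm <- dim(v)
  n <- length(v)
  h <- rep_len(as.vector(h), n); s <- rep_len(as.vector(s), n)
  v <- as.vector(v)
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  pick <- function(c0, c1, c2, c3, c4, c5) {
    out <- c0
    out[i == 1] <- c1[i == 1]; out[i == 2] <- c2[i == 2]
    out[i == 3] <- c3[i == 3]; out[i == 4] <- c4[i == 4]
    out[i == 5] <- c5[i == 5]
    out
  }
  shape <- function(x) {
    m <- round(255 * x)
    dim(m) <- dm
    m
  }
  list(r = shape(pick(v, q, p, p, t, v)),
       g = shape(pick(t, v, v, q, p, p)),
       b = shape(pick(p, p, t, v, v, q)))
}

value_pattern <- function(recipe) {
  h <- recipe$size[1]; w <- recipe$size[2]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  amp <- recipe$contrast / 2
  switch(recipe$kind,
    constant = matrix(0.5, h, w),
    grating = {
      phi <- recipe$orientation * pi / 180
      u <- cos(phi) * rows + sin(phi) * cols
      0.5 + amp * sin(2 * pi * recipe$freq * u / max(h, w))
    },
    checkerboard = {
      parity <- (floor((rows - 1) / recipe$block) +
                   floor((cols - 1) / recipe$block)) %% 2
      0.5 + amp * (2 * parity - 1)
    },
    `filtered-noise` = {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
      set.seed(recipe$seed)
      z <- matrix(stats::rnorm(h * w), h, w)
      sigma <- max(recipe$block / 2, 0.5)
      r <- ceiling(3 * sigma)
      k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
      # separable Gaussian blur with edge replication
      blur1 <- function(m) {
        out <- matrix(0, nrow(m), ncol(m))
        for (oo in -r:r) out <- out + k[oo + r + 1] * shift_clamped(m, oo, 0L)
        out
      }
      z <- t(blur1(t(blur1(z))))
      z <- (z - mean(z)) / max(stats::sd(z), 1e-12)
      0.5 + amp * pmin(pmax(z / 2.5, -1), 1)
    },
    blobs = {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
      set.seed(recipe$seed)
      n_blob <- max(3L, round(h * w / (pi * recipe$block^2) / 6))
      cy <- stats::runif(n_blob, 1, h); cx <- stats::runif(n_blob, 1, w)
      z <- matrix(0, h, w)
      for (b in seq_len(n_blob)) {
        z <- z + exp(-((rows - cy[b])^2 + (cols - cx[b])^2) /
                       (2 * recipe$block^2))
      }
      rng <- range(z)
      z <- if (diff(rng) > 0) (z - rng[1]) / diff(rng) else z * 0 + 0.5
      0.5 + amp * (2 * z - 1)
    }
  )
}

#' Generate a procedural texture image
#'
#' Deterministic in the recipe (including its seed). The value channel
#' carries the spatial pattern with the requested contrast around mid-gray;
#' hue and saturation are constant over the image.
#'
#' @param recipe An [texture_recipe()].
#' @return An [texture_image()].
#' @examples
#' img <- gen_texture(texture_recipe("checkerboard", block = 8))
#' @export
gen_texture <- function(recipe) {
  stopifnot(inherits(recipe, "aes_recipe"))
  v <- value_pattern(recipe)
  ch <- hsv_to_rgb255(recipe$hue, recipe$saturation, v)
  texture_image(array(c(ch$r, ch$g, ch$b), dim = c(dim(v), 3L)))
}

#' Generate a suite of textures spanning the recipe space
#'
#' Recipes are laid out by seeded Latin-hypercube sampling over orientation,
#' scale, contrast, hue and saturation, cycling through the four textured
#' kinds, so that every one of the 106 features varies across the suite.
#'
#' @param n Number of textures (the emulated study used 151).
#' @param seed Integer seed.
#' @param size Image size `c(H, W)` for every texture (default 64 x 64).
#' @return Tibble with columns `texture_id`, `kind`, `recipe` (list) and
#'   `image` (list of [texture_image()]).
#' @export
gen_texture_suite <- function(n, seed = 1L, size = c(64L, 64L)) {
  stopifnot(n >= 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  u <- lhs::randomLHS(n, 5L)
  kinds <- rep(c("grating", "checkerboard", "filtered-noise", "blobs"),
               length.out = n)
  recipes <- purrr::map(seq_len(n), function(i) {
    texture_recipe(
      kind = kinds[i],
      orientation = 180 * u[i, 1],
      freq = 2 + 14 * u[i, 2],
      block = 4 + round(12 * u[i, 2]),
      contrast = 0.3 + 0.7 * u[i, 3],
      hue = u[i, 4],
      saturation = u[i, 5],
      size = size,
      seed = seed * 10000L + i
    )
  })
  tibble::tibble(
    texture_id = sprintf("tex_%03d", seq_len(n)),
    kind = kinds,
    recipe = recipes,
    image = purrr::map(recipes, gen_texture)
  )
}

#' Synthetic rating-study configuration
#'
#' Defaults emulate the study design: a panel of 20 raters scoring each
#' texture on all 8 properties on the open (-100, 100) scale, with Gaussian
#' rater noise (SD 5) and a 5% chance that a score is replaced by an extreme
#' outlier.
#'
#' @param n_raters Panel size (`>= 3`; default 20).
#' @param noise_sd Rater noise SD in rating units (default 5).
#' @param outlier_prob Per-score probability of an extreme outlier
#'   (default 0.05).
#' @param outlier_range Magnitude range of the injected deviation
#'   (default 45 to 85 rating units, random sign).
#' @param clip Saturate the planted model's response to features beyond
#'   3 robust SDs (default TRUE; see vignette).
#' @param seed Integer seed.
#' @return List of class `aes_study_config`.
#' @export
study_config <- function(n_raters = 20L, noise_sd = 5, outlier_prob = 0.05,
                         outlier_range = c(45, 85), clip = TRUE, seed = 1L) {
  stopifnot(n_raters >= 3L, noise_sd >= 0, outlier_prob >= 0,
            outlier_prob <= 1)
  structure(list(n_raters = as.integer(n_raters), noise_sd = noise_sd,
                 outlier_prob = outlier_prob, outlier_range = outlier_range,
                 clip = clip, seed = as.integer(seed)),
            class = "aes_study_config")
}

# robust per-column standardization used by the planted ground truth: center
# at the median, scale by MAD, optionally clip at +/- 3 (perceptual
# saturation of extreme feature values)
robust_z <- function(X, clip = TRUE) {
  out <- purrr::map(X, function(v) {
    md <- stats::median(v); s <- stats::mad(v)
    if (s == 0) s <- max(stats::sd(v), 1e-12)
    z <- (v - md) / s
    if (clip) z <- pmin(pmax(z, -3), 3)
    z
  })
  tibble::as_tibble(out)
}

#' Plant a ground-truth hierarchical model on a feature table
#'
#' Builds a simple, basis-realizable hierarchy (per property: an intercept,
#' two linear terms, and one pairwise product over robust-standardized
#' selected features; judgment properties additionally read one affective
#' value and the emotional property reads T3) with coefficients drawn from a
#' seeded generator and scaled so true ratings stay inside (-100, 100).
#'
#' @param f Tibble of selected feature values (`f1` .. `f10` columns;
#'   `texture_id` optional).
#' @param seed Integer seed.
#' @param clip See [study_config()].
#' @param clamp Clamp true ratings to `[-90, 90]` so rater noise rarely
#'   pushes scores against the scale boundary (default TRUE).
#' @return Object of class `aes_truth`: functions and tables to evaluate the
#'   noiseless ground truth, plus `values`, the true ratings for `f`.
#' @export
plant_hierarchy <- function(f, seed = 1L, clip = TRUE, clamp = TRUE) {
  f_cols <- grep("^f[0-9]+$", names(f), value = TRUE)
  Z <- robust_z(f[, f_cols], clip = clip)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  schema <- property_schema()
  draw <- function(prop, layer) {
    vs <- sample(f_cols, 2L)
    list(property = prop, layer = layer,
         intercept = stats::runif(1, -10, 10),
         lin_vars = vs, lin_coefs = stats::runif(2, 5, 10) *
           sample(c(-1, 1), 2L, replace = TRUE),
         prod_coef = stats::runif(1, 2, 4) * sample(c(-1, 1), 1L),
         up_var = switch(layer,
                         affective = NA_character_,
                         judgment = sample(c("G1", "G2", "G3"), 1L),
                         emotional = "T3"),
         up_coef = stats::runif(1, 0.3, 0.6))
  }
  specs <- purrr::map2(schema$property, schema$layer, draw)
  names(specs) <- schema$property
  truth <- structure(list(specs = specs, clip = clip, clamp = clamp,
                          seed = seed),
                     class = "aes_truth")
  truth$values <- eval_truth(truth, f)
  truth
}

#' Evaluate a planted ground-truth model
#'
#' @param truth An `aes_truth` from [plant_hierarchy()].
#' @param f Tibble with the selected feature columns.
#' @return Tibble of true ratings, one column per property.
#' @export
eval_truth <- function(truth, f) {
  f_cols <- grep("^f[0-9]+$", names(f), value = TRUE)
  Z <- robust_z(f[, f_cols], clip = truth$clip)
  vals <- list()
  for (sp in truth$specs) {
    v <- sp$intercept +
      sp$lin_coefs[1] * Z[[sp$lin_vars[1]]] +
      sp$lin_coefs[2] * Z[[sp$lin_vars[2]]] +
      sp$prod_coef * Z[[sp$lin_vars[1]]] * Z[[sp$lin_vars[2]]]
    if (!is.na(sp$up_var)) v <- v + sp$up_coef * vals[[sp$up_var]]
    vals[[sp$property]] <- if (isTRUE(truth$clamp)) pmin(pmax(v, -90), 90)
    else v
  }
  tibble::as_tibble(vals)
}

#' Simulate a semantic-differential rating study
#'
#' For every texture, property and rater, the score is the planted true
#' rating plus Gaussian noise, clamped strictly inside (-100, 100); with
#' probability `outlier_prob` the score is instead pushed by an extreme
#' deviation (random sign, magnitude in `outlier_range`). The injection log
#' allows outlier-screening efficacy to be measured against ground truth.
#'
#' @param suite Tibble from [gen_texture_suite()], or any tibble with a
#'   `texture_id` column matching `features`.
#' @param config An [study_config()].
#' @param features Optional precomputed selected-feature table
#'   (`texture_id` + `f1` .. `f10`); extracted from the suite images via the
#'   published selection when omitted.
#' @param truth Optional `aes_truth`; planted with the config seed when
#'   omitted.
#' @return List of class `aes_study`: `ratings` (texture_id, property,
#'   rater_id, score), `truth_values` (noiseless true ratings), `truth`
#'   (the planted model), `features`, `injections` (log of injected
#'   outliers), `config`.
#' @export
gen_annotation_study <- function(suite, config = study_config(),
                                 features = NULL, truth = NULL) {
  if (is.null(features)) {
    feats <- extract_features_tbl(suite$image, ids = suite$texture_id)
    features <- select_features(feats)
  }
  if (is.null(truth)) {
    truth <- plant_hierarchy(features, seed = config$seed, clip = config$clip)
  }
  tv <- eval_truth(truth, features)
  schema <- property_schema()
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  eps <- 1e-6
  grid <- tidyr::expand_grid(
    texture_id = features$texture_id,
    property = schema$property,
    rater_id = sprintf("r%02d", seq_len(config$n_raters))
  )
  truth_long <- dplyr::mutate(tv, texture_id = features$texture_id) |>
    tidyr::pivot_longer(-"texture_id", names_to = "property",
                        values_to = "truth")
  grid <- dplyr::left_join(grid, truth_long, by = c("texture_id", "property"))
  n <- nrow(grid)
  score <- grid$truth + stats::rnorm(n, sd = config$noise_sd)
  is_out <- stats::runif(n) < config$outlier_prob
  dev <- sample(c(-1, 1), n, replace = TRUE) *
    stats::runif(n, config$outlier_range[1], config$outlier_range[2])
  score[is_out] <- grid$truth[is_out] + dev[is_out]
  score <- pmin(pmax(score, -100 + eps), 100 - eps)
  ratings <- dplyr::mutate(grid[, c("texture_id", "property", "rater_id")],
                           score = score)
  structure(list(
    ratings = ratings,
    truth_values = dplyr::mutate(tv, texture_id = features$texture_id,
                                 .before = 1),
    truth = truth,
    features = features,
    injections = dplyr::mutate(ratings[is_out, ],
                               truth = grid$truth[is_out]),
    config = config
  ), class = "aes_study")
}

#' @export
print.aes_study <- function(x, ...) {
  cat(sprintf(
    "<aes_study> %d textures x %d properties x %d raters (%d injected outliers)\n",
    dplyr::n_distinct(x$ratings$texture_id), 8L, x$config$n_raters,
    nrow(x$injections)))
  invisible(x)
}
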