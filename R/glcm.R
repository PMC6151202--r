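# Gray-level co-occurrence features.
#
# Orientation convention for an offset (row, col) displacement at distance d:
#   0 degrees   -> ( 0,  d)   horizontal neighbour
#   45 degrees  -> (-d,  d)
#   90 degrees  -> (-d,  0)   vertical neighbour
#   135 degrees -> (-d, -d)
# Counting is symmetric: each ordered pair is counted in both directions, so
# every matrix is symmetric and 180-degree offsets are redundant.

glcm_offset <- function(d, theta) {
  switch(as.character(theta),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop("`theta` must be one of 0, 45, 90, 135", call. = FALSE)
  )
}

#' Quantize a luminance image to discrete gray levels
#'
#' Uniform binning of `[0, 255]` into `L` levels, returning integer levels in
#' `0 .. L - 1`.
#'
#' @param gray H x W numeric matrix in `[0, 255]`.
#' @param levels Number of gray levels `L` (default 16).
#' @return Integer matrix of the same shape.
#' @export
quantize_gray <- function(gray, levels = 16L) {
  if (levels < 2L) stop("`levels` must be at least 2", call. = FALSE)
  q <- floor(gray * levels / 256)
  q[q > levels - 1L] <- levels - 1L
  q[q < 0L] <- 0L
  storage.mode(q) <- "integer"
  q
}

#' Gray-level co-occurrence matrix
#'
#' Computes the symmetric, normalized co-occurrence matrix of gray-level pairs
#' at pixel distance `d` and orientation `theta` after uniform quantization to
#' `levels` gray levels. Entries are pair probabilities (non-negative, summing
#' to 1); the matrix is symmetric because each pair is counted in both
#' directions.
#'
#' @param gray H x W numeric matrix in `[0, 255]` (or an already-quantized
#'   integer matrix if `quantized = TRUE`).
#' @param d Pixel distance, one of 2, 4, 6, 8 (other positive integers are
#'   accepted for experimentation).
#' @param theta Orientation in degrees: 0, 45, 90 or 135.
#' @param levels Number of gray levels (default 16).
#' @param quantized Set `TRUE` if `gray` already holds levels `0 .. levels-1`.
#' @return An `L x L` matrix of class `aes_glcm` with attributes `d`, `theta`,
#'   `levels`.
#' @export
compute_glcm <- function(gray, d, theta, levels = 16L, quantized = FALSE) {
  stopifnot(is.matrix(gray), d >= 1)
  q <- if (quantized) gray else quantize_gray(gray, levels)
  off <- glcm_offset(as.integer(d), theta)
  h <- nrow(q); w <- ncol(q)
  r_lo <- max(1L, 1L - off[1]); r_hi <- min(h, h - off[1])
  c_lo <- max(1L, 1L - off[2]); c_hi <- min(w, w - off[2])
  if (r_lo > r_hi || c_lo > c_hi) {
    stop("image too small for offset d = ", d, call. = FALSE)
  }
  rows <- r_lo:r_hi
  cols <- c_lo:c_hi
  a <- q[rows, cols, drop = FALSE]
  b <- q[rows + off[1], cols + off[2], drop = FALSE]
  counts <- matrix(
    tabulate(as.vector(a) * levels + as.vector(b) + 1L, nbins = levels^2),
    levels, levels, byrow = TRUE
  )
  sym <- counts + t(counts)
  P <- sym / sum(sym)
  structure(P, class = c("aes_glcm", "matrix", "array"),
            d = as.integer(d), theta = theta, levels = as.integer(levels))
}

#' Haralick statistics of a co-occurrence matrix
#'
#' The four statistics used per (distance, orientation) cell of the feature
#' catalog: contrast, correlation, energy (angular second moment) and
#' homogeneity (inverse difference moment). Correlation is defined as 0 when
#' either marginal variance vanishes.
#'
#' @param P A normalized (sums to 1, non-negative) co-occurrence matrix.
#' @return Named numeric vector `c(contrast, correlation, energy, homogeneity)`.
#' @export
glcm_statistics <- function(P) {
  P <- unclass(P)
  if (!is.matrix(P) || nrow(P) != ncol(P)) {
    stop("`P` must be a square matrix", call. = FALSE)
  }
  if (any(P < 0) || abs(sum(P) - 1) > 1e-9) {
    stop("`P` must be a normalized co-occurrence matrix (non-negative, sum 1)",
         call. = FALSE)
  }
  L <- nrow(P)
  i <- matrix(0:(L - 1), L, L)           # row level
  j <- t(i)                              # column level
  contrast    <- sum(P * (i - j)^2)
  energy      <- sum(P^2)
  homogeneity <- sum(P / (1 + (i - j)^2))
  px <- rowSums(P); py <- colSums(P)
  mx <- sum((0:(L - 1)) * px); my <- sum((0:(L - 1)) * py)
  vx <- sum((0:(L - 1) - mx)^2 * px); vy <- sum((0:(L - 1) - my)^2 * py)
  correlation <- if (vx <= 0 || vy <= 0) 0 else {
    (sum(i * j * P) - mx * my) / sqrt(vx * vy)
  }
  c(contrast = contrast, correlation = correlation,
    energy = energy, homogeneity = homogeneity)
}

glcm_distances    <- c(2L, 4L, 6L, 8L)
glcm_orientations <- c(0L, 45L, 90L, 135L)
glcm_stat_names   <- c("contrast", "correlation", "energy", "homogeneity")

#' The 64 co-occurrence features of a luminance image
#'
#' Four Haralick statistics at each of four distances (2, 4, 6, 8 pixels) and
#' four orientations (0, 45, 90, 135 degrees): 4 x 4 x 4 = 64 values. Order is
#' fixed: distance outermost, then orientation, then statistic, matching the
#' feature catalog (`glcm_d2_a0_contrast`, `glcm_d2_a0_correlation`, ...).
#'
#' @inheritParams compute_glcm
#' @return Named numeric vector of length 64.
#' @export
glcm_feature_block <- function(gray, levels = 16L) {
  q <- quantize_gray(gray, levels)
  out <- unlist(lapply(glcm_distances, function(d) {
    lapply(glcm_orientations, function(a) {
      glcm_statistics(compute_glcm(q, d, a, levels, quantized = TRUE))
    })
  }))
  names(out) <- as.vector(vapply(
    glcm_distances,
    function(d) vapply(glcm_orientations, function(a) {
      paste0("glcm_d", d, "_a", a, "_", glcm_stat_names)
    }, character(4)),
    character(16)
  ))
  out
}
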