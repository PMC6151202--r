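# Tamura perceptual texture features: coarseness, contrast, directionality.
# Parameters follow the classic formulation: dyadic averaging windows 2^k for
# k = 1..5, Prewitt gradient masks, a 16-bin orientation histogram over
# [0, pi) and a gradient-magnitude threshold of 12 on the 0-255 scale.

# Mean over a centred s x s window, borders handled by edge replication.
box_mean <- function(m, s) {
  h <- nrow(m); w <- ncol(m)
  lo <- -(s %/% 2L); hi <- lo + s - 1L
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  # pad by edge replication, then use a summed-area table
  ri <- clamp(seq(1L + lo, h + hi), h)
  ci <- clamp(seq(1L + lo, w + hi), w)
  p <- m[ri, ci, drop = FALSE]
  sat <- apply(apply(p, 2L, cumsum), 1L, cumsum)  # transposed SAT
  sat <- t(sat)
  zpad <- function(x) rbind(0, cbind(0, x))
  S <- zpad(sat)
  r1 <- seq_len(h); c1 <- seq_len(w)
  (S[r1 + s, c1 + s, drop = FALSE] - S[r1, c1 + s, drop = FALSE] -
     S[r1 + s, c1, drop = FALSE] + S[r1, c1, drop = FALSE]) / s^2
}

# shift a matrix by (dr, dc) with edge clamping
shift_clamped <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  m[pmin(pmax(seq_len(h) + dr, 1L), h), pmin(pmax(seq_len(w) + dc, 1L), w),
    drop = FALSE]
}

#' Tamura coarseness
#'
#' At every pixel, the dyadic window size `2^k` (k = 1 .. `k_max`) that
#' maximizes the difference between averages of opposing neighbourhoods is
#' chosen (ties broken toward the smallest window, so a featureless image has
#' coarseness 2); the feature is the mean optimal size over all pixels.
#' Larger values mean coarser (blockier) texture.
#'
#' @param gray H x W numeric matrix in `[0, 255]`.
#' @param k_max Largest dyadic exponent considered; capped so the window fits
#'   inside the image (default 5, i.e. windows up to 32 x 32).
#' @return A scalar `>= 2`.
#' @export
tamura_coarseness <- function(gray, k_max = 5L) {
  h <- nrow(gray); w <- ncol(gray)
  if (min(h, w) < 4L) {
    stop("image too small for the smallest 2 x 2 coarseness window",
         call. = FALSE)
  }
  k_max <- min(k_max, floor(log2(min(h, w))) - 1L)
  best_e <- matrix(-Inf, h, w)
  best_k <- matrix(1L, h, w)
  for (k in seq_len(k_max)) {
    s <- 2L^k
    half <- s %/% 2L
    A <- box_mean(gray, s)
    eh <- abs(shift_clamped(A, 0L, half) - shift_clamped(A, 0L, -half))
    ev <- abs(shift_clamped(A, half, 0L) - shift_clamped(A, -half, 0L))
    e <- pmax(eh, ev)
    upd <- e > best_e + 1e-12   # strict: ties keep the smaller window
    best_k[upd] <- k
    best_e[upd] <- e[upd]
  }
  mean(2^best_k)
}

#' Tamura contrast
#'
#' `sigma / alpha4^(1/4)` where `alpha4 = mu4 / sigma^4` is the kurtosis of
#' the gray-level distribution (population moments). Defined as 0 for
#' zero-variance images.
#'
#' @inheritParams tamura_coarseness
#' @return A non-negative scalar.
#' @export
tamura_contrast <- function(gray) {
  v <- as.vector(gray)
  mu <- mean(v)
  s2 <- mean((v - mu)^2)
  if (s2 <= 0) return(0)
  alpha4 <- mean((v - mu)^4) / s2^2
  sqrt(s2) / alpha4^0.25
}

#' Tamura directionality
#'
#' Builds a 16-bin histogram of gradient orientations over `[0, pi)` from
#' Prewitt differences, keeping pixels whose gradient magnitude
#' `(|dH| + |dV|) / 2` exceeds `threshold`, and reports one minus the
#' normalized second moment of the histogram about its peak (wrapped bin
#' distance). The result lies in `[0, 1]`; an ideal grating approaches 1,
#' while isotropic noise stays well below. Returns 0 with a warning when no
#' gradient clears the threshold (no orientation evidence).
#'
#' @inheritParams tamura_coarseness
#' @param n_bins Number of orientation bins (default 16).
#' @param threshold Gradient-magnitude threshold on the 0-255 scale
#'   (default 12).
#' @return A scalar in `[0, 1]`.
#' @export
tamura_directionality <- function(gray, n_bins = 16L, threshold = 12) {
  h <- nrow(gray); w <- ncol(gray)
  if (h < 3L || w < 3L) stop("image too small for 3 x 3 gradient masks",
                             call. = FALSE)
  ri <- 2:(h - 1); ci <- 2:(w - 1)
  # Prewitt masks, valid interior only
  dh <- (gray[ri - 1, ci + 1] + gray[ri, ci + 1] + gray[ri + 1, ci + 1] -
           gray[ri - 1, ci - 1] - gray[ri, ci - 1] - gray[ri + 1, ci - 1]) / 3
  dv <- (gray[ri - 1, ci - 1] + gray[ri - 1, ci] + gray[ri - 1, ci + 1] -
           gray[ri + 1, ci - 1] - gray[ri + 1, ci] - gray[ri + 1, ci + 1]) / 3
  mag <- (abs(dh) + abs(dv)) / 2
  keep <- mag >= threshold
  if (!any(keep)) {
    rlang::warn("no gradient magnitude above threshold; directionality is 0",
                class = "aestex_no_orientation")
    return(0)
  }
  theta <- (atan2(dv[keep], dh[keep])) %% pi
  bin <- pmin(floor(theta / pi * n_bins), n_bins - 1L)
  hist <- tabulate(bin + 1L, nbins = n_bins)
  p <- hist / sum(hist)
  peak <- which.max(p) - 1L
  dist <- abs(seq_len(n_bins) - 1L - peak)
  dist <- pmin(dist, n_bins - dist)          # wrapped distance, max n_bins/2
  1 - sum(p * (dist / (n_bins / 2))^2)
}
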