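# 2-D discrete wavelet transform with the 4-tap Daubechies (D4) filter and
# periodic boundary handling. Periodization keeps the transform orthonormal,
# so detail/approximation energies add up exactly to the image energy
# (Parseval), which the energy-signature features rely on.

d4_lo <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
d4_hi <- rev(d4_lo) * c(1, -1, 1, -1)

# one analysis step along dim 1 (rows); input must have an even row count
dwt_step <- function(X, filt) {
  n <- nrow(X)
  ks <- seq(1L, n, by = 2L)
  out <- matrix(0, n / 2L, ncol(X))
  for (m in 0:3) {
    out <- out + filt[m + 1L] * X[((ks - 1L + m) %% n) + 1L, , drop = FALSE]
  }
  out
}

even_pad <- function(X) {
  # replicate the last row/column when a dimension is odd; exact Parseval is
  # guaranteed when both dimensions are multiples of 2^levels
  if (nrow(X) %% 2L == 1L) X <- rbind(X, X[nrow(X), , drop = FALSE])
  if (ncol(X) %% 2L == 1L) X <- cbind(X, X[, ncol(X), drop = FALSE])
  X
}

# single-level 2-D decomposition: returns LL approximation and the three
# detail bands. "h" holds horizontal structure (variation down the rows,
# e.g. a horizontal edge), "v" vertical structure, "d" diagonal.
dwt2_level <- function(X) {
  X <- even_pad(X)
  lo_r <- dwt_step(X, d4_lo)          # lowpass along rows
  hi_r <- dwt_step(X, d4_hi)
  lo <- function(M) t(dwt_step(t(M), d4_lo))
  hi <- function(M) t(dwt_step(t(M), d4_hi))
  list(a = lo(lo_r), h = lo(hi_r), v = hi(lo_r), d = hi(hi_r))
}

#' Multi-level 2-D wavelet decomposition
#'
#' Orthonormal D4 decomposition with periodic extension. Returns the detail
#' subbands of each level and the final approximation.
#'
#' @param gray H x W numeric matrix.
#' @param levels Number of decomposition levels (default 4).
#' @return List with `details` (list per level of `h`, `v`, `d` matrices) and
#'   `approx` (final LL band).
#' @export
dwt2 <- function(gray, levels = 4L) {
  min_side <- 2L^levels
  if (min(dim(gray)) < min_side) {
    stop(sprintf("image must be at least %d x %d for %d wavelet levels",
                 min_side, min_side, levels), call. = FALSE)
  }
  details <- vector("list", levels)
  A <- gray
  for (l in seq_len(levels)) {
    dec <- dwt2_level(A)
    details[[l]] <- dec[c("h", "v", "d")]
    A <- dec$a
  }
  list(details = details, approx = A)
}

#' Wavelet energy signatures
#'
#' For each of the three high-frequency subbands (horizontal, vertical,
#' diagonal) of the first `levels` decomposition levels, computes three
#' statistics: the per-coefficient L1 norm `mean(|c|)`, the per-coefficient
#' L2 norm `sqrt(mean(c^2))`, and the Shannon entropy of the normalized
#' squared coefficients `p_i = c_i^2 / sum(c^2)` (natural log, `0 log 0 = 0`;
#' an all-zero subband has entropy 0). With the default 4 levels this yields
#' 36 features in catalog order: level, then subband (h, v, d), then
#' statistic (l1norm, l2norm, entropy).
#'
#' @inheritParams dwt2
#' @return Named numeric vector of length `3 * 3 * levels` (36 by default).
#' @export
wavelet_signatures <- function(gray, levels = 4L) {
  dec <- dwt2(gray, levels)
  stats3 <- function(cf) {
    v <- as.vector(cf)
    v[abs(v) < 1e-9] <- 0   # suppress numerical dust (inputs are 0-255 scale)
    l1 <- mean(abs(v))
    l2 <- sqrt(mean(v^2))
    e <- sum(v^2)
    ent <- if (e <= 0) 0 else {
      p <- v^2 / e
      p <- p[p > 0]
      -sum(p * log(p))
    }
    c(l1norm = l1, l2norm = l2, entropy = ent)
  }
  out <- unlist(lapply(seq_len(levels), function(l) {
    lapply(c("h", "v", "d"), function(b) stats3(dec$details[[l]][[b]]))
  }))
  names(out) <- as.vector(vapply(seq_len(levels), function(l) {
    vapply(c("h", "v", "d"), function(b) {
      paste0("wav_", b, l, "_", c("l1norm", "l2norm", "entropy"))
    }, character(3))
  }, character(9)))
  out
}
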