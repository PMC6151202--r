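# Independent brute-force oracles. These re-derive the quantities the package
# computes, by direct enumeration or plain arithmetic, and share no code with
# the implementation.

# exhaustive pair-enumeration co-occurrence matrix (symmetric, normalized)
naive_glcm <- function(gray, d, theta, levels = 16) {
  q <- pmin(floor(gray * levels / 256), levels - 1)
  off <- switch(as.character(theta),
                "0" = c(0, d), "45" = c(-d, d),
                "90" = c(-d, 0), "135" = c(-d, -d))
  counts <- matrix(0, levels, levels)
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(ncol(q))) {
      i2 <- i + off[1]; j2 <- j + off[2]
      if (i2 >= 1 && i2 <= nrow(q) && j2 >= 1 && j2 <= ncol(q)) {
        a <- q[i, j] + 1; b <- q[i2, j2] + 1
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    }
  }
  counts / sum(counts)
}

# double-loop Haralick statistics
naive_glcm_stats <- function(P) {
  L <- nrow(P)
  contrast <- 0; energy <- 0; homog <- 0; eij <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    p <- P[i + 1, j + 1]
    contrast <- contrast + p * (i - j)^2
    energy <- energy + p^2
    homog <- homog + p / (1 + (i - j)^2)
    eij <- eij + p * i * j
  }
  px <- rowSums(P); py <- colSums(P)
  mx <- sum((0:(L - 1)) * px); my <- sum((0:(L - 1)) * py)
  vx <- sum((0:(L - 1))^2 * px) - mx^2
  vy <- sum((0:(L - 1))^2 * py) - my^2
  corr <- if (vx <= 0 || vy <= 0) 0 else (eij - mx * my) / sqrt(vx * vy)
  c(contrast = contrast, correlation = corr, energy = energy,
    homogeneity = homog)
}

naive_glcm_block <- function(gray, levels = 16) {
  out <- c()
  for (d in c(2, 4, 6, 8)) for (a in c(0, 45, 90, 135)) {
    out <- c(out, naive_glcm_stats(naive_glcm(gray, d, a, levels)))
  }
  out
}

# plain moment sums for the Tamura contrast statistic
naive_tamura_contrast <- function(gray) {
  v <- as.vector(gray); n <- length(v)
  mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  m4 <- sum((v - mu)^4) / n
  if (m2 == 0) 0 else sqrt(m2) / (m4 / m2^2)^(1 / 4)
}

# Reference-equation oracle: each published equation transcribed a second
# time as one flat arithmetic expression (no shared code with the term-list
# representation used by the package).
oracle_affective <- function(f) {
  with(as.list(f), c(
    G1 = -8094.8087 + 812.5336 * f8 + 45616.6421 * f9 + 912.3156 * f10 -
      12.2778 * f1 - 193.0201 * f1 * f9 - 3851 * f8 * f9 -
      5152.5354 * f9 * f10,
    G2 = -2.4097 + 2.4427e-3 * f7,
    G3 = -17383.3439 + 1632.0393 * f1 - 8.4352 * f3 + 4091.5619 * f10 -
      179.9276 * f1 * f7 - 1740.2929 * f1 * f9 - 239.9238 * f10^2
  ))
}

oracle_judgment <- function(f, G) {
  with(c(as.list(f), as.list(G)), c(
    T1 = -5802.8782 - 2.6621 * f1 + 1376.0294 * f10 + G3 +
      0.5044 * f3 * G3 - (f8 * G3) / (f1 * f3 * G1) - 81.5644 * f10^2,
    T2 = -120.8679 + 18.7771 * f10 + 6.2114 * f3 * f4 - 16.5658 * f2 * f4 -
      5.0154 * f4 * f9 + 14.4728 * G1 * f9^2,
    T3 = -525.3141 + 22064.1366 * f4 + f7 + 61.6075 * f10 -
      92.5762 * f1 * f8 - 152.7179 * f1 * f2 + 228.3617 * f9^2 -
      5175.2472 * f3 * f4 * f10 + 303.4996 * f3 * f4 * f10^2,
    T4 = 4.3881e3 + 1.8217 * G2 + 71.5439 * f9 + 0.8139 * f7
  ))
}

oracle_emotional <- function(f, G, T_) {
  with(c(as.list(f), as.list(G), as.list(T_)), c(
    Q = 38.4474 - 10.7260 * f1 - 57.6083 * f8 + 0.0914 * T3 +
      1.4546 * f1 * G1
  ))
}

oracle_layers <- function(f) {
  G <- oracle_affective(f)
  T_ <- oracle_judgment(f, G)
  c(G, T_, oracle_emotional(f, G, T_))
}

# brute-force double-loop NCA regression objective
naive_nca_objective <- function(w, x, y, lambda) {
  n <- nrow(x)
  total <- 0
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sum(w^2 * abs(x[i, ] - x[j, ]))
    e <- exp(-d); e[i] <- 0
    p <- e / sum(e)
    total <- total + sum(p * abs(y[i] - y))
  }
  total / n + lambda * sum(w^2)
}
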