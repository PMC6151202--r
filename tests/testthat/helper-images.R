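# small image fixtures, all generated in code

rand_gray <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w, 0, 255), h, w)
}

rand_rgb <- function(h, w, seed) {
  set.seed(seed)
  array(runif(h * w * 3, 0, 255), dim = c(h, w, 3))
}

const_rgb <- function(r, g, b, h = 32, w = 32) {
  array(rep(c(r, g, b), each = h * w), dim = c(h, w, 3))
}

# 90-degree counterclockwise rotation of a matrix
rot90_mat <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# replicate each pixel into a k x k block
block_replicate <- function(m, k) {
  m[rep(seq_len(nrow(m)), each = k), rep(seq_len(ncol(m)), each = k)]
}

f_ones <- stats::setNames(rep(1, 10), paste0("f", 1:10))
f_zeros <- stats::setNames(rep(0, 10), paste0("f", 1:10))

rand_f_tbl <- function(n, seed) {
  set.seed(seed)
  out <- tibble::as_tibble(stats::setNames(
    lapply(1:10, function(i) runif(n, 0.2, 2)), paste0("f", 1:10)))
  out
}
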