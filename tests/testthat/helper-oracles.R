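# Independent oracles and small fixture builders, kept deliberately naive.

# Quadruple-loop valid convolution, the reference for convolve_valid().
naive_convolve <- function(img, w) {
  img <- unclass(img)
  out <- matrix(0, 9, 9)
  for (r in 1:9) for (c in 1:9) {
    acc <- 0
    for (i in 1:20) for (j in 1:20)
      acc <- acc + img[r + i - 1, c + j - 1] * w[i, j]
    out[r, c] <- acc
  }
  out
}

random_image <- function(seed) {
  set.seed(seed)
  gray_image(matrix(sample(0:255, 28 * 28, replace = TRUE), 28, 28))
}

random_filter_weights <- function(seed) {
  set.seed(seed)
  matrix(sample(-128:127, 400, replace = TRUE), 20, 20)
}

# A 4-ON test pattern with ON cells spread over the 4x4 field.
spread_pattern <- function() {
  p <- integer(16); p[c(1, 6, 11, 16)] <- 1L
  p
}
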