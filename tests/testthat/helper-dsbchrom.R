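# Shared fixtures and independent oracles, all built in code.

# Naive double-loop insulation oracle: independent indexing/extraction of
# the sliding square, same arithmetic (sum/length, log2 of ratio to the
# chromosome mean). Used for bit-for-bit equivalence checks.
naive_insulation <- function(counts, square_bins) {
  n <- nrow(counts)
  d <- square_bins
  raw <- rep(NaN, n)
  if (n >= 2 * d + 1) {
    for (i in (d + 1):(n - d)) {
      vals <- numeric(0)
      n_total <- 0L
      for (b in (i + 1):(i + d)) {        # columns outer: storage order
        for (a in (i - d):(i - 1)) {
          n_total <- n_total + 1L
          if (is.finite(counts[a, b])) vals <- c(vals, counts[a, b])
        }
      }
      if (length(vals) < n_total / 2) next
      raw[i] <- sum(vals) / length(vals)
    }
  }
  fin <- is.finite(raw)
  log2(raw / (sum(raw[fin]) / sum(fin)))
}

# random symmetric count matrix, optionally with symmetric NaN masking
rand_sym_matrix <- function(n, lambda = 20, nan_frac = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(0, n, n)
  ut <- upper.tri(m, diag = TRUE)
  m[ut] <- rpois(sum(ut), lambda)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  if (nan_frac > 0) {
    mask <- sample.int(n, max(1, round(nan_frac * n)))
    m[mask, ] <- NaN
    m[, mask] <- NaN
  }
  m
}

# tiny ChIP scenario shared by several tests: one 12 Mb chromosome,
# paper-scale narrow/broad components
tiny_chip_params <- function(seed = 1, ...) {
  sim_params(genome = c(chrA = 12e6), chip_bin_size = 100,
             depth = 5e6, seed = seed, ...)
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
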