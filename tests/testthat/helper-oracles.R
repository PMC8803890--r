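# Independent oracles used across the suite.

# Exhaustive-search simplex prediction: brute-force distance scan,
# explicit exponential weight formula. Stays independent of the
# package's neighbour-search path.
simplex_oracle <- function(points, target, lib, pred, k) {
  vapply(pred, function(q) {
    lib2 <- lib[lib != q]
    d <- sqrt(colSums((t(points[lib2, , drop = FALSE]) - points[q, ])^2))
    o <- order(d)
    kk <- min(k, length(lib2))
    nn_idx <- lib2[o[seq_len(kk)]]
    nn_d <- d[o[seq_len(kk)]]
    d1 <- nn_d[1L]
    w <- if (d1 == 0) as.numeric(nn_d == 0) else exp(-nn_d / d1)
    sum(w * target[nn_idx]) / sum(w)
  }, numeric(1L))
}

# Hand enumeration of lagged tuples for small embedding cases.
embed_oracle <- function(v, E, tau) {
  n <- length(v)
  t0 <- (E - 1) * tau + 1
  rows <- lapply(t0:n, function(t) v[t - (0:(E - 1)) * tau])
  matrix(unlist(rows), nrow = n - t0 + 1, ncol = E, byrow = TRUE)
}

# Differential entropies with closed forms, used as kdp oracles.
H_UNIFORM <- 0
H_GAUSSIAN <- 0.5 * log(2 * pi * exp(1))
H_EXP <- 1
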