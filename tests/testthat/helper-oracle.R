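# Independent brute-force references used to cross-check the package's
# FFT-based cascade and vectorized statistics.  These deliberately share
# no code with the implementation: plain loops, explicit index-wise
# circular wrapping.

# One analysis step by naive summation: a[j] = sum_k f[k] x[(2(j-1)+k-1) mod N + 1]
oracle_analysis_step <- function(x, f) {
  n <- length(x)
  out <- numeric(n / 2)
  for (j in seq_len(n / 2)) {
    s <- 0
    for (k in seq_along(f)) {
      s <- s + f[k] * x[(2 * (j - 1) + k - 1) %% n + 1]
    }
    out[j] <- s
  }
  out
}

# Full packet cascade by naive convolution, natural node order.
oracle_wpt <- function(x, wavelet_name, level) {
  w <- wavelet_filters(wavelet_name)
  block <- 2^level
  padded <- block * ceiling(length(x) / block)
  nodes <- list(c(x, numeric(padded - length(x))))
  for (lev in seq_len(level)) {
    nxt <- list()
    for (nd in nodes) {
      nxt <- c(nxt, list(oracle_analysis_step(nd, w$dec_lo)),
               list(oracle_analysis_step(nd, w$dec_hi)))
    }
    nodes <- nxt
  }
  nodes
}

# Energy / entropy / ratio recomputed coefficient-by-coefficient.
oracle_fitness <- function(coefs, base = exp(1)) {
  e <- 0
  for (c_i in coefs) e <- e + c_i * c_i
  s <- 0
  for (c_i in coefs) {
    p <- c_i * c_i / e
    if (p > 0) s <- s - p * log(p, base = base)
  }
  list(energy = e, entropy = s, ratio = e / s)
}

# Daubechies low-pass filter by spectral factorization of the half-band
# polynomial (extremal-phase root selection) — an independent derivation
# of the shipped filter tables.
oracle_daubechies_lowpass <- function(N) {
  Pc <- choose(N - 1 + 0:(N - 1), 0:(N - 1))
  yr <- polyroot(Pc)
  zs <- vapply(yr, function(y) {
    b <- 2 - 4 * y
    disc <- sqrt(as.complex(b^2 - 4))
    z <- c((b + disc) / 2, (b - disc) / 2)
    z[which.min(Mod(z))]
  }, complex(1))
  pmul <- function(a, b) {
    out <- complex(length(a) + length(b) - 1)
    for (i in seq_along(a)) {
      idx <- i:(i + length(b) - 1)
      out[idx] <- out[idx] + a[i] * b
    }
    out
  }
  h <- 1 + 0i
  for (k in seq_len(N)) h <- pmul(h, c(1, 1))
  for (z in zs) h <- pmul(h, c(-z, 1))
  h <- Re(h)
  h * sqrt(2) / sum(h)
}

# Convenience: a small deterministic tri-axial segment.
make_test_segment <- function(seed = 1, n = 125, label = "walking") {
  set.seed(seed)
  har_segment(matrix(rnorm(3 * n), ncol = 3), label = label)
}
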