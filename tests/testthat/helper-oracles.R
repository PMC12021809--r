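# Brute-force reference implementations used as independent oracles.

# Double-loop normalized pixel-mass Shannon entropy.
entropy_bruteforce <- function(m) {
  tot <- sum(m)
  acc <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      p <- m[i, j] / tot
      if (p > 0) acc <- acc - p * log2(p)
    }
  }
  acc / log2(length(m))
}

# O(n^2) Moran's I with explicit row-normalized rook weight matrix.
moran_bruteforce <- function(m) {
  nr <- nrow(m); nc <- ncol(m); n <- nr * nc
  idx <- function(i, j) (j - 1) * nr + i
  W <- matrix(0, n, n)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      nb <- list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
      nb <- Filter(function(p) p[1] >= 1 && p[1] <= nr &&
        p[2] >= 1 && p[2] <= nc, nb)
      for (p in nb) W[idx(i, j), idx(p[1], p[2])] <- 1
    }
  }
  W <- W / rowSums(W)
  z <- as.vector(m) - mean(m)
  (n / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
}

# Winding-number phase-singularity detection by explicit loop integration
# around every 2x2 plaquette.
ps_bruteforce <- function(phase) {
  wrap <- function(a) atan2(sin(a), cos(a))
  out <- NULL
  for (i in seq_len(nrow(phase) - 1)) {
    for (j in seq_len(ncol(phase) - 1)) {
      s <- wrap(phase[i, j + 1] - phase[i, j]) +
        wrap(phase[i + 1, j + 1] - phase[i, j + 1]) +
        wrap(phase[i + 1, j] - phase[i + 1, j + 1]) +
        wrap(phase[i, j] - phase[i + 1, j])
      w <- round(s / (2 * pi))
      if (w != 0) out <- rbind(out, c(i + 0.5, j + 0.5, w))
    }
  }
  out
}
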