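# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately avoid the package's code paths: quantization,
# counting and transforms are re-derived from first principles.

# Brute-force quantizer: same contract (min-max to 0..n_bins-1, floor,
# top value clamped), written as an explicit per-pixel loop.
oracle_quantize <- function(v, n_bins) {
  v <- as.numeric(v)
  lo <- min(v); hi <- max(v)
  if (lo == hi) return(rep(0L, length(v)))
  q <- integer(length(v))
  for (i in seq_along(v)) {
    b <- floor((v[i] - lo) / (hi - lo) * n_bins)
    q[i] <- if (b >= n_bins) n_bins - 1L else b
  }
  q
}

# Entropy by explicit histogram counting over occupied levels.
oracle_entropy <- function(plane, n_bins = 256L) {
  q <- oracle_quantize(plane, n_bins)
  h <- 0
  for (lev in unique(q)) {
    p <- sum(q == lev) / length(q)
    h <- h - p * log2(p)
  }
  h
}

# Mutual information by the definition: the double sum of
# p(a,b) * log2(p(a,b) / (p(a) p(b))) over occupied joint cells.
oracle_mi_double_sum <- function(a, b, n_bins = 256L) {
  qa <- oracle_quantize(a, n_bins)
  qb <- oracle_quantize(b, n_bins)
  n <- length(qa)
  pa <- table(qa) / n
  pb <- table(qb) / n
  joint <- table(paste(qa, qb))
  mi <- 0
  for (cell in names(joint)) {
    ab <- strsplit(cell, " ")[[1]]
    pab <- joint[[cell]] / n
    mi <- mi + pab * log2(pab / (pa[[ab[1]]] * pb[[ab[2]]]))
  }
  mi
}

# Direct windowed-DFT LPQ code at one pixel (1-based r, c): the 8-bit
# sign code of the 4 low-frequency STFT coefficients, computed from the
# transform's definition without convolution or whitening.
oracle_lpq_code <- function(plane, r, c, window) {
  rr <- (window - 1) / 2
  a <- 1 / window
  freqs <- list(c(a, 0), c(0, a), c(a, a), c(a, -a))  # (ux, uy)
  comps <- numeric(8)
  for (j in 1:4) {
    F <- 0 + 0i
    for (dy in -rr:rr) for (dx in -rr:rr) {
      F <- F + plane[r + dy, c + dx] *
        exp(-2i * pi * (freqs[[j]][1] * dx + freqs[[j]][2] * dy))
    }
    comps[j] <- Re(F)
    comps[j + 4] <- Im(F)
  }
  sum(2^(0:7) * (comps >= 0))
}

rotate90 <- function(m) t(m[nrow(m):1, , drop = FALSE])  # clockwise

chi_square_dist <- function(h1, h2) {
  s <- h1 + h2
  ok <- s > 0
  sum((h1[ok] - h2[ok])^2 / s[ok])
}

# Oriented sinusoid + noise plane, the micro-texture family used across
# the texture tests.
sinusoid_plane <- function(n, orientation_deg, frequency, noise_sd = 0.05,
                           amplitude = 1) {
  th <- orientation_deg * pi / 180
  u <- outer(seq_len(n), rep(1, n)) * sin(th) +
       outer(rep(1, n), seq_len(n)) * cos(th)
  amplitude * sin(2 * pi * frequency * u) +
    noise_sd * matrix(rnorm(n * n), n, n)
}

# Cube with known near-duplicate bands: `duplicates` maps 0-based source
# band -> perturbation sd for one inserted copy (after the source).
fixture_duplicate_cube <- function(n = 32, n_base = 4, duplicates = list(),
                                   label = "", source_id = "<fixture>") {
  bands <- list()
  for (k in seq_len(n_base)) {
    base <- matrix(runif(n * n), n, n)
    bands[[length(bands) + 1L]] <- base
    key <- as.character(k - 1L)
    if (!is.null(duplicates[[key]]))
      bands[[length(bands) + 1L]] <-
        base + duplicates[[key]] * matrix(rnorm(n * n), n, n)
  }
  px <- array(0, c(n, n, length(bands)))
  for (i in seq_along(bands)) px[, , i] <- bands[[i]]
  spectral_cube(px, label = label, source_id = source_id)
}

# concatenate 3-D arrays along columns / rows (for patch reassembly checks)
abind_cols <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2] + dim(b)[2], dim(a)[3]))
  out[, seq_len(dim(a)[2]), ] <- a
  out[, dim(a)[2] + seq_len(dim(b)[2]), ] <- b
  out
}
abind_rows <- function(a, b) {
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}
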