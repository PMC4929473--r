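# Independent brute-force oracles and small image builders shared by the
# tests. The oracles deliberately use naive O(N^2) loops so they stay
# independent of the implementation they check.

# naive mean filter with symmetric-reflect padding
oracle_mean_filter <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  # symmetric reflection with edge repeat, matching the package convention
  reflect <- function(i, n) {
    j <- (i - 1L) %% (2L * n)
    ifelse(j >= n, 2L * n - 1L - j, j) + 1L
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ri <- reflect((i - r):(i + r), h)
    ci <- reflect((j - r):(j + r), w)
    out[i, j] <- mean(m[ri, ci])
  }
  out
}

# naive radial binning of a centered 2D power matrix
oracle_radial <- function(p) {
  h <- nrow(p); w <- ncol(p)
  cy <- h %/% 2 + 1L; cx <- w %/% 2 + 1L
  r_max <- min(cy - 1L, h - cy, cx - 1L, w - cx)
  sums <- numeric(r_max + 1L)
  counts <- integer(r_max + 1L)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    r <- round(sqrt((i - cy)^2 + (j - cx)^2))
    if (r <= r_max) {
      sums[r + 1L] <- sums[r + 1L] + p[i, j]
      counts[r + 1L] <- counts[r + 1L] + 1L
    }
  }
  list(freq_fraction = seq(0L, r_max) / r_max, power = sums / counts)
}

# deterministic pseudo-random test image (values in [0, 255])
random_image <- function(h, w, seed = 1) {
  set.seed(seed)
  matrix(runif(h * w, 0, 255), h, w)
}

# a 1D power-spectrum object assembled by hand, for direct tail_stats tests
ps1d_from <- function(power, method = "summed") {
  structure(list(freq_fraction = seq(0, 1, length.out = length(power)),
                 power = power, method = method),
            class = "power_spectrum_1d")
}

# impulse image: zeros except one central pixel
impulse_image <- function(n = 32L, amplitude = 1000) {
  m <- matrix(0, n, n)
  m[n %/% 2 + 1L, n %/% 2 + 1L] <- amplitude
  m
}
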