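# Frequency-domain measures: normalized 2D power spectrum, reduction to a
# 1D profile (radial average or row/column sums with frequency folding),
# and descriptive statistics of the high-frequency tail.
#
# Blur removes fine detail and attenuates the spectral tail; noise does the
# opposite. Restricting the statistics to frequencies above a threshold
# fraction of the maximum representable frequency removes the contribution
# of large spatial structures, which vary strongly from image to image.

# move the zero-frequency sample to (floor(h/2)+1, floor(w/2)+1)
fftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c((h - h %/% 2 + 1L):h, seq_len(h - h %/% 2)),
    c((w - w %/% 2 + 1L):w, seq_len(w - w %/% 2)), drop = FALSE]
}

#' Normalized 2D power spectrum of an image
#'
#' Computes the squared magnitude of the centered discrete Fourier
#' transform (so all values are non-negative) and divides it by the image
#' average gray level times the total number of pixels. The division makes
#' the spectrum insensitive to image-to-image brightness differences:
#' scaling all pixels by `k > 0` scales the normalized spectrum by exactly
#' `k`, leaving within-dataset rank orders unchanged.
#'
#' Before normalization the spectrum satisfies Parseval's identity:
#' `sum(|F|^2) / N == sum(g^2)`; the `normalization` field records the
#' `(mean gray level, pixel count)` divisor so this can be verified.
#'
#' @param img A [gray_image()] or numeric matrix with positive mean.
#' @return A `power_spectrum_2d`: list with `power` (centered matrix of
#'   non-negative values) and `normalization = c(mean_gray, n_pixels)`.
#' @export
power_spectrum_2d <- function(img) {
  m <- as_matrix(img)
  mu <- mean(m)
  if (mu <= 0) {
    stop("image mean is zero; power-spectrum normalization undefined",
         call. = FALSE)
  }
  p <- fftshift2(Mod(stats::fft(m))^2)
  structure(list(power = p / (mu * length(m)),
                 normalization = c(mean_gray = mu, n_pixels = length(m))),
            class = "power_spectrum_2d")
}

new_ps1d <- function(freq_fraction, power, method) {
  structure(list(freq_fraction = freq_fraction, power = power,
                 method = method),
            class = "power_spectrum_1d")
}

#' Radial average reduction of a 2D power spectrum
#'
#' For each integer radius `r` from 0 to the maximum inscribed radius
#' around the zero-frequency center, averages the power values whose
#' rounded Euclidean distance from the center equals `r`. The frequency
#' axis is expressed as the fraction `r / r_max` of the maximum
#' representable radius, so thresholds are comparable across image sizes.
#'
#' @param ps A `power_spectrum_2d` from [power_spectrum_2d()].
#' @return A `power_spectrum_1d` with `method = "radial"`.
#' @export
reduce_radial <- function(ps) {
  stopifnot(inherits(ps, "power_spectrum_2d"))
  p <- ps$power
  h <- nrow(p); w <- ncol(p)
  cy <- h %/% 2 + 1L; cx <- w %/% 2 + 1L
  r_max <- min(cy - 1L, h - cy, cx - 1L, w - cx)
  d <- round(sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+")))
  keep <- d <= r_max
  idx <- d[keep] + 1L
  sums <- vapply(split(p[keep], idx), sum, numeric(1))
  counts <- tabulate(idx, nbins = r_max + 1L)
  new_ps1d(seq(0L, r_max) / r_max, as.numeric(sums) / counts, "radial")
}

# fold a centered 1D profile: add each negative frequency onto the matching
# positive one; the (unpaired) Nyquist sample of an even-length axis maps to
# the top bin
fold_centered <- function(v) {
  n <- length(v)
  c0 <- n %/% 2 + 1L
  half <- n %/% 2
  out <- numeric(half + 1L)
  out[1L] <- v[c0]
  f <- seq_len(half)
  pos <- ifelse(c0 + f <= n, v[pmin(c0 + f, n)], 0)
  pos[c0 + f > n] <- 0
  out[f + 1L] <- pos + v[c0 - f]
  out
}

#' Summed (row/column) reduction of a 2D power spectrum
#'
#' Adds all rows together and all columns together, giving one profile
#' over horizontal and one over vertical signed frequency; folds each by
#' adding the negative frequencies onto the matching positive ones; and
#' sums the two folded profiles. For a non-square image the shorter
#' profile is linearly interpolated onto the longer one's frequency grid
#' before summing. This reduction involves only additions and is much
#' faster than the radial average, and is the default throughout.
#'
#' @param ps A `power_spectrum_2d` from [power_spectrum_2d()].
#' @return A `power_spectrum_1d` with `method = "summed"`.
#' @export
reduce_summed <- function(ps) {
  stopifnot(inherits(ps, "power_spectrum_2d"))
  p <- ps$power
  prow <- fold_centered(colSums(p))  # over horizontal frequency
  pcol <- fold_centered(rowSums(p))  # over vertical frequency
  nr <- length(prow); nc <- length(pcol)
  if (nr == nc) {
    pw <- prow + pcol
    n <- nr
  } else {
    n <- max(nr, nc)
    grid <- seq(0, 1, length.out = n)
    interp <- function(v) {
      stats::approx(seq(0, 1, length.out = length(v)), v, xout = grid)$y
    }
    pw <- interp(prow) + interp(pcol)
  }
  new_ps1d(seq(0, 1, length.out = n), pw, "summed")
}

#' Tail statistics of a 1D power spectrum
#'
#' Crops the profile to frequencies strictly above `threshold` (a fraction
#' of the maximum frequency) and computes descriptive statistics of the
#' tail power values: `fMean` (mean), `fSTD` (standard deviation),
#' `cv = fSTD/fMean`, moment skewness and excess kurtosis,
#' `spectral_entropy` (Shannon entropy of the tail renormalized to a
#' probability vector, in bits), `high90` (summed power at frequencies
#' above 90% of maximum) and `MeanBin` (mean of the first five tail
#' samples -- a single five-sample-wide bin starting at the threshold).
#'
#' Blur attenuates every one of these; additive noise raises `fMean` and
#' `MeanBin`. A degenerate all-equal tail has `fSTD = 0` and, by
#' convention, zero skewness and kurtosis.
#'
#' @param ps1d A `power_spectrum_1d` from [reduce_summed()] or
#'   [reduce_radial()].
#' @param threshold Frequency threshold in (0, 1); default 0.40. Lower
#'   values (e.g. 0.02) extend the usable blur-detection dynamic range.
#' @return A `spectral_stats`: named list of the eight statistics plus the
#'   `threshold` used.
#' @export
tail_stats <- function(ps1d, threshold = 0.40) {
  stopifnot(inherits(ps1d, "power_spectrum_1d"))
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must be strictly between 0 and 1", call. = FALSE)
  }
  x <- ps1d$power[ps1d$freq_fraction > threshold]
  if (length(x) < 5L) {
    stop("power-spectrum tail has only ", length(x),
         " samples; use a lower `threshold`", call. = FALSE)
  }
  f_mean <- mean(x)
  f_std <- stats::sd(x)
  if (f_std > 0) {
    skew <- e1071::skewness(x, type = 1)
    kurt <- e1071::kurtosis(x, type = 1)
  } else {
    skew <- 0
    kurt <- 0
  }
  tot <- sum(x)
  spec_ent <- if (tot > 0) shannon_entropy(x / tot) else 0
  structure(list(
    fMean = f_mean,
    fSTD = f_std,
    cv = if (f_mean > 0) f_std / f_mean else NA_real_,
    skewness = skew,
    kurtosis = kurt,
    spectral_entropy = spec_ent,
    high90 = sum(ps1d$power[ps1d$freq_fraction > 0.90]),
    MeanBin = mean(x[1:5]),
    threshold = threshold
  ), class = "spectral_stats")
}

#' Invert a dataset-normalized measure
#'
#' Maps a normalized value `v` in `[0, 1]` to `1 - v`. Inversion is only
#' meaningful after dataset normalization; e.g. `invSTD = 1 - fSTD`
#' (normalized) favors non-noisy images, because noise inflates the
#' spectral tail.
#'
#' @param value Numeric vector of normalized values in `[0, 1]`.
#' @return `1 - value`.
#' @export
invert_measure <- function(value) {
  if (any(!is.finite(value)) || any(value < 0) || any(value > 1)) {
    stop("inversion is defined only for dataset-normalized values in [0, 1]",
         call. = FALSE)
  }
  1 - value
}
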