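# Contrast quantification: detail mask + masked histogram + Shannon entropy.
#
# Fluorescence images are mostly dark background, so a raw histogram is
# dominated by background counts. The detail mask keeps only pixels whose
# local mean intensity lies above a percentile of the smoothed image, and
# the histogram entropy is computed over the original values at those
# positions.

# Uniform (box) mean filter of side 2r+1 with symmetric-reflect padding,
# computed with an integral image: O(N) regardless of radius.
uniform_mean_filter <- function(m, radius) {
  h <- nrow(m); w <- ncol(m); r <- radius
  ri <- c(r:1, 1:h, h:(h - r + 1L))         # reflected row indices
  ci <- c(r:1, 1:w, w:(w - r + 1L))
  p <- m[ri, ci]
  # integral image with a zero border
  s <- rbind(0, apply(p, 2L, cumsum))
  s <- cbind(0, t(apply(s, 1L, cumsum)))
  k <- 2L * r + 1L
  i1 <- 1:h; j1 <- 1:w
  (s[i1 + k, j1 + k] - s[i1, j1 + k] - s[i1 + k, j1] + s[i1, j1]) / (k * k)
}

#' Compute the detail mask of an image
#'
#' Smooths the image with a large uniform (averaging) filter of radius
#' `filter_radius` (a square window of side `2r + 1`, symmetric-reflect
#' boundary) and thresholds the smoothed image at its `percentile`-th
#' percentile: the mask selects the pixels whose smoothed value strictly
#' exceeds that threshold, i.e. the neighborhoods with the highest local
#' mean intensity. With the default 80th percentile at most ~20% of the
#' pixels are selected. The smoothing ensures single bright pixels (dust,
#' hot pixels) do not pass for detail. When no pixel strictly exceeds the
#' threshold (heavily tied smoothed images; constant images in the
#' extreme) the comparison falls back to `>=`, which for a constant image
#' yields the all-true mask.
#'
#' When the image is smaller than the filter window, the radius is clamped
#' to `floor(min(dim)/2) - 1` with a warning.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param filter_radius Averaging filter radius in pixels (default 100).
#' @param percentile Threshold percentile in (0, 100), default 80.
#' @return A `detail_mask`: logical matrix of the image shape with a
#'   `coverage` attribute (fraction of pixels selected).
#' @export
compute_detail_mask <- function(img, filter_radius = 100L, percentile = 80) {
  m <- as_matrix(img)
  if (filter_radius < 1L) stop("`filter_radius` must be >= 1", call. = FALSE)
  if (percentile <= 0 || percentile >= 100) {
    stop("`percentile` must be strictly between 0 and 100", call. = FALSE)
  }
  if (filter_radius > nrow(m) && filter_radius > ncol(m)) {
    stop("`filter_radius` (", filter_radius,
         ") exceeds both image dimensions", call. = FALSE)
  }
  min_dim <- min(dim(m))
  if (min_dim < 2L * filter_radius + 1L) {
    clamped <- max(1L, min_dim %/% 2L - 1L)
    warning("filter window larger than image; clamping radius from ",
            filter_radius, " to ", clamped, call. = FALSE)
    filter_radius <- clamped
  }
  f <- uniform_mean_filter(m, as.integer(filter_radius))
  thr <- stats::quantile(f, percentile / 100, names = FALSE)
  mask <- f > thr
  # strict inequality caps coverage at 1 - percentile/100, but a heavily
  # tied smoothed image (flat plateaus; constant images in the extreme)
  # can leave it empty -- relax to >=, which is all-true for a constant
  if (!any(mask)) mask <- f >= thr
  structure(mask, class = c("detail_mask", "matrix", "array"),
            coverage = mean(mask))
}

#' Histogram of the masked pixel values
#'
#' Computes the normalized histogram of the original (not smoothed) pixel
#' values at the positions selected by the mask, over `n_bins` equal-width
#' bins spanning the `[min, max]` range of the selected values. When all
#' selected values are equal, the whole mass falls in a single bin.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param mask A logical matrix of the image shape, e.g. from
#'   [compute_detail_mask()].
#' @param n_bins Number of histogram bins (default 256).
#' @return A `normalized_histogram`: list with `probabilities` (summing to
#'   1) and `bin_edges` (length `n_bins + 1`).
#' @export
masked_histogram <- function(img, mask, n_bins = 256L) {
  m <- as_matrix(img)
  if (!all(dim(mask) == dim(m))) {
    stop("mask shape does not match image shape", call. = FALSE)
  }
  if (!any(mask)) stop("mask selects no pixels", call. = FALSE)
  if (n_bins < 2L) stop("`n_bins` must be >= 2", call. = FALSE)
  v <- m[mask]
  lo <- min(v); hi <- max(v)
  if (lo == hi) {  # degenerate: one occupied bin
    edges <- seq(lo - 0.5, lo + 0.5, length.out = n_bins + 1L)
  } else {
    edges <- seq(lo, hi, length.out = n_bins + 1L)
  }
  idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(probabilities = counts / length(v), bin_edges = edges),
            class = "normalized_histogram")
}

#' Shannon entropy of a normalized histogram
#'
#' Returns \eqn{-\sum_i P_i \log_2 P_i} in bits, with \eqn{0 \log_2 0 = 0}.
#' The result lies in `[0, log2(n_bins)]`; it is maximal for a uniform
#' histogram (every gray level equally occupied -- full use of the dynamic
#' range) and zero when a single bin holds all mass.
#'
#' @param hist A `normalized_histogram` from [masked_histogram()], or a
#'   numeric probability vector summing to 1.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(hist) {
  p <- if (inherits(hist, "normalized_histogram")) hist$probabilities else hist
  if (!is.numeric(p) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("`hist` must be a normalized histogram (non-negative, sum 1)",
         call. = FALSE)
  }
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Masked spatial entropy of an image
#'
#' Convenience wrapper chaining [compute_detail_mask()],
#' [masked_histogram()] and [shannon_entropy()]: the contrast measure of
#' the ranking method.
#'
#' @inheritParams compute_detail_mask
#' @inheritParams masked_histogram
#' @return Entropy in bits.
#' @export
spatial_entropy <- function(img, filter_radius = 100L, percentile = 80,
                            n_bins = 256L) {
  mask <- compute_detail_mask(img, filter_radius, percentile)
  shannon_entropy(masked_histogram(img, mask, n_bins))
}
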