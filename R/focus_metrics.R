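# Baseline autofocus metrics used for benchmarking the spectral tail
# measures: the spatial-domain Brenner gradient and the frequency-domain
# Spectral Moments score.

new_focus_score <- function(value, metric_name) {
  structure(list(value = value, metric_name = metric_name),
            class = "focus_score")
}

#' @export
print.focus_score <- function(x, ...) {
  cat(sprintf("<focus_score> %s = %g\n", x$metric_name, x$value))
  invisible(x)
}

#' Brenner autofocus metric
#'
#' The classical Brenner score: the sum over the image of the squared
#' intensity difference between pixels two samples apart,
#' \deqn{\sum_{i=1}^{N_y} \sum_{j=1}^{N_x-2} (G_{i,j+2} - G_{i,j})^2,}
#' a spatial-domain derivative measure. The difference is taken along the
#' row (x) direction; the metric is therefore invariant to transposition
#' only up to this axis convention. It is zero exactly for images constant
#' along x, and decreases as blur flattens local gradients.
#'
#' @param img A [gray_image()] or numeric matrix with at least 3 columns.
#' @return A `focus_score` with `metric_name = "brenner"`.
#' @export
brenner <- function(img) {
  m <- as_matrix(img)
  w <- ncol(m)
  if (w < 3L) stop("image must be at least 3 pixels wide", call. = FALSE)
  d <- m[, 3:w, drop = FALSE] - m[, 1:(w - 2L), drop = FALSE]
  new_focus_score(sum(d * d), "brenner")
}

# the moment formula proper, isolated so the expression can be adjusted
# without touching any monotonicity test: index-weighted sum over the
# normalized (sum = 1) 1D power spectrum with logarithmic scaling, which
# emphasizes the high-frequency components
spectral_moments_formula <- function(p) {
  i <- seq_along(p) - 1  # spectral component index, DC = 0
  sum(i * log2(1 + p))
}

#' Spectral Moments autofocus metric
#'
#' Computes the 1D power spectrum of the image (summed reduction of the
#' normalized 2D spectrum), renormalizes it to sum 1, and returns the
#' log-scaled index-weighted sum
#' \deqn{\sum_i i \, \log_2(1 + P_i),}
#' where `i` is the spectral component index and `P` the normalized
#' power spectrum. Unlike the tail measures, the entire spectrum is used
#' (no threshold crop); the logarithmic scaling somewhat emphasizes high
#' frequencies, but the metric responds less steeply to blur than the
#' tail statistics at a 40% threshold.
#'
#' @param img A [gray_image()] or numeric matrix with positive mean.
#' @return A `focus_score` with `metric_name = "spectral_moments"`.
#' @export
spectral_moments <- function(img) {
  ps1d <- reduce_summed(power_spectrum_2d(img))
  p <- ps1d$power / sum(ps1d$power)
  new_focus_score(spectral_moments_formula(p), "spectral_moments")
}
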