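# Synthetic microscopy-like test images and Gaussian-blur focus series.
#
# The generator stands in for the real base images of a focus-series
# benchmark: filament-like structures (intermediate filaments), bead-like
# spots (fluorescent nanoparticles), an intensity ramp, white noise, and a
# photograph-like composite "scene". Blurring a base image with increasing
# Gaussian radii emulates a through-focus series; the known radius order is
# the ground truth that ranking measures are validated against.

# run `expr` with a deterministic RNG stream without clobbering the
# caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# pixel-coordinate grids: gx = column (x) index, gy = row (y) index
coord_grids <- function(h, w) {
  list(gx = matrix(rep(seq_len(w), each = h), h, w),
       gy = matrix(rep(seq_len(h), w), h, w))
}

# add an anti-aliased line segment of Gaussian cross-section
add_segment <- function(img, g, p1, p2, amp, sigma) {
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  l2 <- vx^2 + vy^2
  t <- pmin(pmax(((g$gx - p1[1]) * vx + (g$gy - p1[2]) * vy) / l2, 0), 1)
  d2 <- (g$gx - (p1[1] + t * vx))^2 + (g$gy - (p1[2] + t * vy))^2
  img + amp * exp(-d2 / (2 * sigma^2))
}

# add an isotropic Gaussian spot
add_spot <- function(img, g, cx, cy, amp, sigma) {
  img + amp * exp(-((g$gx - cx)^2 + (g$gy - cy)^2) / (2 * sigma^2))
}

#' Generate a synthetic base image
#'
#' Deterministic (per seed) synthetic images on a 0--255 intensity scale:
#'
#' * `filaments`: random anti-aliased line segments of Gaussian
#'   cross-section over a dark background (intermediate-filament-like).
#' * `beads`: isolated Gaussian spots at random positions
#'   (nanoparticle-like).
#' * `ramp`: a pure linear intensity gradient along x.
#' * `white_noise`: i.i.d. uniform pixels over the full range.
#' * `scene`: a photograph-like composite of smooth large-scale blobs,
#'   filaments, spots and mild Gaussian sensor noise; scenes drawn with
#'   different seeds form a family of images with comparable broadband
#'   spectra, emulating a set of grayscale photographs.
#'
#' @param kind One of `"filaments"`, `"beads"`, `"ramp"`,
#'   `"white_noise"`, `"scene"`.
#' @param size Integer `(height, width)`, each at least 64 (default
#'   `c(256, 256)`).
#' @param seed Integer RNG seed; the same seed always reproduces the same
#'   image bit-for-bit.
#' @param params Optional named list overriding kind-specific defaults:
#'   `n_segments`, `amplitude`, `line_sigma`, `background` (filaments);
#'   `n_beads`, `amplitude`, `bead_sigma`, `background`, `margin`
#'   (beads); `low`, `high` (ramp and white_noise); `noise_sd` (scene).
#' @return A [gray_image()].
#' @export
make_base_image <- function(kind, size = c(256L, 256L), seed = 1L,
                            params = list()) {
  kind <- match.arg(kind,
                    c("filaments", "beads", "ramp", "white_noise", "scene"))
  h <- as.integer(size[1]); w <- as.integer(size[2])
  if (h < 64L || w < 64L) {
    stop("`size` must be at least 64x64", call. = FALSE)
  }
  p <- function(name, default) {
    if (!is.null(params[[name]])) params[[name]] else default
  }
  g <- coord_grids(h, w)
  img <- with_seed(seed, switch(kind,
    filaments = {
      m <- matrix(p("background", 8), h, w)
      n_seg <- p("n_segments", 14L)
      amp <- p("amplitude", 150)
      sig <- p("line_sigma", 1.2)
      for (k in seq_len(n_seg)) {
        p1 <- c(stats::runif(1, 1, w), stats::runif(1, 1, h))
        ang <- stats::runif(1, 0, pi)
        len <- stats::runif(1, 0.4, 1.2) * min(h, w)
        p2 <- p1 + len * c(cos(ang), sin(ang))
        m <- add_segment(m, g, p1, p2, amp, sig)
      }
      m
    },
    beads = {
      m <- matrix(p("background", 10), h, w)
      n_beads <- p("n_beads", 40L)
      amp <- p("amplitude", 180)
      sig <- p("bead_sigma", 2)
      mar <- p("margin", 5)
      cx <- stats::runif(n_beads, mar, w - mar)
      cy <- stats::runif(n_beads, mar, h - mar)
      for (k in seq_len(n_beads)) m <- add_spot(m, g, cx[k], cy[k], amp, sig)
      m
    },
    ramp = {
      lo <- p("low", 10); hi <- p("high", 245)
      matrix(rep(seq(lo, hi, length.out = w), each = h), h, w)
    },
    white_noise = {
      lo <- p("low", 0); hi <- p("high", 255)
      matrix(stats::runif(h * w, lo, hi), h, w)
    },
    scene = {
      m <- matrix(stats::runif(1, 10, 30), h, w)
      for (k in seq_len(sample(3:6, 1))) {
        m <- add_spot(m, g, stats::runif(1, 1, w), stats::runif(1, 1, h),
                      stats::runif(1, 20, 60),
                      stats::runif(1, min(h, w) / 8, min(h, w) / 3))
      }
      for (k in seq_len(sample(6:14, 1))) {
        p1 <- c(stats::runif(1, 1, w), stats::runif(1, 1, h))
        ang <- stats::runif(1, 0, pi)
        len <- stats::runif(1, 0.3, 1.1) * min(h, w)
        m <- add_segment(m, g, p1, p1 + len * c(cos(ang), sin(ang)),
                         stats::runif(1, 40, 90),
                         stats::runif(1, 0.8, 1.6))
      }
      for (k in seq_len(sample(20:40, 1))) {
        m <- add_spot(m, g, stats::runif(1, 3, w - 3),
                      stats::runif(1, 3, h - 3),
                      stats::runif(1, 40, 120), stats::runif(1, 1, 2.5))
      }
      m + matrix(stats::rnorm(h * w, 0, p("noise_sd", 2.5)), h, w)
    }
  ))
  gray_image(pmin(pmax(img, 0), 255))
}

# dense banded convolution matrix for a 1D Gaussian kernel with
# symmetric-reflect boundary; row i holds the weights contributing to
# output sample i, so blurred = C_rows %*% img %*% t(C_cols)
gauss_conv_matrix <- function(n, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  # symmetric reflection with edge repeat: ... 2 1 | 1 2 ... n | n n-1 ...
  reflect <- function(i) {
    j <- (i - 1L) %% (2L * n)
    ifelse(j >= n, 2L * n - 1L - j, j) + 1L
  }
  cm <- matrix(0, n, n)
  for (o in seq(-half, half)) {
    j <- reflect(seq_len(n) + o)
    idx <- cbind(seq_len(n), j)
    cm[idx] <- cm[idx] + k[o + half + 1L]
  }
  cm
}

#' Gaussian blur of an image
#'
#' Separable 2D Gaussian convolution with symmetric-reflect boundary
#' handling. The blur `radius` follows the kernel-support convention
#' `radius = 3 * sigma`: a radius-3 blur uses a Gaussian of standard
#' deviation 1 pixel. Radius 0 is the identity. Because the kernel is
#' normalized and the boundary reflected, the total image intensity is
#' conserved (to well within 1e-6 relative).
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param radius Blur radius in pixels, `>= 0` (`sigma = radius / 3`).
#' @return The blurred image as a [gray_image()].
#' @export
gaussian_blur <- function(img, radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0) {
    stop("`radius` must be a single non-negative number", call. = FALSE)
  }
  m <- as_matrix(img)
  if (radius == 0) return(gray_image(m))
  sigma <- radius / 3
  cr <- gauss_conv_matrix(nrow(m), sigma)
  cc <- if (ncol(m) == nrow(m)) cr else gauss_conv_matrix(ncol(m), sigma)
  out <- cr %*% m %*% t(cc)
  gray_image(pmax(out, 0))
}

blur_series_filename <- function(kind, base_idx, seed, r) {
  base_tag <- if (is.na(base_idx)) "" else sprintf("%02d", base_idx)
  sprintf("%s%s_s%d_r%04.1f.tif", kind, base_tag, seed, r)
}

#' Generate a Gaussian-blur focus series on disk
#'
#' Blurs one synthetic base image (or, for `kind = "mixed"`, each of
#' `n_bases` photograph-like scenes) with every radius in `radii` and
#' writes the results as TIFF files whose names encode kind, seed and
#' radius (e.g. `beads_s7_r03.0.tif`), so lexicographic filename order
#' equals radius order. A ground-truth sidecar CSV
#' (`<kind>_s<seed>_truth.csv`: `image_id`, `kind`, `radius`) is written
#' next to the images as the oracle for separation and monotonicity
#' checks.
#'
#' Single-kind series are written as 16-bit TIFF, matching microscope
#' acquisitions; the `mixed` photograph-like dataset is written as 8-bit,
#' matching photographs (override with `bit_depth`).
#'
#' @param kind `"filaments"`, `"beads"`, `"ramp"`, `"white_noise"`,
#'   `"scene"` or `"mixed"`.
#' @param radii Non-negative blur radii, ascending, including 0 (the
#'   unblurred original). Default `0:29`.
#' @param seed Integer seed for the base image(s).
#' @param size Integer `(height, width)` of the images.
#' @param out_dir Output directory, created if missing.
#' @param n_bases Number of base scenes for `kind = "mixed"` (default 12).
#' @param bit_depth 8 or 16; default 16 (8 for `mixed`).
#' @return Character vector of the written image paths (radius order,
#'   grouped by base), with the truth-table path in attribute
#'   `"truth_csv"`.
#' @export
make_blur_series <- function(kind, radii = 0:29, seed = 1L,
                             size = c(256L, 256L), out_dir,
                             n_bases = 12L, bit_depth = NULL) {
  kind <- match.arg(kind, c("filaments", "beads", "ramp", "white_noise",
                            "scene", "mixed"))
  radii <- as.numeric(radii)
  if (is.unsorted(radii, strictly = TRUE) || any(radii < 0) ||
      radii[1] != 0) {
    stop("`radii` must be strictly ascending, non-negative, and include 0",
         call. = FALSE)
  }
  if (is.null(bit_depth)) bit_depth <- if (kind == "mixed") 8L else 16L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scale <- (2^bit_depth - 1) / 255  # bases live on a 0-255 scale
  paths <- character(0)
  truth <- list()
  base_specs <- if (kind == "mixed") {
    lapply(seq_len(n_bases), function(i) {
      list(kind = "scene", seed = seed + i - 1L, idx = i)
    })
  } else {
    list(list(kind = kind, seed = seed, idx = NA_integer_))
  }
  for (bs in base_specs) {
    base <- make_base_image(bs$kind, size, bs$seed)
    for (r in radii) {
      img <- as_matrix(gaussian_blur(base, r)) * scale
      fn <- blur_series_filename(if (kind == "mixed") "mixed" else kind,
                                 bs$idx, bs$seed, r)
      fp <- file.path(out_dir, fn)
      save_image(img, fp, bits = bit_depth)
      paths <- c(paths, fp)
      truth[[length(truth) + 1L]] <- data.frame(
        image_id = fn, kind = bs$kind, radius = r,
        stringsAsFactors = FALSE)
    }
  }
  truth_path <- file.path(out_dir, sprintf("%s_s%d_truth.csv", kind, seed))
  utils::write.csv(do.call(rbind, truth), truth_path, row.names = FALSE)
  structure(paths, truth_csv = truth_path)
}

#' Generate a screening-like time course with focus failures
#'
#' Emulates a high-content-screening well imaged over time: the amount of
#' image content ramps from nearly empty to detail-packed across frames
#' (spots and short filaments accumulating over a noisy background), and
#' a deterministic (per seed) subset of frames is blurred at a medium
#' (`radius = 2`, "blurred") or heavy (`radius = 8`, "out_of_focus")
#' level, emulating autofocus failures. Frames are written as 8-bit TIFFs
#' named so lexicographic order equals time order, together with a
#' ground-truth sidecar CSV (`image_id`, `kind`, `radius`, `label` in
#' `in_focus` / `blurred` / `out_of_focus`).
#'
#' @param seed Integer seed; fixes content, blur assignment and noise.
#' @param out_dir Output directory, created if missing.
#' @param n_frames Number of time points (default 48).
#' @param size Integer `(height, width)` of the frames.
#' @return Character vector of the written image paths (time order), with
#'   the truth-table path in attribute `"truth_csv"`.
#' @export
make_hcs_like_series <- function(seed = 1L, out_dir, n_frames = 48L,
                                 size = c(256L, 256L)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- as.integer(size[1]); w <- as.integer(size[2])
  g <- coord_grids(h, w)
  # blur assignment: ~1/6 heavy, ~1/6 medium, deterministic per seed
  assign_tbl <- with_seed(seed, {
    lab <- rep("in_focus", n_frames)
    shuffled <- sample(seq_len(n_frames))
    n_heavy <- max(2L, n_frames %/% 6L)
    n_med <- max(2L, n_frames %/% 6L)
    lab[shuffled[seq_len(n_heavy)]] <- "out_of_focus"
    lab[shuffled[n_heavy + seq_len(n_med)]] <- "blurred"
    lab
  })
  radius_of <- c(in_focus = 0, blurred = 2, out_of_focus = 8)
  paths <- character(n_frames)
  truth <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    # content density ramps over the time course
    n_obj <- round(2 + (t - 1) * 58 / max(1L, n_frames - 1L))
    frame <- with_seed(seed * 10000L + t, {
      m <- matrix(12, h, w)
      for (k in seq_len(n_obj)) {
        if (stats::runif(1) < 0.7) {
          m <- add_spot(m, g, stats::runif(1, 3, w - 3),
                        stats::runif(1, 3, h - 3),
                        stats::runif(1, 60, 140), stats::runif(1, 1.2, 2.5))
        } else {
          p1 <- c(stats::runif(1, 1, w), stats::runif(1, 1, h))
          ang <- stats::runif(1, 0, pi)
          len <- stats::runif(1, 0.05, 0.15) * min(h, w)
          m <- add_segment(m, g, p1, p1 + len * c(cos(ang), sin(ang)),
                           stats::runif(1, 50, 110),
                           stats::runif(1, 0.9, 1.5))
        }
      }
      m + matrix(stats::rnorm(h * w, 0, 2), h, w)
    })
    lab <- assign_tbl[t]
    r <- radius_of[[lab]]
    frame <- as_matrix(gaussian_blur(pmin(pmax(frame, 0), 255), r))
    fn <- sprintf("hcs_s%d_t%03d.tif", seed, t)
    fp <- file.path(out_dir, fn)
    save_image(frame, fp, bits = 8L)
    paths[t] <- fp
    truth[[t]] <- data.frame(image_id = fn, kind = "hcs", radius = r,
                             label = lab, stringsAsFactors = FALSE)
  }
  truth_path <- file.path(out_dir, sprintf("hcs_s%d_truth.csv", seed))
  utils::write.csv(do.call(rbind, truth), truth_path, row.names = FALSE)
  structure(paths, truth_csv = truth_path)
}
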