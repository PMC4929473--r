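test_that("base images are deterministic per seed and leave RNG alone", {
  a <- make_base_image("filaments", c(64L, 64L), seed = 9)
  b <- make_base_image("filaments", c(64L, 64L), seed = 9)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a),
                         unclass(make_base_image("filaments", c(64L, 64L),
                                                 seed = 10))))
  set.seed(123)
  before <- .Random.seed
  invisible(make_base_image("scene", c(64L, 64L), seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("a single centered bead is radially symmetric with central max", {
  # margin = half the size pins the random position to the exact center
  img <- unclass(make_base_image("beads", c(64L, 64L), seed = 1,
                                 params = list(n_beads = 1L, margin = 32)))
  expect_identical(which(img == max(img), arr.ind = TRUE)[1, ],
                   c(row = 32L, col = 32L))
  expect_equal(img[32, 32 + 5], img[32, 32 - 5], tolerance = 1e-9)
  expect_equal(img[32 + 5, 32], img[32 - 5, 32], tolerance = 1e-9)
  expect_equal(img[32 + 4, 32], img[32, 32 + 4], tolerance = 1e-9)
})

test_that("unknown kinds and undersized images are rejected", {
  expect_error(make_base_image("vortex", c(64L, 64L), 1), "arg")
  expect_error(make_base_image("beads", c(32L, 32L), 1), "64x64")
})

test_that("gaussian blur is identity at 0, conserves mass, rejects r < 0", {
  m <- random_image(48, 48, seed = 2)
  expect_equal(unclass(gaussian_blur(m, 0)), m, ignore_attr = TRUE)
  for (r in c(1, 3, 9)) {
    out <- gaussian_blur(m, r)
    expect_equal(sum(out), sum(m), tolerance = 1e-9)
  }
  expect_error(gaussian_blur(m, -1), "non-negative")
})

test_that("blurring an impulse reproduces the closed-form kernel", {
  n <- 33L
  m <- impulse_image(n, amplitude = 1)
  out <- unclass(gaussian_blur(m, 3))  # sigma = 1
  half <- ceiling(4)
  k <- dnorm(seq(-half, half), sd = 1)
  k <- k / sum(k)
  ref <- matrix(0, n, n)
  ref[17 + seq(-half, half), 17 + seq(-half, half)] <- outer(k, k)
  expect_equal(out, ref, tolerance = 1e-9)
})

test_that("blur series writes one file per radius in sortable order", {
  d <- withr::local_tempdir()
  paths <- make_blur_series("beads", radii = c(0, 1, 2), seed = 3,
                            size = c(64L, 64L), out_dir = d)
  expect_length(paths, 3L)
  expect_true(all(file.exists(paths)))
  expect_identical(basename(paths), sort(basename(paths)))
  truth <- utils::read.csv(attr(paths, "truth_csv"))
  expect_equal(truth$radius, c(0, 1, 2))
  expect_identical(truth$image_id, basename(paths))
  expect_error(make_blur_series("beads", radii = c(1, 2), seed = 1,
                                size = c(64L, 64L), out_dir = d),
               "include 0")
})

test_that("mixed series writes radii x bases photograph-like images", {
  d <- withr::local_tempdir()
  paths <- make_blur_series("mixed", radii = c(0, 1, 2), seed = 5,
                            size = c(64L, 64L), out_dir = d, n_bases = 4L)
  expect_length(paths, 12L)
  truth <- utils::read.csv(attr(paths, "truth_csv"))
  expect_identical(nrow(truth), 12L)
  expect_true(all(truth$kind == "scene"))
})

test_that("blur series ranks below the sharp original in the pipeline", {
  base <- make_base_image("filaments", c(96L, 96L), seed = 8)
  f0 <- tail_stats(reduce_summed(power_spectrum_2d(base)), 0.40)$fMean
  f2 <- tail_stats(reduce_summed(power_spectrum_2d(gaussian_blur(base, 2))),
                   0.40)$fMean
  expect_gt(f0, f2)
})

test_that("screening series is reproducible with labelled ground truth", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- make_hcs_like_series(seed = 4, out_dir = d1, n_frames = 8L,
                             size = c(64L, 64L))
  p2 <- make_hcs_like_series(seed = 4, out_dir = d2, n_frames = 8L,
                             size = c(64L, 64L))
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  truth <- utils::read.csv(attr(p1, "truth_csv"))
  expect_identical(nrow(truth), 8L)
  expect_setequal(unique(truth$label),
                  c("in_focus", "blurred", "out_of_focus"))
  expect_identical(truth$image_id, basename(p1))  # time order
})
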