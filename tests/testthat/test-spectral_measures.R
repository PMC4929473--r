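test_that("power spectrum satisfies Parseval before normalization", {
  for (seed in 1:3) {
    m <- random_image(64, 64, seed)
    ps <- power_spectrum_2d(m)
    lhs <- sum(ps$power) * ps$normalization[["mean_gray"]]
    expect_equal(lhs, sum(m^2), tolerance = 1e-10)
  }
})

test_that("flat and impulse images have the expected spectra", {
  ps <- power_spectrum_2d(matrix(42, 32, 32))
  p <- ps$power
  p[17, 17] <- 0  # remove the DC sample
  expect_equal(max(p), 0, tolerance = 1e-12)

  ps_i <- power_spectrum_2d(impulse_image(32))
  expect_equal(max(ps_i$power) / min(ps_i$power), 1, tolerance = 1e-9)

  expect_error(power_spectrum_2d(matrix(0, 16, 16)), "mean")
})

test_that("brightness scaling moves the normalized spectrum by exactly k", {
  m <- random_image(48, 48, seed = 6)
  p1 <- power_spectrum_2d(m)$power
  p3 <- power_spectrum_2d(3 * m)$power
  expect_equal(p3, 3 * p1, tolerance = 1e-9)
})

test_that("radial reduction equals the brute-force binning oracle", {
  for (dims in list(c(16L, 16L), c(33L, 33L), c(48L, 64L), c(64L, 64L))) {
    ps <- power_spectrum_2d(random_image(dims[1], dims[2],
                                         seed = sum(dims)))
    got <- reduce_radial(ps)
    ref <- oracle_radial(ps$power)
    expect_identical(got$freq_fraction, ref$freq_fraction)
    expect_equal(got$power, ref$power, tolerance = 1e-12)
    expect_identical(got$freq_fraction[1], 0)
    expect_identical(got$freq_fraction[length(got$freq_fraction)], 1)
  }
})

test_that("summed reduction folds conjugate-symmetric energy correctly", {
  m <- random_image(33, 33, seed = 2)  # odd size: every frequency paired
  ps <- power_spectrum_2d(m)
  ps1 <- reduce_summed(ps)
  # folding preserves total energy; rows + cols each count it once
  expect_equal(sum(ps1$power), 2 * sum(ps$power), tolerance = 1e-9)
  # real input: negative frequencies mirror positive ones, folding doubles
  cs <- colSums(ps$power)
  c0 <- 17L
  folded <- iqrank:::fold_centered(cs)
  expect_equal(folded[-1], 2 * cs[(c0 + 1):33], tolerance = 1e-9)
  # constant image: no AC power anywhere in the folded profile
  flat <- reduce_summed(power_spectrum_2d(matrix(9, 32, 32)))
  expect_equal(max(flat$power[-1]), 0, tolerance = 1e-12)
})

test_that("summed reduction handles non-square images", {
  ps1 <- reduce_summed(power_spectrum_2d(random_image(48, 96, seed = 8)))
  expect_identical(range(ps1$freq_fraction), c(0, 1))
  expect_true(all(diff(ps1$freq_fraction) > 0))
  expect_true(all(ps1$power >= 0))
  expect_gte(length(ps1$power), 8L)
})

test_that("tail statistics match hand-computed values", {
  flat_tail <- ps1d_from(rep(4, 101))
  st <- tail_stats(flat_tail, 0.40)
  expect_equal(st$fMean, 4)
  expect_equal(st$fSTD, 0)
  expect_equal(st$skewness, 0)
  expect_equal(st$kurtosis, 0)
  expect_equal(st$MeanBin, 4)
  expect_equal(st$cv, 0)

  # freq grid 0..1 over 101 samples: tail > 0.4 starts at sample 42
  ramp_tail <- ps1d_from(c(rep(0, 41), 1:60))
  st2 <- tail_stats(ramp_tail, 0.40)
  expect_equal(st2$MeanBin, 3)  # mean of 1..5
  expect_equal(st2$fMean, mean(1:60))
  expect_equal(st2$fSTD, sd(1:60))
  expect_equal(st2$high90, sum((1:60)[ramp_tail$freq_fraction[-(1:41)] > 0.9]))

  expect_error(tail_stats(ps1d_from(rep(1, 10)), 0.8), "lower")
  expect_error(tail_stats(flat_tail, 1.2), "between 0 and 1")
})

test_that("blur depresses and noise inflates the spectral tail", {
  base <- make_base_image("filaments", c(128L, 128L), seed = 3)
  st0 <- tail_stats(reduce_summed(power_spectrum_2d(base)), 0.40)
  stb <- tail_stats(reduce_summed(power_spectrum_2d(gaussian_blur(base, 2))),
                    0.40)
  expect_lt(stb$fMean, st0$fMean)
  expect_lt(stb$MeanBin, st0$MeanBin)
  set.seed(1)
  noisy <- pmin(pmax(unclass(base) +
                       matrix(rnorm(length(base), 0, 8), nrow(base)), 0), 255)
  stn <- tail_stats(reduce_summed(power_spectrum_2d(noisy)), 0.40)
  expect_gt(stn$fMean, st0$fMean)
  expect_gt(stn$MeanBin, st0$MeanBin)
})

test_that("summed and radial reductions rank a blur series identically", {
  # compare in the linear (2%) regime, where both reductions track blur
  base <- make_base_image("beads", c(96L, 96L), seed = 4)
  fm <- vapply(c(0, 2, 4, 6, 8, 10), function(r) {
    ps <- power_spectrum_2d(gaussian_blur(base, r))
    c(tail_stats(reduce_summed(ps), 0.02)$fMean,
      tail_stats(reduce_radial(ps), 0.02)$fMean)
  }, numeric(2))
  expect_identical(order(fm[1, ]), order(fm[2, ]))
  expect_true(all(diff(fm[1, ]) < 0))
  expect_true(all(diff(fm[2, ]) < 0))
})

test_that("measure inversion is 1 - value on [0, 1] only", {
  expect_equal(invert_measure(0), 1)
  expect_equal(invert_measure(1), 0)
  expect_equal(invert_measure(0.3), 0.7)
  expect_error(invert_measure(1.5), "normalized")
  expect_error(invert_measure(-0.1), "normalized")
})
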