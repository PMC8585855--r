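test_that("gm_mask thresholds probabilities and refuses empty masks", {
  p <- array(1, c(4, 4, 4))
  expect_true(all(gm_mask(p, 0.9)))
  expect_error(gm_mask(array(0.89, c(4, 4, 4)), 0.9), "empty")
  expect_error(gm_mask(array(1.2, c(2, 2, 2))), "\\[0, 1\\]")
  ph <- make_phantom(c(20, 20, 24), seed = 3)
  expect_identical(gm_mask(ph$gm_probability, 0.9), ph$labels == 1L)
})

test_that("spatial SNR matches a brute-force recomputation of the sum-difference formula", {
  set.seed(41)
  d <- c(8, 8, 6)
  nf <- 10
  x <- array(rnorm(prod(d) * nf, mean = 3), c(d, nf))
  mask <- array(runif(prod(d)) > 0.4, d)
  got <- spatial_snr(x, mask)

  # independent recomputation, 0-based even/odd split in acquisition order
  E <- 0 * x[, , , 1]; O <- E
  for (f in seq_len(nf)) {
    if ((f - 1) %% 2 == 0) E <- E + x[, , , f] else O <- O + x[, , , f]
  }
  E <- E / (nf / 2); O <- O / (nf / 2)
  expected <- mean((E + O)[mask]) / (sd((E - O)[mask]) / sqrt(2))
  expect_equal(as.numeric(got), expected, tolerance = 1e-10)
  expect_false(attr(got, "degenerate"))
  expect_identical(attr(got, "n_mask"), sum(mask))
})

test_that("spatial SNR is homogeneous in signal and flags degenerate input", {
  set.seed(42)
  d <- c(6, 6, 4); nf <- 8
  signal <- array(5, c(d, nf))
  noise <- array(rnorm(prod(d) * nf, sd = 0.5), c(d, nf))
  mask <- array(TRUE, d)
  s1 <- as.numeric(spatial_snr(signal + noise, mask))
  s2 <- as.numeric(spatial_snr(2 * signal + noise, mask))
  # exact in expectation; the shared noise perturbs the sum-image mean only
  expect_equal(s2 / s1, 2, tolerance = 0.01)

  const <- array(3, c(d, 4))
  sdeg <- spatial_snr(const, mask)
  expect_true(attr(sdeg, "degenerate"))
  expect_identical(as.numeric(sdeg), Inf)
  expect_error(spatial_snr(array(1, c(d, 1)), mask), "at least 2")
})

test_that("temporal SNR approaches mean/sd and is scale-invariant", {
  set.seed(43)
  d <- c(10, 10, 2)
  nf <- 2000
  c0 <- 4; sigma <- 2
  x <- array(rnorm(prod(d) * nf, mean = c0, sd = sigma), c(d, nf))
  mask <- array(TRUE, d)
  t1 <- temporal_snr(x, mask)
  expect_equal(as.numeric(t1), c0 / sigma, tolerance = 0.02)
  expect_equal(as.numeric(temporal_snr(3 * x, mask)), as.numeric(t1),
               tolerance = 1e-12)
  t2 <- temporal_snr(x, mask, aggregate = "ratio-of-means")
  expect_equal(as.numeric(t2), c0 / sigma, tolerance = 0.02)

  const <- array(1, c(d, 5))
  tdeg <- temporal_snr(const, mask)
  expect_true(attr(tdeg, "degenerate"))
  expect_identical(attr(tdeg, "n_zero_sd"), as.integer(prod(d)))
})

test_that("blur correlation separates sharp from slice-smooth volumes", {
  set.seed(44)
  noise_vol <- array(rnorm(16 * 16 * 30), c(16, 16, 30))
  r_noise <- as.numeric(blur_correlation(noise_vol))
  expect_lt(abs(r_noise), 0.05)

  inplane <- matrix(rnorm(16 * 16), 16, 16)
  smooth_vol <- array(rep(inplane, 30), c(16, 16, 30))
  expect_equal(as.numeric(blur_correlation(smooth_vol)), 1, tolerance = 1e-12)

  rdeg <- blur_correlation(array(2, c(4, 4, 4)))
  expect_true(attr(rdeg, "degenerate"))
  expect_true(is.na(as.numeric(rdeg)))
  expect_error(blur_correlation(array(0, c(4, 4, 1))), ">= 2 slices")
})

test_that("slice smoothing is exact at FWHM 0 and monotone in the blur correlation", {
  set.seed(45)
  vol <- array(rnorm(12 * 12 * 40), c(12, 12, 40))
  expect_identical(smooth_slices(vol, 0), vol)
  fwhms <- c(0, 0.5, 1, 1.5, 2.5, 4)
  rs <- vapply(fwhms, function(f) {
    as.numeric(blur_correlation(smooth_slices(vol, f)))
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
  # kernel preserves a constant volume (weights sum to one, reflect edges)
  const <- array(7, c(4, 4, 8))
  expect_equal(smooth_slices(const, 2.2), const, tolerance = 1e-12)
})

test_that("match_blur recovers the FWHM found by a brute-force grid search", {
  set.seed(46)
  vol <- array(rnorm(12 * 12 * 40), c(12, 12, 40))
  target_r <- as.numeric(blur_correlation(smooth_slices(vol, 1.3)))
  fit <- match_blur(vol, target_r, tol = 1e-4)

  grid <- seq(0, 3, by = 0.01)
  errs <- vapply(grid, function(f) {
    abs(as.numeric(blur_correlation(smooth_slices(vol, f))) - target_r)
  }, numeric(1))
  expect_equal(fit$fwhm_vox, grid[which.min(errs)], tolerance = 0.02)
  expect_lt(abs(fit$r - target_r), 2e-4)

  # identity when the target equals the current correlation
  r0 <- as.numeric(blur_correlation(vol))
  fit0 <- match_blur(vol, r0)
  expect_equal(fit0$fwhm_vox, 0)
  expect_equal(fit0$volume, vol)

  expect_error(match_blur(vol, r0 - 0.1), "below the unsmoothed")
  expect_error(match_blur(vol, 0.99999, fwhm_bounds = c(0, 1)),
               "not reachable")
})

test_that("snr_report collects the metrics for one condition", {
  g <- slider_preset("slider2")
  ph <- tiny_phantom(g, nxy = 16L)
  sim <- simulate_acquisition(ph, g, noise_model(var_thermal = 16),
                              n_meas = 10, seed = 8)
  inv <- tikhonov_inverse(sim$operator, 0.1)
  perf <- reconstruct_series(lapply(sim$sets, perfusion_frames), inv)
  rep_ <- snr_report(perf, gm_mask(ph$gm_probability),
                     condition = "slider2", lambda = 0.1)
  expect_s3_class(rep_, "snr_report")
  expect_gt(rep_$ssnr, 0)
  expect_gt(rep_$tsnr, 0)
  expect_true(rep_$blur_corr > 0 && rep_$blur_corr < 1)
  expect_false(rep_$degenerate)
})
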