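test_that("phantoms are deterministic given the seed and tissue-complete", {
  ph1 <- make_phantom(c(20, 20, 24), seed = 5)
  ph2 <- make_phantom(c(20, 20, 24), seed = 5)
  expect_identical(ph1, ph2)
  ph3 <- make_phantom(c(20, 20, 24), seed = 6)
  expect_false(identical(ph1$labels, ph3$labels))

  # GM and WM present in every axial quadrant
  nx <- dim(ph1$labels)[1]; ny <- dim(ph1$labels)[2]
  qx <- list(1:(nx %/% 2), (nx %/% 2 + 1):nx)
  qy <- list(1:(ny %/% 2), (ny %/% 2 + 1):ny)
  for (ix in 1:2) for (iy in 1:2) {
    quad <- ph1$labels[qx[[ix]], qy[[iy]], ]
    expect_gt(sum(quad == 1L), 0)
    expect_gt(sum(quad == 2L), 0)
  }

  # perfusion histogram has modes exactly at the tissue values
  expect_setequal(unique(as.vector(ph1$perfusion)), c(0, 60, 20))
  expect_error(make_phantom(c(4, 4, 4)), "shape")
})

test_that("noise-free acquisitions equal the forward-projected difference signal", {
  g <- slider_preset("slider2")
  ph <- tiny_phantom(g, nxy = 16L)
  sim <- simulate_acquisition(ph, g, quiet_noise(), n_meas = 3, seed = 1)
  op <- sim$operator
  d <- dim(ph$labels)
  for (k in 1:2) {
    Ak <- op$matrix[op$row_map$set == k - 1L, , drop = FALSE]
    expected <- array(t(Ak %*% t(matrix(sim$truth$dm, nrow = d[1] * d[2]))),
                      dim = c(d[1], d[2], nrow(Ak)))
    got <- mean_volume(perfusion_frames(sim$sets[[k]]))
    expect_equal(got, expected, tolerance = 1e-12)
  }
  # identical seeds reproduce the acquisition bit-for-bit
  sim2 <- simulate_acquisition(ph, g, quiet_noise(), n_meas = 3, seed = 1)
  expect_identical(sim$sets[[1]]$data, sim2$sets[[1]]$data)
})

test_that("frame variance follows the thickness-normalized thermal plus physiological model", {
  g <- slider_preset("slider2")
  ph <- tiny_phantom(g, nxy = 16L)
  vt <- 9; vp <- 4
  # dm_scale = 0: constant signal, so frame variance is pure noise
  sim <- simulate_acquisition(ph, g, noise_model(vt, vp, rho = 0),
                              n_meas = 600, seed = 2, dm_scale = 0)
  x <- sim$sets[[1]]$data
  resid <- sweep(x, 1:3, apply(x, 1:3, mean))
  emp_var <- mean(apply(resid, 1:3, stats::var))
  # stored thick-slice thermal SD is sqrt(vt)/n_set
  expect_equal(emp_var, vt / g$n_set^2 + vp, tolerance = 0.05)

  # doubling g quadruples the thermal contribution only
  simg <- simulate_acquisition(ph, g, noise_model(vt, vp, rho = 0, g_map = 2),
                               n_meas = 600, seed = 3, dm_scale = 0)
  xg <- simg$sets[[1]]$data
  residg <- sweep(xg, 1:3, apply(xg, 1:3, mean))
  empg <- mean(apply(residg, 1:3, stats::var))
  expect_equal(empg, 4 * vt / g$n_set^2 + vp, tolerance = 0.05)
})

test_that("physiological noise is AR(1) with the requested lag-1 correlation", {
  ac1 <- function(m) {
    mean(vapply(seq_len(nrow(m)), function(i) {
      v <- m[i, ]
      stats::cor(v[-length(v)], v[-1])
    }, numeric(1)))
  }
  set.seed(31)
  m_white <- ar1_noise(300, 400, var = 2, rho = 0)
  expect_equal(mean(apply(m_white, 1, stats::var)), 2, tolerance = 0.05)
  expect_lt(abs(ac1(m_white)), 0.02)
  m_corr <- ar1_noise(300, 400, var = 2, rho = 0.8)
  expect_equal(mean(apply(m_corr, 1, stats::var)), 2, tolerance = 0.05)
  expect_equal(ac1(m_corr), 0.8, tolerance = 0.05)

  # in-simulation: physiological-only noise carries the correlation
  g <- slider_preset("slider2")
  ph <- tiny_phantom(g, nxy = 16L)
  sim <- simulate_acquisition(ph, g, noise_model(0, 1, rho = 0.8),
                              n_meas = 300, seed = 4)
  x <- sim$sets[[1]]$data
  # remove the alternating label/control signal before autocorrelating
  resid <- sweep(x[, , , seq(1, 599, 2)], 1:3,
                 apply(x[, , , seq(1, 599, 2)], 1:3, mean))
  m <- matrix(resid, nrow = prod(dim(resid)[1:3]))
  expect_equal(ac1(m[sample(nrow(m), 200), ]), 0.8^2, tolerance = 0.08)
})

test_that("the reference passes interleave to the full thin grid", {
  g <- slider_preset("reference")
  ph <- tiny_phantom(g, nxy = 16L)
  sim <- simulate_reference(ph, g, quiet_noise(), n_meas = 2, seed = 1)
  idx1 <- sim$sets[[1]]$slice_indices
  idx2 <- sim$sets[[2]]$slice_indices
  expect_length(intersect(idx1, idx2), 0)
  expect_setequal(c(idx1, idx2), 0:47)

  merged <- merge_reference_passes(lapply(sim$sets, perfusion_frames))
  expect_equal(mean_volume(merged), sim$truth$dm, tolerance = 1e-12)
  m0 <- merge_reference_passes(sim$m0)
  expect_equal(m0$data[, , , 1], ph$m0, tolerance = 1e-12)

  expect_error(simulate_reference(ph, slider_preset("slider2"),
                                  quiet_noise(), 2), "reference")
})

test_that("noise model validates its parameter ranges", {
  expect_error(noise_model(-1), "variances")
  expect_error(noise_model(1, rho = 1), "rho")
  expect_error(noise_model(1, g_map = 0.5), "g-factor")
})
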