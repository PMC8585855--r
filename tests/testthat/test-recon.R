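test_that("filter factors take their closed-form values on an orthogonal operator", {
  # the reference operator is a permutation: all singular values are 1
  op <- build_forward_operator(slider_preset("reference"))
  inv0 <- tikhonov_inverse(op, 0)
  expect_equal(inv0$matrix %*% op$matrix, diag(48), tolerance = 1e-12)
  inv1 <- tikhonov_inverse(op, 1)
  # sigma / (sigma^2 + lambda) = 1/2 for every component
  expect_equal(inv1$matrix, t(op$matrix) / 2, tolerance = 1e-12)
  expect_false(inv0$rank_deficient)
  expect_equal(inv0$condition_number, 1)
})

test_that("the SVD inverse equals a dense normal-equations solve for all presets", {
  set.seed(21)
  for (preset in c("reference", "slider2", "slider3", "slider4")) {
    op <- build_forward_operator(slider_preset(preset))
    A <- as.matrix(op)
    for (lambda in c(0, 0.1, 0.3, 0.5)) {
      inv <- tikhonov_inverse(op, lambda)
      B <- matrix(rnorm(nrow(A) * 20), ncol = 20)
      x_svd <- inv$matrix %*% B
      x_ne <- solve(crossprod(A) + lambda * diag(ncol(A)), crossprod(A, B))
      expect_equal(x_svd, x_ne, tolerance = 1e-8,
                   info = sprintf("%s lambda=%g", preset, lambda))
    }
  }
})

test_that("noise-free acquisitions are recovered exactly at lambda = 0", {
  for (preset in c("slider2", "slider3", "slider4")) {
    g <- slider_preset(preset)
    ph <- tiny_phantom(g, nxy = 20L)
    sim <- simulate_acquisition(ph, g, quiet_noise(), n_meas = 1, seed = 1)
    inv <- tikhonov_inverse(sim$operator, 0)
    perf <- reconstruct_series(lapply(sim$sets, perfusion_frames), inv)
    err <- abs(mean_volume(perf) - sim$truth$dm)
    interior <- 2:(dim(err)[3] - 1L)
    expect_lt(max(err[, , interior]), 1e-6)
  }
})

test_that("reconstruction output vanishes as lambda grows without bound", {
  g <- tiny_geometry()
  op <- build_forward_operator(g)
  lr <- list(array(5, c(4, 4, 3)), array(5, c(4, 4, 3)))
  big <- reconstruct_volume(lr, op, lambda = 1e8)
  expect_lt(max(abs(big)), 1e-5)
})

test_that("high-frequency slice energy of the reconstruction is non-increasing in lambda", {
  g <- slider_preset("slider2")
  ph <- tiny_phantom(g, nxy = 16L)
  sim <- simulate_acquisition(ph, g, noise_model(var_thermal = 16),
                              n_meas = 8, seed = 7)
  hf_energy <- function(lambda) {
    inv <- tikhonov_inverse(sim$operator, lambda)
    v <- mean_volume(reconstruct_series(lapply(sim$sets, perfusion_frames),
                                        inv))
    nz <- dim(v)[3]
    sum((v[, , 2:nz] - v[, , 1:(nz - 1)])^2)
  }
  e <- vapply(c(0.05, 0.1, 0.3, 0.5), hf_energy, numeric(1))
  expect_true(all(diff(e) < 0))
})

test_that("series reconstruction is frame-wise and order-preserving", {
  g <- tiny_geometry()
  op <- build_forward_operator(g)
  inv <- tikhonov_inverse(op, 0.1)
  set.seed(22)
  arrays <- lapply(1:2, function(k) array(rnorm(4 * 4 * 3 * 6),
                                          c(4, 4, 3, 6)))
  series <- lapply(arrays, volume_series)
  hr <- reconstruct_series(series, inv)
  for (f in 1:6) {
    expect_equal(hr$data[, , , f],
                 reconstruct_volume(lapply(arrays, function(a) a[, , , f]),
                                    inv))
  }
  # permuting input frames permutes output frames identically
  perm <- c(3, 1, 6, 2, 5, 4)
  hr_perm <- reconstruct_series(
    lapply(arrays, function(a) volume_series(a[, , , perm])), inv)
  expect_equal(hr_perm$data, hr$data[, , , perm])
})

test_that("mismatched inputs are rejected with the offending set named", {
  g <- tiny_geometry()
  op <- build_forward_operator(g)
  inv <- tikhonov_inverse(op, 0.1)
  good <- array(0, c(4, 4, 3))
  expect_error(reconstruct_volume(list(good), inv), "expected 2")
  expect_error(reconstruct_volume(list(good, array(0, c(4, 5, 3))), inv),
               "shift set 2")
  s1 <- volume_series(array(0, c(4, 4, 3, 4)))
  s2 <- volume_series(array(0, c(4, 4, 3, 2)))
  expect_error(reconstruct_series(list(s1, s2), inv), "unequal frame counts")
  expect_error(tikhonov_inverse(op, -0.1), "lambda")
})
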