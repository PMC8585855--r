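test_that("the two-shift toy operator averages the expected thin pairs", {
  op <- build_forward_operator(tiny_geometry())   # 3 thick, 6 thin
  A <- as.matrix(op)
  expect_equal(dim(A), c(6L, 6L))
  # set 0: pairs {0,1}, {2,3}, {4,5}
  expect_equal(A[1, ], c(.5, .5, 0, 0, 0, 0))
  expect_equal(A[2, ], c(0, 0, .5, .5, 0, 0))
  expect_equal(A[3, ], c(0, 0, 0, 0, .5, .5))
  # set 1 (shifted one thin slice): {1,2}, {3,4}, {5, out-of-slab}
  expect_equal(A[4, ], c(0, .5, .5, 0, 0, 0))
  expect_equal(A[5, ], c(0, 0, 0, .5, .5, 0))
  expect_equal(A[6, ], c(0, 0, 0, 0, 0, .5))   # truncated, not renormalized
  expect_equal(op$row_map$set, rep(0:1, each = 3))
  expect_equal(op$row_map$thick_slice, rep(0:2, 2))
})

test_that("operators match a brute-force footprint construction", {
  for (preset in c("reference", "slider2", "slider3", "slider4")) {
    g <- slider_preset(preset)
    A <- as.matrix(build_forward_operator(g))
    B <- brute_force_matrix(g)
    expect_equal(A, B, info = preset)
    expect_equal(svd(A)$d, svd(B)$d, tolerance = 1e-12, info = preset)
  }
})

test_that("a constant thin-slice profile is preserved on interior rows", {
  for (preset in c("slider2", "slider3", "slider4")) {
    op <- build_forward_operator(slider_preset(preset))
    y <- apply_forward(op, rep(7, ncol(op$matrix)))
    interior <- rowSums(op$matrix != 0) == op$geometry$n_set
    expect_equal(unname(y[interior]), rep(7, sum(interior)), info = preset)
    # row sums: 1 on interior rows, <= 1 on truncated boundary rows
    expect_true(all(rowSums(op$matrix) <= 1 + 1e-12))
  }
})

test_that("a delta input excites exactly the rows whose footprint holds it", {
  op <- build_forward_operator(slider_preset("slider2"))
  j <- 10L                                   # 0-based thin slice
  x <- numeric(48); x[j + 1L] <- 1
  y <- apply_forward(op, x)
  expect_equal(which(y != 0), which(op$matrix[, j + 1L] != 0))
  expect_true(all(y[y != 0] == 0.5))
  expect_equal(apply_forward(op, numeric(48)), numeric(48))
})

test_that("forward application is a dense matrix-vector product", {
  op <- build_forward_operator(slider_preset("slider3"))
  set.seed(11)
  x <- rnorm(ncol(op$matrix))
  expect_equal(apply_forward(op, x), drop(brute_force_matrix(op$geometry) %*% x))
  X <- matrix(rnorm(ncol(op$matrix) * 5), ncol = 5)
  expect_equal(apply_forward(op, X), op$matrix %*% X)
})

test_that("shifting the input by n_set thin slices shifts each set's output by one thick slice", {
  g <- slider_preset("slider3")
  op <- build_forward_operator(g)
  n_set <- g$n_set
  set.seed(12)
  x <- rnorm(ncol(op$matrix))
  x_shift <- c(numeric(n_set), x[seq_len(length(x) - n_set)])
  y <- apply_forward(op, x)
  y_shift <- apply_forward(op, x_shift)
  for (k in 0:(n_set - 1L)) {
    rows <- which(op$row_map$set == k)
    interior <- 3:(length(rows) - 1L)       # skip slab-edge rows
    expect_equal(y_shift[rows][interior], y[rows][interior - 1L],
                 info = sprintf("set %d", k))
  }
})

test_that("the reference operator is a row permutation of the identity", {
  op <- build_forward_operator(slider_preset("reference"))
  A <- as.matrix(op)
  expect_equal(dim(A), c(48L, 48L))
  expect_true(all(rowSums(A != 0) == 1))
  expect_true(all(colSums(A != 0) == 1))
  expect_true(all(A[A != 0] == 1))
  expect_equal(svd(A)$d, rep(1, 48))
})

test_that("every thin slice is covered exactly once per interior set", {
  for (preset in c("slider2", "slider3", "slider4")) {
    op <- build_forward_operator(slider_preset(preset))
    g <- op$geometry
    for (k in 0:(g$n_set - 1L)) {
      Ak <- op$matrix[op$row_map$set == k, , drop = FALSE]
      cover <- colSums(Ak != 0)
      # all slices covered at most once within a set; the k slices the
      # shifted slab leaves behind (or pushes out) are the exception
      expect_true(all(cover <= 1), info = preset)
      expect_equal(sum(cover == 0), k, info = preset)
    }
  }
})

test_that("profile and dimension mismatches raise configuration errors", {
  g <- slider_preset("slider2")
  expect_error(build_forward_operator(g, slice_profile(3)), "support")
  op <- build_forward_operator(g)
  expect_error(apply_forward(op, numeric(47)), "47")
  expect_error(slice_profile(2, weights = c(-1, 2)), "non-negative")
  expect_equal(slice_profile(4)$weights, rep(0.25, 4))
})

test_that("operator export writes valid MatrixMarket coordinates", {
  op <- build_forward_operator(tiny_geometry())
  path <- withr::local_tempfile(fileext = ".mtx")
  write_operator_mm(op, path)
  lines <- readLines(path)
  expect_match(lines[1], "MatrixMarket")
  header <- scan(text = lines[2], quiet = TRUE)
  expect_equal(header[1:2], c(6, 6))
  entries <- read.table(text = lines[-(1:2)])
  A <- matrix(0, 6, 6)
  A[cbind(entries$V1, entries$V2)] <- entries$V3
  expect_equal(A, as.matrix(op))
})
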