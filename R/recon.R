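#' Tikhonov-regularized pseudo-inverse of the forward operator
#'
#' Computes `(A'A + lambda I)^-1 A'` through the singular value decomposition
#' of `A`: with `A = U diag(s) V'`, the inverse is `V diag(f) U'` with filter
#' factors `f_i = s_i / (s_i^2 + lambda)`.  For `lambda = 0` this is the
#' Moore-Penrose pseudo-inverse restricted to singular values above
#' `1e-10 * max(s)` (rank deficiency is reported in the diagnostics rather
#' than raised as an error).
#'
#' Singular values are those of the averaging-convention operator (boxcar
#' entries `1/n_set`, largest singular value near 1), so a given `lambda` is
#' comparable across protocols; no spectrum rescaling is applied.
#'
#' @param operator A [build_forward_operator()] result.
#' @param lambda Tikhonov regularization parameter, `>= 0`.
#' @return An object of class `slider_inverse`: list with the dense `matrix`
#'   (`n_hr` by `n_rows`), `lambda`, `singular_values`, `filter_factors`,
#'   `condition_number` (of `A`), `rank_deficient` flag, and the `operator`.
#' @examples
#' op <- build_forward_operator(slider_preset("slider2"))
#' inv <- tikhonov_inverse(op, lambda = 0.1)
#' range(inv$filter_factors)
#' @export
tikhonov_inverse <- function(operator, lambda) {
  stopifnot(inherits(operator, "slider_operator"))
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0)
    stop("'lambda' must be a single finite number >= 0", call. = FALSE)
  A <- operator$matrix
  sv <- svd(A)
  s <- sv$d
  tol <- 1e-10 * max(s)
  nonzero <- s > tol
  f <- numeric(length(s))
  if (lambda == 0) {
    f[nonzero] <- 1 / s[nonzero]
  } else {
    f <- s / (s^2 + lambda)
  }
  Ainv <- sv$v %*% (f * t(sv$u))
  structure(
    list(matrix = Ainv,
         lambda = lambda,
         singular_values = s,
         filter_factors = f * s,   # spectrum of A_inv A: s^2/(s^2+lambda)
         condition_number = if (any(nonzero)) max(s) / min(s[nonzero]) else Inf,
         rank_deficient = any(!nonzero),
         operator = operator),
    class = "slider_inverse"
  )
}

#' @export
print.slider_inverse <- function(x, ...) {
  cat(sprintf("SLIDER Tikhonov inverse (lambda = %g)\n", x$lambda))
  cat(sprintf("  %d x %d; singular values [%.4g, %.4g], condition %.4g%s\n",
              nrow(x$matrix), ncol(x$matrix),
              min(x$singular_values), max(x$singular_values),
              x$condition_number,
              if (x$rank_deficient) " (rank-deficient)" else ""))
  invisible(x)
}

# Stack per-set thick-slice volumes into the measurement matrix
# (rows ordered set-major to match the operator's row_map, columns are
# in-plane voxels).
stack_lr_sets <- function(lr_sets, operator) {
  geom <- operator$geometry
  n_sets_expected <- length(unique(operator$row_map$set))
  if (!is.list(lr_sets))
    stop("'lr_sets' must be a list with one volume per shift set",
         call. = FALSE)
  if (length(lr_sets) != n_sets_expected)
    stop(sprintf("expected %d shift-set volumes, got %d",
                 n_sets_expected, length(lr_sets)), call. = FALSE)
  dims <- lapply(lr_sets, dim)
  ref_dim <- dims[[1L]]
  if (length(ref_dim) != 3L)
    stop("each shift-set volume must be a 3-D array (x, y, slice)",
         call. = FALSE)
  for (k in seq_along(lr_sets)) {
    if (!identical(dims[[k]], ref_dim))
      stop(sprintf(
        "shift set %d has dimensions %s; expected %s (all sets must match)",
        k, paste(dims[[k]], collapse = "x"),
        paste(ref_dim, collapse = "x")), call. = FALSE)
    if (dims[[k]][3L] != geom$n_thick_slices)
      stop(sprintf(
        "shift set %d has %d slices; geometry expects %d thick slices",
        k, dims[[k]][3L], geom$n_thick_slices), call. = FALSE)
  }
  nxy <- prod(ref_dim[1:2])
  do.call(rbind, lapply(lr_sets, function(v) {
    matrix(v, nrow = nxy, ncol = ref_dim[3L])  |> t()
  }))
}

#' Reconstruct one high-resolution volume from shifted thick-slice volumes
#'
#' Applies the Tikhonov pseudo-inverse independently to every in-plane voxel
#' column (the slice-direction problem decouples over in-plane position):
#' `I_hr = (A'A + lambda I)^-1 A' I_lr`.
#'
#' @param lr_sets List of 3-D arrays `(x, y, thick slice)`, one per shift set,
#'   in set order.
#' @param inverse A [tikhonov_inverse()] result (or a `slider_operator`, in
#'   which case `lambda` must be given and the inverse is computed here).
#' @param lambda Regularization parameter, used only when `inverse` is an
#'   operator.
#' @return 3-D array `(x, y, hr slice)` on the thin-slice grid.
#' @export
reconstruct_volume <- function(lr_sets, inverse, lambda = NULL) {
  if (inherits(inverse, "slider_operator")) {
    if (is.null(lambda))
      stop("supply 'lambda' when passing a forward operator", call. = FALSE)
    inverse <- tikhonov_inverse(inverse, lambda)
  }
  stopifnot(inherits(inverse, "slider_inverse"))
  op <- inverse$operator
  Y <- stack_lr_sets(lr_sets, op)
  X <- inverse$matrix %*% Y
  d <- dim(lr_sets[[1L]])
  array(t(X), dim = c(d[1L], d[2L], nrow(inverse$matrix)))
}

#' Reconstruct a high-resolution time series
#'
#' Frame `f` of the output is reconstructed from frame `f` of every shift
#' set's series; frame labels are taken from the first set and preserved.
#' Sets with unequal frame counts are an error (no implicit truncation):
#' matched repetitions per set are assumed.
#'
#' @param lr_series List of [volume_series] objects (or 4-D arrays), one per
#'   shift set, with identical frame counts and in-plane dimensions.
#' @param inverse A [tikhonov_inverse()] result.
#' @return A [volume_series] on the thin-slice grid with the same frame
#'   labels.
#' @export
reconstruct_series <- function(lr_series, inverse) {
  stopifnot(inherits(inverse, "slider_inverse"))
  op <- inverse$operator
  arrays <- lapply(lr_series, function(s) {
    if (inherits(s, "volume_series")) s$data else s
  })
  labels <- if (inherits(lr_series[[1L]], "volume_series"))
    lr_series[[1L]]$frame_labels else NULL
  nf <- vapply(arrays, function(a) dim(a)[4L], integer(1))
  if (length(unique(nf)) != 1L)
    stop(sprintf(
      "shift sets have unequal frame counts (%s); refusing to truncate",
      paste(nf, collapse = ", ")), call. = FALSE)
  nf <- nf[1L]
  d <- dim(arrays[[1L]])
  out <- array(0, dim = c(d[1L], d[2L], nrow(inverse$matrix), nf))
  for (f in seq_len(nf)) {
    out[, , , f] <- reconstruct_volume(
      lapply(arrays, function(a) a[, , , f, drop = TRUE]), inverse)
  }
  geom <- op$geometry
  volume_series(out,
                frame_labels = labels,
                spacing_mm = c(NA_real_, NA_real_, geom$thin_thickness_mm),
                geometry = geom)
}

#' Reconstruction diagnostics as a list (JSON-ready)
#'
#' @param inverse A `slider_inverse`.
#' @return List with lambda, singular values, filter factors, condition
#'   number and rank-deficiency flag.
#' @export
recon_diagnostics <- function(inverse) {
  stopifnot(inherits(inverse, "slider_inverse"))
  list(lambda = inverse$lambda,
       singular_values = inverse$singular_values,
       filter_factors = inverse$filter_factors,
       condition_number = inverse$condition_number,
       rank_deficient = inverse$rank_deficient)
}
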