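#' Slice excitation profile
#'
#' The sensitivity profile of one acquired thick slice expressed on the thin
#' slice grid.  The boxcar profile — equal weight on each of the `support`
#' thin slices covered, weights summing to one (averaging convention, so the
#' thick-slice signal is the mean of its thin slices and perfusion/M0 units
#' are preserved across resolutions) — is the model used by the reconstruction;
#' the abstraction exists so that non-ideal profiles can be added without
#' touching the solver.
#'
#' @param support_thin_slices Number of thin slices covered by one thick slice.
#' @param kind Profile family; only `"boxcar"` is implemented.
#' @param weights Optional custom non-negative weights (length `support`);
#'   they are normalized to sum to one.
#' @return An object of class `slice_profile` with fields `kind`,
#'   `support_thin_slices` and `weights`.
#' @export
slice_profile <- function(support_thin_slices, kind = "boxcar",
                          weights = NULL) {
  support_thin_slices <- as.integer(support_thin_slices)
  if (support_thin_slices < 1L)
    stop("profile support must be a positive integer", call. = FALSE)
  if (is.null(weights)) {
    if (kind != "boxcar")
      stop(sprintf("unknown slice profile kind '%s'", kind), call. = FALSE)
    weights <- rep(1 / support_thin_slices, support_thin_slices)
  } else {
    if (length(weights) != support_thin_slices)
      stop("length(weights) must equal support_thin_slices", call. = FALSE)
    if (any(weights < 0) || sum(weights) <= 0)
      stop("profile weights must be non-negative with positive sum",
           call. = FALSE)
    weights <- weights / sum(weights)
  }
  structure(list(kind = kind,
                 support_thin_slices = support_thin_slices,
                 weights = weights),
            class = "slice_profile")
}

#' Forward operator mapping thin-slice columns to shifted thick-slice stacks
#'
#' Builds the banded linear operator `A` of the slice-direction
#' super-resolution problem `A I_hr = I_lr`.  Row `(k, j)` (acquisition set
#' `k`, thick slice `j`, both 0-based) averages the thin slices in the
#' footprint of that thick slice: thin indices
#' `j * n_set + shift(k) + (0 .. support-1)`.  Footprints that extend past
#' the nominal slab are truncated to in-slab thin slices *without*
#' renormalization (zero signal outside the slab); Tikhonov regularization
#' stabilizes the weakly determined edge slices.
#'
#' Rows are ordered set-major: all thick slices of set 0, then set 1, etc.
#'
#' @param geometry A [slider_geometry()] with `n_set >= 1`.
#' @param profile A [slice_profile()]; defaults to the boxcar of support
#'   `n_set`.  Its support must equal `n_set` for the boxcar model.
#' @return An object of class `slider_operator`: list with the dense `matrix`
#'   (`n_set * n_thick_slices` rows by `hr_grid(geometry)$n_slices` columns),
#'   `row_map` (data.frame of 0-based `set` and `thick_slice` per row),
#'   `geometry` and `profile`.
#' @examples
#' op <- build_forward_operator(slider_preset("slider2"))
#' dim(op$matrix)  # 48 x 48
#' @export
build_forward_operator <- function(geometry, profile = NULL) {
  stopifnot(inherits(geometry, "slider_geometry"))
  if (is.null(profile)) profile <- slice_profile(geometry$n_set)
  stopifnot(inherits(profile, "slice_profile"))
  if (profile$kind == "boxcar" &&
      profile$support_thin_slices != geometry$n_set)
    stop(sprintf(paste0(
      "boxcar profile support (%d) must equal n_set (%d): each thick ",
      "slice covers n_set thin slices"),
      profile$support_thin_slices, geometry$n_set), call. = FALSE)
  if (is_reference(geometry) && profile$support_thin_slices != 1L)
    stop("reference (n_set = 1) protocol requires profile support 1",
         call. = FALSE)

  n_set <- geometry$n_set
  n_thick <- geometry$n_thick_slices
  n_hr <- hr_grid(geometry)$n_slices
  shifts <- if (is_reference(geometry)) c(0L, 1L) else set_shifts(geometry)
  # Within one set, consecutive thick slices step by n_set thin slices
  # (contiguous thick slab); the reference's two interleaved passes sample
  # every other thin slice (100% gap), i.e. stride 2 with support 1.
  stride <- if (is_reference(geometry)) 2L else n_set
  n_rows <- length(shifts) * n_thick

  A <- matrix(0, nrow = n_rows, ncol = n_hr)
  row_set <- integer(n_rows)
  row_thick <- integer(n_rows)
  support <- profile$support_thin_slices
  w <- profile$weights
  for (k in seq_along(shifts)) {
    for (j in seq_len(n_thick)) {
      r <- (k - 1L) * n_thick + j
      row_set[r] <- k - 1L
      row_thick[r] <- j - 1L
      thin0 <- (j - 1L) * stride + shifts[k]   # 0-based first thin index
      idx <- thin0 + seq_len(support) - 1L
      keep <- idx >= 0L & idx < n_hr
      A[r, idx[keep] + 1L] <- w[keep]
    }
  }

  structure(
    list(matrix = A,
         row_map = data.frame(set = row_set, thick_slice = row_thick),
         geometry = geometry,
         profile = profile),
    class = "slider_operator"
  )
}

#' @export
as.matrix.slider_operator <- function(x, ...) x$matrix

#' Apply the forward operator to a thin-slice column
#'
#' Computes the stacked thick-slice measurements `A x` for one thin-slice
#' column (or a matrix whose columns are thin-slice profiles of independent
#' in-plane voxels — the problem decouples over in-plane position).
#'
#' @param operator A [build_forward_operator()] result.
#' @param hr_column Numeric vector of length `ncol(A)`, or a matrix with that
#'   many rows.
#' @return Vector (or matrix) of length `nrow(A)`, ordered by `row_map`
#'   (set-major).
#' @export
apply_forward <- function(operator, hr_column) {
  stopifnot(inherits(operator, "slider_operator"))
  A <- operator$matrix
  if (is.matrix(hr_column)) {
    if (nrow(hr_column) != ncol(A))
      stop(sprintf("hr input has %d rows; operator expects %d thin slices",
                   nrow(hr_column), ncol(A)), call. = FALSE)
    return(A %*% hr_column)
  }
  if (length(hr_column) != ncol(A))
    stop(sprintf("hr column has length %d; operator expects %d thin slices",
                 length(hr_column), ncol(A)), call. = FALSE)
  drop(A %*% hr_column)
}

#' Export an operator in MatrixMarket coordinate format
#'
#' Writes the nonzero entries of the forward matrix as a plain-text
#' MatrixMarket `coordinate real general` file, for inspection with external
#' tools.
#'
#' @param operator A `slider_operator`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_operator_mm <- function(operator, path) {
  stopifnot(inherits(operator, "slider_operator"))
  A <- operator$matrix
  nz <- which(A != 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 2L], nz[, 1L]), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate real general", con)
  writeLines(sprintf("%d %d %d", nrow(A), ncol(A), nrow(nz)), con)
  writeLines(sprintf("%d %d %.17g", nz[, 1L], nz[, 2L],
                     A[nz]), con)
  invisible(path)
}

#' @export
print.slider_operator <- function(x, ...) {
  cat(sprintf(
    "SLIDER forward operator: %d measurements (%d sets x %d thick) -> %d thin slices\n",
    nrow(x$matrix), length(unique(x$row_map$set)),
    x$geometry$n_thick_slices, ncol(x$matrix)))
  cat(sprintf("  profile: %s, support %d\n",
              x$profile$kind, x$profile$support_thin_slices))
  invisible(x)
}
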