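#' 4-D image time series
#'
#' A light container for a 4-D stack `(x, y, slice, frame)` with per-frame
#' labels and voxel spacing.  Frame labels are one of `"label"`, `"control"`,
#' `"m0"` or `"perfusion"`; an ASL series alternates label/control frames in
#' acquisition order.
#'
#' @param data 3-D or 4-D numeric array; a 3-D array becomes a single-frame
#'   series.
#' @param frame_labels Character vector, one per frame, or `NULL` (labels
#'   `"unknown"`).
#' @param spacing_mm Numeric length-3 voxel spacing `(dx, dy, dz)`; `NA`
#'   entries allowed where unknown.
#' @param geometry Optional [slider_geometry()] the series was acquired
#'   under.
#' @param slice_indices Optional 0-based indices of the slices on a parent
#'   thin grid (used by the interleaved reference passes).
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, frame_labels = NULL,
                          spacing_mm = c(NA_real_, NA_real_, NA_real_),
                          geometry = NULL, slice_indices = NULL) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L)
    stop("'data' must be a 3-D or 4-D array", call. = FALSE)
  nf <- dim(data)[4L]
  if (is.null(frame_labels)) frame_labels <- rep("unknown", nf)
  if (length(frame_labels) != nf)
    stop(sprintf("%d frame labels for %d frames", length(frame_labels), nf),
         call. = FALSE)
  ok <- frame_labels %in% c("label", "control", "m0", "perfusion", "unknown")
  if (!all(ok))
    stop(sprintf("unknown frame label(s): %s",
                 paste(unique(frame_labels[!ok]), collapse = ", ")),
         call. = FALSE)
  structure(
    list(data = data,
         frame_labels = frame_labels,
         spacing_mm = as.numeric(spacing_mm),
         geometry = geometry,
         slice_indices = slice_indices),
    class = "volume_series"
  )
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume_series: %d x %d x %d voxels, %d frame(s)\n",
              d[1L], d[2L], d[3L], d[4L]))
  cat(sprintf("  spacing: %s mm; labels: %s\n",
              paste(signif(x$spacing_mm, 4), collapse = " x "),
              paste(utils::head(unique(x$frame_labels), 4), collapse = "/")))
  invisible(x)
}

#' Number of frames in a series
#' @param series A [volume_series].
#' @return Integer frame count.
#' @export
n_frames <- function(series) {
  stopifnot(inherits(series, "volume_series"))
  dim(series$data)[4L]
}

#' Pairwise perfusion-difference frames of a label/control series
#'
#' Subtracts consecutive label/control pairs in acquisition order
#' (`control - label`, the perfusion-weighted signal `dM`), producing one
#' perfusion frame per pair.  The series must contain alternating
#' label/control frames (either order within each pair).
#'
#' @param series A [volume_series] of alternating label/control frames.
#' @return A [volume_series] of `"perfusion"` frames, half as many frames.
#' @export
perfusion_frames <- function(series) {
  stopifnot(inherits(series, "volume_series"))
  lab <- series$frame_labels
  nf <- length(lab)
  if (nf < 2L || nf %% 2L != 0L)
    stop("label/control series must have an even number of frames >= 2",
         call. = FALSE)
  first <- lab[seq(1L, nf, by = 2L)]
  second <- lab[seq(2L, nf, by = 2L)]
  if (!(all(first == "label") && all(second == "control")) &&
      !(all(first == "control") && all(second == "label")))
    stop("frames must alternate label/control in consecutive pairs",
         call. = FALSE)
  sgn <- if (first[1L] == "label") 1 else -1
  d <- dim(series$data)
  a <- series$data[, , , seq(1L, nf, by = 2L), drop = FALSE]
  b <- series$data[, , , seq(2L, nf, by = 2L), drop = FALSE]
  volume_series(sgn * (b - a),
                frame_labels = rep("perfusion", nf %/% 2L),
                spacing_mm = series$spacing_mm,
                geometry = series$geometry,
                slice_indices = series$slice_indices)
}

#' Mean volume of a series
#' @param series A [volume_series].
#' @return 3-D array: voxelwise mean across frames.
#' @export
mean_volume <- function(series) {
  stopifnot(inherits(series, "volume_series"))
  apply(series$data, c(1, 2, 3), mean)
}
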