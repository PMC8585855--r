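#' Gray-matter mask from a probability map
#'
#' Thresholds a tissue probability map: the mask is `probability >= threshold`
#' (the conventional cutoff for a conservative GM mask is 0.9).
#'
#' @param probability_map 3-D array of probabilities in `[0, 1]`.
#' @param threshold Probability cutoff (default 0.9).
#' @return Logical array of the same shape.  An empty mask is an error,
#'   since every masked statistic would be undefined.
#' @export
gm_mask <- function(probability_map, threshold = 0.9) {
  if (any(probability_map < 0 | probability_map > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  mask <- !is.na(probability_map) & probability_map >= threshold
  if (!any(mask))
    stop(sprintf("empty mask: no probability >= %g", threshold),
         call. = FALSE)
  mask
}

as_frame_array <- function(x) {
  if (inherits(x, "volume_series")) x <- x$data
  if (length(dim(x)) != 4L)
    stop("expected a volume_series or 4-D array", call. = FALSE)
  x
}

degenerate_value <- function(value, degenerate, n_mask = NA_integer_) {
  structure(value, degenerate = degenerate, n_mask = n_mask)
}

#' Spatial SNR by the even/odd sum-difference method
#'
#' Even- and odd-numbered perfusion frames (0-based acquisition order) are
#' averaged separately; their sum and difference images are formed, and
#' `sSNR = mean(sum within mask) / (sd(difference within mask) / sqrt(2))`.
#' The difference image cancels the (common) signal, so its spatial SD
#' estimates the noise level while being robust to spatially inhomogeneous
#' noise.
#'
#' @param perfusion_series A [volume_series] (or 4-D array) of perfusion
#'   frames; at least 2 frames.
#' @param mask Logical 3-D array, non-empty.
#' @return The sSNR as a double with attributes `degenerate` (TRUE when the
#'   difference image has zero SD, in which case the value is `Inf`) and
#'   `n_mask`.
#' @export
spatial_snr <- function(perfusion_series, mask) {
  x <- as_frame_array(perfusion_series)
  nf <- dim(x)[4L]
  if (nf < 2L)
    stop("spatial SNR needs at least 2 perfusion frames", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  even <- seq(1L, nf, by = 2L)   # acquisition frames 0, 2, ... (0-based)
  odd <- seq(2L, nf, by = 2L)
  E <- apply(x[, , , even, drop = FALSE], c(1, 2, 3), mean)
  O <- apply(x[, , , odd, drop = FALSE], c(1, 2, 3), mean)
  sum_img <- E + O
  diff_img <- E - O
  noise_sd <- stats::sd(diff_img[mask])
  if (!is.finite(noise_sd) || noise_sd == 0)
    return(degenerate_value(Inf, TRUE, sum(mask)))
  degenerate_value(mean(sum_img[mask]) / (noise_sd / sqrt(2)),
                   FALSE, sum(mask))
}

#' Temporal SNR within a mask
#'
#' Per-voxel mean divided by per-voxel SD across frames.  By default the
#' per-voxel ratios are averaged within the mask (`aggregate = "voxel-mean"`,
#' the map-then-average convention); `"ratio-of-means"` instead divides the
#' mask-average mean by the mask-average SD.  Voxels with zero temporal SD
#' are excluded and counted.
#'
#' @param perfusion_series A [volume_series] or 4-D array, >= 2 frames.
#' @param mask Logical 3-D array.
#' @param aggregate `"voxel-mean"` (default) or `"ratio-of-means"`.
#' @return The tSNR as a double with attributes `degenerate` (TRUE when no
#'   voxel has nonzero temporal SD), `n_mask` and `n_zero_sd`.
#' @export
temporal_snr <- function(perfusion_series, mask,
                         aggregate = c("voxel-mean", "ratio-of-means")) {
  aggregate <- match.arg(aggregate)
  x <- as_frame_array(perfusion_series)
  nf <- dim(x)[4L]
  if (nf < 2L)
    stop("temporal SNR needs at least 2 frames", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  nvox <- prod(dim(x)[1:3])
  m <- matrix(x, nrow = nvox)[as.vector(mask), , drop = FALSE]
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  keep <- sdv > 0
  n_zero <- sum(!keep)
  if (!any(keep)) {
    out <- degenerate_value(Inf, TRUE, sum(mask))
    attr(out, "n_zero_sd") <- n_zero
    return(out)
  }
  val <- if (aggregate == "voxel-mean") mean(mu[keep] / sdv[keep])
         else mean(mu[keep]) / mean(sdv[keep])
  out <- degenerate_value(val, FALSE, sum(mask))
  attr(out, "n_zero_sd") <- n_zero
  out
}

#' Slice-shift blur correlation
#'
#' Pearson correlation between a volume and its copy shifted one slice along
#' the slice axis, over the overlapping slab with all voxels collapsed into
#' a vector.  Sharper volumes decorrelate faster across slices, so larger
#' `r` indicates more slice-direction blur.
#'
#' @param volume 3-D array with at least 2 slices (a single-frame
#'   [volume_series] is accepted).
#' @param mask Optional logical 3-D array; a voxel pair enters the
#'   correlation only if the mask is TRUE at both slice positions.  Default
#'   uses all voxels of the overlapping slab.
#' @return Pearson `r` with attribute `degenerate` (TRUE, value `NA`, for a
#'   constant volume).
#' @export
blur_correlation <- function(volume, mask = NULL) {
  if (inherits(volume, "volume_series")) {
    if (n_frames(volume) != 1L)
      stop("blur_correlation expects a single volume", call. = FALSE)
    volume <- volume$data[, , , 1L]
  }
  d <- dim(volume)
  if (length(d) != 3L || d[3L] < 2L)
    stop("volume must be 3-D with >= 2 slices", call. = FALSE)
  nz <- d[3L]
  a <- volume[, , 1:(nz - 1L)]
  b <- volume[, , 2:nz]
  if (!is.null(mask)) {
    keep <- mask[, , 1:(nz - 1L)] & mask[, , 2:nz]
    if (!any(keep)) stop("mask leaves no overlapping voxels", call. = FALSE)
    a <- a[keep]; b <- b[keep]
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(degenerate_value(NA_real_, TRUE))
  degenerate_value(stats::cor(as.vector(a), as.vector(b)), FALSE)
}

gaussian_kernel_1d <- function(fwhm_vox) {
  if (fwhm_vox <= 0) return(1)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  radius <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-radius):radius / sigma)^2)
  k / sum(k)
}

#' Gaussian smoothing along the slice axis
#'
#' 1-D Gaussian convolution along the third (slice) axis only, with
#' reflecting boundaries (avoids the edge darkening a zero-padded kernel
#' would introduce, which would bias the blur correlation).
#'
#' @param volume 3-D array.
#' @param fwhm_vox Kernel full width at half maximum in voxel (slice) units;
#'   `0` returns the input unchanged.
#' @return Smoothed 3-D array.
#' @export
smooth_slices <- function(volume, fwhm_vox) {
  d <- dim(volume)
  if (length(d) != 3L) stop("volume must be 3-D", call. = FALSE)
  if (fwhm_vox < 0) stop("'fwhm_vox' must be >= 0", call. = FALSE)
  if (fwhm_vox == 0) return(volume)
  k <- gaussian_kernel_1d(fwhm_vox)
  radius <- (length(k) - 1L) %/% 2L
  nz <- d[3L]
  # reflect-pad slice indices: ... 2 1 | 1 2 ... nz | nz nz-1 ...
  idx <- c(rev(seq_len(min(radius, nz))),
           seq_len(nz),
           rev(seq_len(nz))[seq_len(min(radius, nz))])
  while (length(idx) < nz + 2L * radius) {      # radius > nz: keep reflecting
    idx <- c(rev(idx[seq_len(min(radius, length(idx)))]), idx)
    idx <- idx[seq_len(nz + 2L * radius)]
  }
  padded <- volume[, , idx, drop = FALSE]
  out <- array(0, dim = d)
  for (j in seq_along(k)) {
    out <- out + k[j] * padded[, , j:(j + nz - 1L), drop = FALSE]
  }
  out
}

#' Match a volume's slice blur to a target correlation
#'
#' Finds, by bisection, the slice-direction Gaussian FWHM whose smoothed
#' volume has [blur_correlation()] equal to `target_r` (within `tol`).  The
#' blur correlation is monotone non-decreasing in the FWHM, so the solution
#' is unique when it exists.
#'
#' @param volume 3-D array.
#' @param target_r Target Pearson correlation.
#' @param fwhm_bounds Search interval in voxels (default `c(0, 8)`).
#' @param tol Tolerance on the achieved correlation (default 1e-3).
#' @param mask Optional mask forwarded to [blur_correlation()].
#' @return List with `fwhm_vox`, `volume` (smoothed), and `r` (achieved
#'   correlation).  Errors if `target_r` is below the unsmoothed correlation
#'   or above what the upper bound reaches.
#' @export
match_blur <- function(volume, target_r, fwhm_bounds = c(0, 8),
                       tol = 1e-3, mask = NULL) {
  if (inherits(volume, "volume_series")) volume <- volume$data[, , , 1L]
  r_at <- function(f) {
    as.numeric(blur_correlation(smooth_slices(volume, f), mask = mask))
  }
  lo <- fwhm_bounds[1L]; hi <- fwhm_bounds[2L]
  r_lo <- r_at(lo); r_hi <- r_at(hi)
  if (target_r < r_lo - tol)
    stop(sprintf(
      "target r = %.4f is below the unsmoothed correlation %.4f",
      target_r, r_lo), call. = FALSE)
  if (target_r > r_hi + tol)
    stop(sprintf(
      "target r = %.4f not reachable within FWHM bound %g (r = %.4f there)",
      target_r, hi, r_hi), call. = FALSE)
  if (target_r <= r_lo + tol && lo == 0) {
    return(list(fwhm_vox = lo, volume = smooth_slices(volume, lo), r = r_lo))
  }
  for (i in seq_len(60L)) {
    mid <- (lo + hi) / 2
    r_mid <- r_at(mid)
    if (abs(r_mid - target_r) <= tol) {
      return(list(fwhm_vox = mid, volume = smooth_slices(volume, mid),
                  r = r_mid))
    }
    if (r_mid < target_r) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  list(fwhm_vox = mid, volume = smooth_slices(volume, mid), r = r_at(mid))
}

#' Assemble an SNR report for one reconstruction condition
#'
#' @param perfusion_series Perfusion-frame [volume_series] or 4-D array.
#' @param mask Logical GM mask.
#' @param condition Label for the condition (e.g. `"slider2"`).
#' @param lambda Regularization parameter used (recorded only).
#' @return Object of class `snr_report`: one-row data.frame with `condition`,
#'   `lambda`, `ssnr`, `tsnr`, `blur_corr`, `n_mask`, `degenerate`.
#' @export
snr_report <- function(perfusion_series, mask, condition = "unnamed",
                       lambda = NA_real_) {
  x <- as_frame_array(perfusion_series)
  s <- spatial_snr(x, mask)
  t <- temporal_snr(x, mask)
  mean_img <- apply(x, c(1, 2, 3), mean)
  b <- blur_correlation(mean_img)
  out <- data.frame(condition = condition,
                    lambda = lambda,
                    ssnr = as.numeric(s),
                    tsnr = as.numeric(t),
                    blur_corr = as.numeric(b),
                    n_mask = attr(s, "n_mask"),
                    degenerate = attr(s, "degenerate") ||
                      attr(t, "degenerate") || attr(b, "degenerate"))
  class(out) <- c("snr_report", "data.frame")
  out
}
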