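#' Parameters of the single-compartment CBF model
#'
#' Constants of the standard single-compartment pCASL quantification model:
#' `CBF = 6000 * lambda_p * dM * exp(PLD / T1b) /
#'        (2 * alpha * T1b_s * M0 * (1 - exp(-tau / T1b)))`
#' in ml/100 g/min, where `dM` is the label/control difference signal, `M0`
#' the equilibrium magnetization, `tau` the labeling duration, `PLD` the
#' (slice-dependent) post-labeling delay, `T1b` the longitudinal relaxation
#' time of arterial blood (`T1b_s` in seconds), `alpha` the labeling
#' efficiency and `lambda_p` the blood-brain partition coefficient.
#'
#' @param alpha Labeling efficiency, `0 < alpha <= 1` (default 0.85).
#' @param blood_t1_ms T1 of arterial blood in ms (default 1650 at 3 T).
#' @param partition_coefficient Blood-brain partition coefficient in ml/g
#'   (default 0.9).
#' @param label_duration_ms pCASL labeling duration in ms (default 1500).
#' @param pld_ms Nominal post-labeling delay in ms (default 1800).
#' @param m0_threshold_frac Voxels with M0 below this fraction of the robust
#'   (99th percentile) M0 maximum are masked out of the CBF map
#'   (default 0.1).
#' @return Object of class `cbf_params`.
#' @export
cbf_params <- function(alpha = 0.85,
                       blood_t1_ms = 1650,
                       partition_coefficient = 0.9,
                       label_duration_ms = 1500,
                       pld_ms = 1800,
                       m0_threshold_frac = 0.1) {
  if (alpha <= 0 || alpha > 1)
    stop("'alpha' must satisfy 0 < alpha <= 1", call. = FALSE)
  if (blood_t1_ms <= 0) stop("'blood_t1_ms' must be > 0", call. = FALSE)
  if (partition_coefficient <= 0)
    stop("'partition_coefficient' must be > 0", call. = FALSE)
  if (label_duration_ms <= 0)
    stop("'label_duration_ms' must be > 0", call. = FALSE)
  if (pld_ms < 0) stop("'pld_ms' must be >= 0", call. = FALSE)
  structure(list(alpha = alpha,
                 blood_t1_ms = blood_t1_ms,
                 partition_coefficient = partition_coefficient,
                 label_duration_ms = label_duration_ms,
                 pld_ms = pld_ms,
                 m0_threshold_frac = m0_threshold_frac),
            class = "cbf_params")
}

# dM = kinetic_factor(PLD) * M0 * CBF: the factor linking the difference
# signal to CBF in the single-compartment model (used forwards by the
# simulator and backwards by quantify_cbf).
asl_kinetic_factor <- function(params, pld_ms) {
  t1b <- params$blood_t1_ms
  2 * params$alpha * (t1b / 1000) *
    (1 - exp(-params$label_duration_ms / t1b)) *
    exp(-pld_ms / t1b) /
    (6000 * params$partition_coefficient)
}

#' Per-thin-slice post-labeling delay offsets on the reconstruction grid
#'
#' Slice groups are read out sequentially, so each acquired thick slice sees
#' the nominal PLD plus its group's timing offset.  On the reconstructed
#' thin grid, a thin slice inherits the offset of the unshifted (set 0)
#' thick slice that contains it; every thin slice therefore has exactly one
#' offset.  For the two-pass reference, a thin slice inherits its pass's
#' thick-slice-position group offset (the passes share the group schedule).
#'
#' @param geometry A [slider_geometry()].
#' @return Numeric vector of per-thin-slice timing offsets in ms, length
#'   `hr_grid(geometry)$n_slices`.
#' @export
hr_pld_offsets <- function(geometry) {
  stopifnot(inherits(geometry, "slider_geometry"))
  timing <- slice_group_timing(geometry)
  n_hr <- hr_grid(geometry)$n_slices
  stride <- if (is_reference(geometry)) 2L else geometry$n_set
  thin <- seq_len(n_hr) - 1L
  thick_of_thin <- pmin(thin %/% stride, geometry$n_thick_slices - 1L)
  timing$slice_offsets_ms[thick_of_thin + 1L]
}

# Difference signal dM implied by the phantom's perfusion under the
# single-compartment model with slice-dependent PLD.
perfusion_difference_signal <- function(phantom, geometry, params) {
  offsets <- hr_pld_offsets(geometry)
  pld <- params$pld_ms + offsets
  kin <- asl_kinetic_factor(params, pld)   # one factor per thin slice
  d <- dim(phantom$m0)
  sweep_fac <- array(rep(kin, each = d[1L] * d[2L]), dim = d)
  phantom$m0 * phantom$perfusion * sweep_fac
}

#' Quantify cerebral blood flow from a perfusion-difference and M0 volume
#'
#' Applies the single-compartment model (see [cbf_params()]) voxelwise with
#' slice-dependent post-labeling delay correction: slice `i` uses
#' `PLD_i = pld_ms + slice_offsets_ms[i]`.  Voxels whose M0 falls at or
#' below `m0_threshold_frac` times the robust M0 maximum (99th percentile)
#' are masked to `NA` and counted.
#'
#' @param perfusion_mean 3-D array: mean label/control difference signal
#'   `dM` on the thin grid.
#' @param m0 3-D array of the same shape: equilibrium magnetization.
#' @param params A [cbf_params()].
#' @param slice_offsets_ms Per-slice timing offsets in ms (length = slice
#'   count), typically [hr_pld_offsets()]; default all zero.
#' @return Object of class `cbf_map`: list with `cbf` (3-D array,
#'   ml/100 g/min, `NA` outside the M0 mask), `m0_mask`, `n_masked_out`,
#'   `params`, `pld_ms` (per-slice PLD actually used).
#' @export
quantify_cbf <- function(perfusion_mean, m0, params = cbf_params(),
                         slice_offsets_ms = NULL) {
  stopifnot(inherits(params, "cbf_params"))
  d <- dim(perfusion_mean)
  if (!identical(d, dim(m0)))
    stop("perfusion and M0 volumes must have identical dimensions",
         call. = FALSE)
  if (length(d) != 3L) stop("inputs must be 3-D volumes", call. = FALSE)
  if (is.null(slice_offsets_ms)) slice_offsets_ms <- rep(0, d[3L])
  if (length(slice_offsets_ms) != d[3L])
    stop(sprintf("%d slice offsets for %d slices",
                 length(slice_offsets_ms), d[3L]), call. = FALSE)

  pld <- params$pld_ms + slice_offsets_ms
  kin <- asl_kinetic_factor(params, pld)
  kin_vol <- array(rep(kin, each = d[1L] * d[2L]), dim = d)

  robust_max <- stats::quantile(m0, 0.99, na.rm = TRUE, names = FALSE)
  thr <- params$m0_threshold_frac * robust_max
  m0_mask <- is.finite(m0) & m0 > thr & m0 > 0

  cbf <- array(NA_real_, dim = d)
  cbf[m0_mask] <- perfusion_mean[m0_mask] / (kin_vol[m0_mask] * m0[m0_mask])

  structure(list(cbf = cbf,
                 m0_mask = m0_mask,
                 n_masked_out = sum(!m0_mask),
                 params = params,
                 pld_ms = pld),
            class = "cbf_map")
}

#' @export
print.cbf_map <- function(x, ...) {
  v <- x$cbf[x$m0_mask]
  cat(sprintf("cbf_map: %s voxels quantified, %d masked out\n",
              format(sum(x$m0_mask)), x$n_masked_out))
  cat(sprintf("  CBF range %.1f .. %.1f, median %.1f ml/100g/min\n",
              min(v), max(v), stats::median(v)))
  invisible(x)
}

#' Mean CBF within labeled regions of interest
#'
#' @param cbf_map A [quantify_cbf()] result (or a bare 3-D CBF array).
#' @param roi_labels Integer/factor 3-D array of region labels aligned with
#'   the CBF map; label 0 (or `NA`) is ignored as background.
#' @param roi_names Optional named translation of label values.
#' @return data.frame with one row per ROI: `roi`, `mean_cbf`, `n_voxels`,
#'   `n_na` (voxels excluded by the M0 mask), `empty` flag.
#' @export
roi_means <- function(cbf_map, roi_labels, roi_names = NULL) {
  cbf <- if (inherits(cbf_map, "cbf_map")) cbf_map$cbf else cbf_map
  if (!identical(dim(cbf), dim(roi_labels)))
    stop("ROI label volume and CBF map dimensions differ", call. = FALSE)
  labs <- sort(unique(as.vector(roi_labels)))
  labs <- labs[!is.na(labs) & labs != 0]
  rows <- lapply(labs, function(l) {
    sel <- !is.na(roi_labels) & roi_labels == l
    v <- cbf[sel]
    data.frame(
      roi = if (!is.null(roi_names) && !is.null(roi_names[[as.character(l)]]))
        roi_names[[as.character(l)]] else as.character(l),
      mean_cbf = if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
      n_voxels = sum(sel),
      n_na = sum(is.na(v)),
      empty = !any(sel)
    )
  })
  do.call(rbind, rows)
}
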