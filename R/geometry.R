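#' Acquisition geometry for SLIDER-SMS ASL
#'
#' Build a validated description of a slice-dithered (SLIDER) simultaneous
#' multi-slice (SMS) acquisition.  `n_set` thick-slice image sets are acquired,
#' each shifted along the slice axis by one thin-slice width relative to the
#' previous one; the acquired slice thickness is `n_set` times the target thin
#' thickness.  `n_set = 1` denotes the thin-slice reference protocol, acquired
#' as two interleaved passes with a 100% slice gap.
#'
#' All derived quantities used downstream (high-resolution slice grid,
#' coverage, slice-group timing) are computed from these fields.
#'
#' @param n_set Number of shifted acquisition sets (1, 2, 3 or 4).
#' @param thin_thickness_mm Target (reconstructed) slice thickness in mm.
#' @param mb_factor Multiband factor: slices excited simultaneously.
#' @param n_groups Number of sequentially excited slice groups per TR.
#' @param group_readout_ms Readout duration of one slice group in ms.
#' @param tr_ms Repetition time in ms.
#' @param label_duration_ms pCASL labeling duration in ms.
#' @param pld_ms Nominal post-labeling delay in ms (first slice group).
#' @param band_spacing_mm Distance between simultaneously excited bands in
#'   mm.  Defaults to `(n_groups - 1) * thick_thickness_mm`, the spacing that
#'   avoids inter-slice cross talk for a contiguous slab; if supplied it is
#'   validated against that rule.
#' @param shift_sign Direction of successive slab shifts in slice-index units:
#'   `+1` (default) shifts each later set toward higher slice indices.
#'
#' @return An object of class `slider_geometry`: a list with the supplied
#'   fields plus `thick_thickness_mm`, `n_thick_slices`, `shift_step_mm`.
#' @seealso [slider_preset()], [hr_grid()], [slice_group_timing()]
#' @examples
#' g <- slider_geometry(n_set = 4, thin_thickness_mm = 2,
#'                      mb_factor = 4, n_groups = 6)
#' hr_grid(g)$n_slices   # 96
#' @export
slider_geometry <- function(n_set,
                            thin_thickness_mm = 2,
                            mb_factor = 4,
                            n_groups = 6,
                            group_readout_ms = 45,
                            tr_ms = 5000,
                            label_duration_ms = 1500,
                            pld_ms = 1800,
                            band_spacing_mm = NULL,
                            shift_sign = 1L) {
  stop_cfg <- function(fmt, ...) {
    stop(sprintf(paste0("invalid acquisition geometry: ", fmt), ...),
         call. = FALSE)
  }
  for (nm in c("n_set", "thin_thickness_mm", "mb_factor", "n_groups",
               "group_readout_ms", "tr_ms", "label_duration_ms", "pld_ms")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_cfg("'%s' must be a single finite number", nm)
  }
  if (n_set != round(n_set) || n_set < 1)
    stop_cfg("'n_set' must be a positive integer (got %s)", n_set)
  if (!n_set %in% 1:4)
    stop_cfg("'n_set' must be 1 (reference), 2, 3 or 4 (got %d)", n_set)
  if (thin_thickness_mm <= 0) stop_cfg("'thin_thickness_mm' must be > 0")
  if (mb_factor < 1 || mb_factor != round(mb_factor))
    stop_cfg("'mb_factor' must be a positive integer")
  if (n_groups < 1 || n_groups != round(n_groups))
    stop_cfg("'n_groups' must be a positive integer")
  if (group_readout_ms < 0) stop_cfg("'group_readout_ms' must be >= 0")
  if (!shift_sign %in% c(-1L, 1L, -1, 1))
    stop_cfg("'shift_sign' must be +1 or -1")

  thick <- n_set * thin_thickness_mm
  n_thick <- as.integer(mb_factor * n_groups)

  default_spacing <- (n_groups - 1) * thick
  if (is.null(band_spacing_mm)) {
    band_spacing_mm <- default_spacing
  } else if (!isTRUE(all.equal(band_spacing_mm, default_spacing))) {
    stop_cfg(paste0(
      "band_spacing_mm (%g) inconsistent with (n_groups - 1) * ",
      "thick_thickness_mm = %g for thickness %g mm"),
      band_spacing_mm, default_spacing, thick)
  }

  total_readout <- n_groups * group_readout_ms
  if (total_readout > tr_ms)
    stop_cfg("total slice-group readout (%g ms) exceeds TR (%g ms)",
             total_readout, tr_ms)

  structure(
    list(
      n_set = as.integer(n_set),
      thin_thickness_mm = thin_thickness_mm,
      thick_thickness_mm = thick,
      n_thick_slices = n_thick,
      mb_factor = as.integer(mb_factor),
      n_groups = as.integer(n_groups),
      band_spacing_mm = band_spacing_mm,
      shift_step_mm = thin_thickness_mm,
      shift_sign = as.integer(sign(shift_sign)),
      group_readout_ms = group_readout_ms,
      tr_ms = tr_ms,
      label_duration_ms = label_duration_ms,
      pld_ms = pld_ms
    ),
    class = "slider_geometry"
  )
}

#' Named protocol presets
#'
#' The four protocols used throughout the package: `"reference"` (thin-slice
#' two-pass interleaved acquisition, `n_set = 1`), and `"slider2"`,
#' `"slider3"`, `"slider4"` (2/3/4 shifted sets at 4/6/8 mm acquired
#' thickness).  All share 2-mm thin slices, MB factor 4, six slice groups,
#' 45 ms group readout, TR 5000 ms, labeling duration 1500 ms and PLD 1800 ms.
#'
#' @param name One of `"reference"`, `"slider2"`, `"slider3"`, `"slider4"`.
#' @param ... Overrides passed on to [slider_geometry()].
#' @return A `slider_geometry`.
#' @examples
#' hr_grid(slider_preset("slider2"))$coverage_mm  # 96
#' @export
slider_preset <- function(name = c("reference", "slider2", "slider3", "slider4"),
                          ...) {
  name <- match.arg(name)
  n_set <- switch(name, reference = 1L, slider2 = 2L,
                  slider3 = 3L, slider4 = 4L)
  g <- slider_geometry(n_set = n_set, ...)
  g$preset <- name
  g
}

is_reference <- function(geometry) geometry$n_set == 1L

#' High-resolution (thin-slice) grid of a geometry
#'
#' The thin-slice grid on which super-resolution volumes are reconstructed:
#' the nominal unshifted slab divided into thin slices.  For the shifted
#' protocols this has `n_thick_slices * n_set` slices; for the two-pass
#' thin-slice reference it has `2 * n_thick_slices` slices (each pass covers
#' every other slice of a gap-free thin stack).
#'
#' Slice index 0 is the most inferior slice; positions are slice-centre
#' millimetres in the half-open slab `[0, coverage_mm)`.
#'
#' @param geometry A [slider_geometry()].
#' @return A list with `n_slices`, `positions_mm` (slice centres),
#'   `spacing_mm` and `coverage_mm`.
#' @export
hr_grid <- function(geometry) {
  stopifnot(inherits(geometry, "slider_geometry"))
  n_passes <- if (is_reference(geometry)) 2L else geometry$n_set
  n <- geometry$n_thick_slices * n_passes
  dz <- geometry$thin_thickness_mm
  list(
    n_slices = as.integer(n),
    positions_mm = (seq_len(n) - 0.5) * dz,
    spacing_mm = dz,
    coverage_mm = n * dz
  )
}

#' Per-thick-slice acquisition timing offsets
#'
#' Slice groups are excited sequentially within each TR, so a slice acquired
#' in group *k* is read out `k * group_readout_ms` after the first group.
#' Thick slices are assigned to groups in ascending interleaved order (slice
#' *j* belongs to group `j mod n_groups`); all `mb_factor` slices of a group
#' share one offset.
#'
#' @param geometry A [slider_geometry()].
#' @return A list with `group_offsets_ms` (length `n_groups`),
#'   `slice_offsets_ms` (length `n_thick_slices`, offset of each thick slice),
#'   `slice_group` (0-based group index per thick slice) and
#'   `total_readout_ms`.
#' @export
slice_group_timing <- function(geometry) {
  stopifnot(inherits(geometry, "slider_geometry"))
  k <- seq_len(geometry$n_groups) - 1L
  group_offsets <- k * geometry$group_readout_ms
  j <- seq_len(geometry$n_thick_slices) - 1L
  grp <- j %% geometry$n_groups
  list(
    group_offsets_ms = group_offsets,
    slice_offsets_ms = group_offsets[grp + 1L],
    slice_group = grp,
    total_readout_ms = geometry$n_groups * geometry$group_readout_ms
  )
}

#' Shift (in thin-slice index units) of each acquisition set
#'
#' Set `k` (0-based) is displaced by `shift_sign * k` thin slices relative to
#' the nominal slab.  For the reference protocol the two interleaved passes
#' acquire the even and odd thin slices and the "shift" is the pass offset.
#'
#' @param geometry A [slider_geometry()].
#' @return Integer vector of per-set shifts, length `n_set` (or 2 for the
#'   reference protocol's passes).
#' @export
set_shifts <- function(geometry) {
  stopifnot(inherits(geometry, "slider_geometry"))
  n <- if (is_reference(geometry)) 2L else geometry$n_set
  geometry$shift_sign * (seq_len(n) - 1L)
}

#' @export
print.slider_geometry <- function(x, ...) {
  grid <- hr_grid(x)
  cat(sprintf(
    "SLIDER-SMS acquisition geometry%s\n",
    if (!is.null(x$preset)) sprintf(" (preset '%s')", x$preset) else ""))
  cat(sprintf("  sets: %d, thin %g mm -> thick %g mm\n",
              x$n_set, x$thin_thickness_mm, x$thick_thickness_mm))
  cat(sprintf("  MB %d x %d groups = %d thick slices/TR (band spacing %g mm)\n",
              x$mb_factor, x$n_groups, x$n_thick_slices, x$band_spacing_mm))
  cat(sprintf("  HR grid: %d slices of %g mm, coverage %g mm\n",
              grid$n_slices, grid$spacing_mm, grid$coverage_mm))
  cat(sprintf("  timing: TR %g ms, label %g ms, PLD %g ms, readout %d x %g ms\n",
              x$tr_ms, x$label_duration_ms, x$pld_ms,
              x$n_groups, x$group_readout_ms))
  invisible(x)
}
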