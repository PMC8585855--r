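#' Digital brain-like phantom on the thin-slice grid
#'
#' A deterministic (seeded) 3-D phantom with concentric tissue compartments —
#' background, gray matter (GM) shell, white matter (WM) core and a central
#' CSF cavity — inside a smoothly perturbed ellipsoid.  Tissue boundaries are
#' curved and oblique to the slice axis, so they span several thin slices and
#' make slice-direction super-resolution informative.  Each tissue carries a
#' perfusion value (ml/100 g/min) and an equilibrium-magnetization (M0)
#' value in arbitrary units; a GM probability map is provided for masking.
#'
#' @param shape Integer length-3 grid size `(nx, ny, n_slices)`; at least
#'   16 x 16 in-plane.
#' @param perfusion Named vector of per-tissue perfusion in ml/100 g/min
#'   (defaults: GM 60, WM 20, CSF 0; background fixed at 0).
#' @param m0 Named vector of per-tissue M0 values (arbitrary units).
#' @param spacing_mm Voxel spacing `(dx, dy, dz)` in mm.
#' @param seed Integer seed controlling the boundary perturbation.
#' @return Object of class `slider_phantom`: list with integer `labels`
#'   (0 = background, 1 = GM, 2 = WM, 3 = CSF), `perfusion`, `m0`,
#'   `gm_probability` (3-D arrays), `tissue_values`, `spacing_mm`, `seed`.
#' @examples
#' ph <- make_phantom(c(24, 24, 48), seed = 1)
#' table(ph$labels)
#' @export
make_phantom <- function(shape,
                         perfusion = c(gm = 60, wm = 20, csf = 0),
                         m0 = c(gm = 1000, wm = 750, csf = 1250),
                         spacing_mm = c(2, 2, 2),
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < c(16L, 16L, 4L)))
    stop("'shape' must be (nx, ny, nz) with nx, ny >= 16 and nz >= 4",
         call. = FALSE)
  for (nm in c("gm", "wm", "csf")) {
    if (is.na(perfusion[nm])) stop(sprintf("perfusion['%s'] missing", nm),
                                   call. = FALSE)
    if (is.na(m0[nm])) stop(sprintf("m0['%s'] missing", nm), call. = FALSE)
  }
  if (any(perfusion < 0)) stop("perfusion values must be >= 0", call. = FALSE)

  nx <- shape[1L]; ny <- shape[2L]; nz <- shape[3L]
  set.seed(seed)
  # low-order smooth boundary perturbation, deterministic given the seed
  amp <- stats::runif(4, 0.01, 0.04)
  phs <- stats::runif(4, 0, 2 * pi)

  x <- (seq_len(nx) - (nx + 1) / 2) / (0.46 * nx)
  y <- (seq_len(ny) - (ny + 1) / 2) / (0.46 * ny)
  z <- (seq_len(nz) - (nz + 1) / 2) / (0.48 * nz)
  X <- array(rep(x, times = ny * nz), dim = shape)
  Y <- array(rep(rep(y, each = nx), times = nz), dim = shape)
  Z <- array(rep(z, each = nx * ny), dim = shape)

  theta <- atan2(Y, X)
  r <- sqrt(X^2 + Y^2 + Z^2) +
    amp[1] * sin(2 * theta + phs[1]) +
    amp[2] * cos(3 * theta + phs[2]) +
    amp[3] * sin(2 * pi * Z + phs[3]) +
    amp[4] * cos(2 * theta + 2 * pi * Z + phs[4])

  labels <- array(0L, dim = shape)          # background
  labels[r < 1.00] <- 1L                    # GM shell
  labels[r < 0.78] <- 2L                    # WM
  labels[r < 0.22] <- 3L                    # central CSF

  lut_perf <- c(0, perfusion[["gm"]], perfusion[["wm"]], perfusion[["csf"]])
  lut_m0 <- c(0, m0[["gm"]], m0[["wm"]], m0[["csf"]])
  perf_vol <- array(lut_perf[labels + 1L], dim = shape)
  m0_vol <- array(lut_m0[labels + 1L], dim = shape)
  lut_p <- c(0.02, 0.95, 0.30, 0.05)
  gm_prob <- array(lut_p[labels + 1L], dim = shape)

  structure(
    list(labels = labels,
         perfusion = perf_vol,
         m0 = m0_vol,
         gm_probability = gm_prob,
         tissue_values = list(perfusion = perfusion, m0 = m0),
         spacing_mm = as.numeric(spacing_mm),
         seed = seed),
    class = "slider_phantom"
  )
}

#' @export
print.slider_phantom <- function(x, ...) {
  d <- dim(x$labels)
  frac <- table(factor(x$labels, levels = 0:3,
                       labels = c("bg", "gm", "wm", "csf"))) / length(x$labels)
  cat(sprintf("slider_phantom: %d x %d x %d (seed %s)\n",
              d[1], d[2], d[3], format(x$seed)))
  cat("  tissue fractions:",
      paste(sprintf("%s %.2f", names(frac), as.numeric(frac)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Thermal/physiological noise model
#'
#' `var_thermal` is the per-acquisition thermal noise variance at the
#' acquired voxel's physical signal scale.  Because acquired images are
#' stored mean-normalized (a thick slice holds the *mean* of its thin
#' slices, so signal units match across resolutions while the physical
#' acquisition measures their sum), the thermal noise added to an
#' `n_set`-times-thicker slice has standard deviation
#' `g * sqrt(var_thermal) / n_set` in stored units.  Physiological noise is
#' a signal-proportional fluctuation: it is added after projection with
#' marginal variance `var_physio` (unscaled by slice thickness or by g) as a
#' stationary AR(1) process with lag-1 correlation `rho` shared across the
#' label/control frame sequence.
#'
#' @param var_thermal Per-acquisition thermal variance (>= 0).
#' @param var_physio Physiological variance (>= 0) in stored signal units.
#' @param rho Lag-1 temporal correlation of physiological noise, `0 <= rho < 1`.
#' @param g_map Noise amplification factor: scalar or per-voxel 3-D array on
#'   the acquired (thick) grid; all values `>= 1`.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(var_thermal, var_physio = 0, rho = 0, g_map = 1) {
  if (var_thermal < 0 || var_physio < 0)
    stop("noise variances must be >= 0", call. = FALSE)
  if (rho < 0 || rho >= 1)
    stop("'rho' must satisfy 0 <= rho < 1", call. = FALSE)
  if (any(g_map < 1))
    stop("g-factor values must be >= 1", call. = FALSE)
  structure(list(var_thermal = var_thermal,
                 var_physio = var_physio,
                 rho = rho,
                 g_map = g_map),
            class = "noise_model")
}

#' Stationary AR(1) noise
#'
#' Generates `n_frames` draws of a stationary first-order autoregressive
#' process with marginal variance `var` and lag-1 correlation `rho`, for
#' `n_voxels` independent voxels.
#'
#' @param n_voxels Number of independent series (rows).
#' @param n_frames Series length (columns).
#' @param var Marginal variance.
#' @param rho Lag-1 correlation, `0 <= rho < 1`.
#' @return `n_voxels` x `n_frames` matrix.
#' @export
ar1_noise <- function(n_voxels, n_frames, var, rho) {
  if (var == 0) return(matrix(0, n_voxels, n_frames))
  sd0 <- sqrt(var)
  out <- matrix(0, n_voxels, n_frames)
  out[, 1L] <- stats::rnorm(n_voxels, 0, sd0)
  if (n_frames > 1L) {
    innov_sd <- sd0 * sqrt(1 - rho^2)
    for (f in 2L:n_frames) {
      out[, f] <- rho * out[, f - 1L] +
        stats::rnorm(n_voxels, 0, innov_sd)
    }
  }
  out
}

# Rows of the forward matrix belonging to one acquisition set, as a
# (n_thick x n_hr) matrix.
set_rows <- function(operator, set_index) {
  keep <- operator$row_map$set == set_index
  operator$matrix[keep, , drop = FALSE]
}

# Project an hr volume (nx, ny, n_hr) through one set's rows.
project_set <- function(operator, set_index, hr_vol) {
  d <- dim(hr_vol)
  Ak <- set_rows(operator, set_index)
  lr <- Ak %*% t(matrix(hr_vol, nrow = d[1L] * d[2L]))
  array(t(lr), dim = c(d[1L], d[2L], nrow(Ak)))
}

# Add thermal + physiological noise to a stack of frames (4-D array),
# sharing one AR(1) physiological process across the frame sequence.
add_acquisition_noise <- function(frames, noise, thermal_scale) {
  d <- dim(frames)
  nvox <- prod(d[1:3])
  nf <- d[4L]
  g <- noise$g_map
  if (is.array(g) && !identical(dim(g), d[1:3]))
    stop("g_map dimensions must match the acquired volume", call. = FALSE)
  if (noise$var_thermal > 0) {
    sd_t <- sqrt(noise$var_thermal) * thermal_scale
    eps <- stats::rnorm(nvox * nf, 0, sd_t)
    eps <- matrix(eps, nvox, nf) * as.vector(g)
    frames <- frames + array(eps, dim = d)
  }
  if (noise$var_physio > 0) {
    phys <- ar1_noise(nvox, nf, noise$var_physio, noise$rho)
    frames <- frames + array(phys, dim = d)
  }
  frames
}

#' Simulate a SLIDER thick-slice acquisition
#'
#' Projects the phantom through each shifted set's slice-averaging rows and
#' adds alternating label/control frames with thermal and AR(1)
#' physiological noise.  The perfusion-weighted difference signal `dM` is
#' derived from the phantom's perfusion via the single-compartment model of
#' [quantify_cbf()] (with slice-dependent post-labeling delays from
#' [hr_pld_offsets()]), so that quantification of a reconstructed simulation
#' recovers the phantom's perfusion values.  Control frames carry
#' `M0 + dM/2`, label frames `M0 - dM/2`.
#'
#' @param phantom A [make_phantom()] result whose slice count equals the
#'   geometry's hr grid.
#' @param geometry A [slider_geometry()] with `n_set >= 2` (use
#'   [simulate_reference()] for the thin-slice protocol).
#' @param noise A [noise_model()].
#' @param n_meas Number of label/control pairs per shift set.
#' @param seed Integer seed.
#' @param cbf_params A [cbf_params()] used for the difference-signal model;
#'   defaults to the geometry's labeling duration and PLD.
#' @param dm_scale Extra multiplicative factor on the difference signal
#'   (default 1).
#' @return Object of class `slider_simulation`: list with `sets` (one
#'   label/control [volume_series] per shift set, on the thick grid), `m0`
#'   (one single-frame thick-slice M0 series per set, thermal noise only),
#'   `truth` (hr-grid `dm` and `m0` arrays), `operator`, `geometry`,
#'   `noise`, `n_meas`, `seed`.
#' @export
simulate_acquisition <- function(phantom, geometry, noise, n_meas,
                                 seed = 1L, cbf_params = NULL,
                                 dm_scale = 1) {
  stopifnot(inherits(phantom, "slider_phantom"),
            inherits(geometry, "slider_geometry"),
            inherits(noise, "noise_model"))
  if (n_meas < 1) stop("'n_meas' must be >= 1", call. = FALSE)
  grid <- hr_grid(geometry)
  if (dim(phantom$labels)[3L] != grid$n_slices)
    stop(sprintf("phantom has %d slices; geometry's hr grid has %d",
                 dim(phantom$labels)[3L], grid$n_slices), call. = FALSE)
  if (is.null(cbf_params))
    cbf_params <- cbf_params(label_duration_ms = geometry$label_duration_ms,
                             pld_ms = geometry$pld_ms)

  op <- build_forward_operator(geometry)
  dm_hr <- dm_scale * perfusion_difference_signal(phantom, geometry, cbf_params)
  m0_hr <- phantom$m0
  ctrl_hr <- m0_hr + dm_hr / 2
  lab_hr <- m0_hr - dm_hr / 2

  set.seed(seed)
  n_sets <- if (is_reference(geometry)) 2L else geometry$n_set
  thermal_scale <- 1 / geometry$n_set   # mean-normalized thick-slice units
  d_in <- dim(phantom$labels)
  sets <- vector("list", n_sets)
  m0_sets <- vector("list", n_sets)
  spacing <- c(phantom$spacing_mm[1:2], geometry$thick_thickness_mm)
  for (k in seq_len(n_sets)) {
    ctrl_lr <- project_set(op, k - 1L, ctrl_hr)
    lab_lr <- project_set(op, k - 1L, lab_hr)
    nf <- 2L * n_meas
    frames <- array(0, dim = c(dim(ctrl_lr), nf))
    labels <- rep(c("label", "control"), n_meas)
    for (f in seq_len(nf)) {
      frames[, , , f] <- if (labels[f] == "label") lab_lr else ctrl_lr
    }
    frames <- add_acquisition_noise(frames, noise, thermal_scale)
    sets[[k]] <- volume_series(frames, frame_labels = labels,
                               spacing_mm = spacing, geometry = geometry)
    m0_lr <- project_set(op, k - 1L, m0_hr)
    m0_fr <- add_acquisition_noise(array(m0_lr, dim = c(dim(m0_lr), 1L)),
                                   noise_model(noise$var_thermal,
                                               g_map = noise$g_map),
                                   thermal_scale)
    m0_sets[[k]] <- volume_series(m0_fr, frame_labels = "m0",
                                  spacing_mm = spacing, geometry = geometry)
  }
  structure(
    list(sets = sets, m0 = m0_sets,
         truth = list(dm = dm_hr, m0 = m0_hr),
         operator = op, geometry = geometry, noise = noise,
         n_meas = as.integer(n_meas), seed = seed,
         cbf_params = cbf_params),
    class = "slider_simulation"
  )
}

#' Simulate the two-pass interleaved thin-slice reference acquisition
#'
#' The reference protocol acquires the full thin-slice stack as two
#' interleaved passes with a 100% slice gap: pass 1 covers the even thin
#' slices (0-based), pass 2 the odd ones.  Each pass is an independent
#' acquisition with the same noise model (thermal scale 1: slices are thin).
#'
#' @param phantom A [make_phantom()] result on the reference hr grid.
#' @param geometry_ref The `n_set = 1` reference [slider_geometry()].
#' @param noise A [noise_model()].
#' @param n_meas Label/control pairs per pass.
#' @param seed Integer seed.
#' @param cbf_params,dm_scale As in [simulate_acquisition()].
#' @return A `slider_simulation` whose `sets` are the two passes (each with
#'   `slice_indices` marking their thin slices on the full grid).
#' @seealso [merge_reference_passes()]
#' @export
simulate_reference <- function(phantom, geometry_ref, noise, n_meas,
                               seed = 1L, cbf_params = NULL, dm_scale = 1) {
  stopifnot(inherits(geometry_ref, "slider_geometry"))
  if (!is_reference(geometry_ref))
    stop("'geometry_ref' must be the n_set = 1 reference protocol",
         call. = FALSE)
  sim <- simulate_acquisition(phantom, geometry_ref, noise, n_meas,
                              seed = seed, cbf_params = cbf_params,
                              dm_scale = dm_scale)
  n_hr <- hr_grid(geometry_ref)$n_slices
  for (k in 1:2) {
    idx <- seq(k - 1L, n_hr - 1L, by = 2L)
    sim$sets[[k]]$slice_indices <- idx
    sim$m0[[k]]$slice_indices <- idx
    sim$sets[[k]]$spacing_mm[3L] <- geometry_ref$thin_thickness_mm
    sim$m0[[k]]$spacing_mm[3L] <- geometry_ref$thin_thickness_mm
  }
  sim
}

#' Merge the two interleaved reference passes onto the full thin grid
#'
#' Frame `f` of the merged series takes its even slices from pass 1 frame
#' `f` and its odd slices from pass 2 frame `f`.
#'
#' @param passes List of the two pass [volume_series] (with
#'   `slice_indices`), as produced by [simulate_reference()].
#' @return A [volume_series] on the full thin-slice grid.
#' @export
merge_reference_passes <- function(passes) {
  stopifnot(length(passes) == 2L)
  for (p in passes)
    if (is.null(p$slice_indices))
      stop("pass series must carry 'slice_indices'", call. = FALSE)
  idx <- sort(c(passes[[1L]]$slice_indices, passes[[2L]]$slice_indices))
  if (any(duplicated(idx)))
    stop("pass slice indices overlap; passes must be disjoint", call. = FALSE)
  n_hr <- length(idx)
  if (!identical(idx, seq(0L, n_hr - 1L)))
    stop("pass slice indices do not tile the full grid", call. = FALSE)
  nf <- n_frames(passes[[1L]])
  if (nf != n_frames(passes[[2L]]))
    stop("passes have unequal frame counts", call. = FALSE)
  d <- dim(passes[[1L]]$data)
  out <- array(0, dim = c(d[1L], d[2L], n_hr, nf))
  for (p in 1:2) {
    out[, , passes[[p]]$slice_indices + 1L, ] <- passes[[p]]$data
  }
  volume_series(out, frame_labels = passes[[1L]]$frame_labels,
                spacing_mm = passes[[1L]]$spacing_mm,
                geometry = passes[[1L]]$geometry)
}
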