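#' Read a volume series from NIfTI file(s)
#'
#' Reads one or several NIfTI files into a [volume_series].  A single 4-D
#' file becomes a multi-frame series; a 3-D file a single frame; several
#' 3-D files are stacked as frames (they must agree in shape and spacing).
#' Frame labels are taken from a JSON sidecar (a file of the same name with
#' extension `.json` holding `{"frame_labels": [...]}`), from the
#' `frame_labels` argument, or default to `"unknown"`.
#'
#' The slice axis is the third array axis; voxel spacing comes from the
#' NIfTI `pixdim`.
#'
#' @param paths Character vector of NIfTI file paths.
#' @param frame_labels Optional character vector overriding the sidecar.
#' @return A [volume_series].
#' @export
read_volume_series <- function(paths, frame_labels = NULL) {
  stopifnot(length(paths) >= 1L)
  vols <- lapply(paths, function(p) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
    RNifti::readNifti(p)
  })
  pix <- lapply(vols, function(v) RNifti::pixdim(v)[1:3])
  dims <- lapply(vols, dim)
  for (i in seq_along(vols)) {
    if (!isTRUE(all.equal(dims[[i]][1:3], dims[[1L]][1:3])))
      stop(sprintf("inconsistent volume shape in %s", paths[i]),
           call. = FALSE)
    if (!isTRUE(all.equal(pix[[i]], pix[[1L]], tolerance = 1e-6)))
      stop(sprintf("inconsistent voxel spacing in %s", paths[i]),
           call. = FALSE)
  }
  if (length(vols) == 1L) {
    arr <- array(as.numeric(vols[[1L]]), dim = dim(vols[[1L]]))
    if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  } else {
    if (any(vapply(dims, length, 1L) != 3L))
      stop("stacking multiple files requires 3-D volumes", call. = FALSE)
    arr <- array(0, dim = c(dims[[1L]], length(vols)))
    for (i in seq_along(vols)) arr[, , , i] <- as.numeric(vols[[i]])
  }
  if (is.null(frame_labels)) {
    sidecar <- sub("\\.nii(\\.gz)?$", ".json", paths[1L])
    if (sidecar != paths[1L] && file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      if (!is.null(meta$frame_labels)) frame_labels <- meta$frame_labels
    }
  }
  volume_series(arr, frame_labels = frame_labels, spacing_mm = pix[[1L]])
}

#' Write a volume series as a NIfTI file (plus JSON sidecar)
#'
#' Writes the 4-D data with voxel spacing encoded in the header `pixdim`
#' (slice axis third), and the frame labels in a `.json` sidecar next to the
#' image, since NIfTI has no standard frame-label field.
#'
#' @param series A [volume_series] (or 3-D/4-D array).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param sidecar Write the JSON frame-label sidecar (default TRUE for
#'   series with informative labels).
#' @return `path`, invisibly.
#' @export
write_volume_series <- function(series, path, sidecar = TRUE) {
  if (!inherits(series, "volume_series")) series <- volume_series(series)
  arr <- series$data
  if (dim(arr)[4L] == 1L) dim(arr) <- dim(arr)[1:3]
  spacing <- series$spacing_mm
  spacing[!is.finite(spacing)] <- 1
  img <- RNifti::asNifti(arr)
  pd <- RNifti::pixdim(img)
  pd[1:3] <- spacing
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  if (sidecar && !all(series$frame_labels == "unknown")) {
    sidecar_path <- sub("\\.nii(\\.gz)?$", ".json", path)
    jsonlite::write_json(list(frame_labels = series$frame_labels),
                         sidecar_path, auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a pipeline/protocol configuration file
#'
#' YAML or JSON (by extension).  Recognized keys: `preset` (one of the
#' [slider_preset()] names) or explicit [slider_geometry()] fields under
#' `geometry`; `noise` ([noise_model()] fields); `recon` (`lambda`);
#' `simulate` (`n_meas`, `seed`); `quant` ([cbf_params()] fields).
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json", call. = FALSE)
}

config_geometry <- function(config) {
  if (!is.null(config$preset)) {
    do.call(slider_preset,
            c(list(name = config$preset), config$geometry))
  } else if (!is.null(config$geometry)) {
    do.call(slider_geometry, config$geometry)
  } else {
    stop("config needs a 'preset' or a 'geometry' block", call. = FALSE)
  }
}

#' Run the simulate-reconstruct-metrics-quantify pipeline
#'
#' Executes the requested stages in order on one protocol configuration,
#' writing NIfTI volumes, JSON reports and a run manifest under `out_dir`.
#' All randomness flows from `config$simulate$seed`; re-running an identical
#' configuration reproduces the outputs exactly.
#'
#' @param config Named list (see [read_config()]) or path to a config file.
#'   Must contain a `preset`/`geometry`; stage blocks `simulate`
#'   (`n_meas`, `seed`), `recon` (`lambda`), `quant` are optional with
#'   defaults (`n_meas` 20, `seed` 1, `lambda` 0.1).
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of
#'   `c("simulate", "reconstruct", "metrics", "quantify")` in pipeline
#'   order.
#' @return The run manifest (named list, also written as `manifest.json`):
#'   config snapshot, seed, output paths, per-stage wall-clock seconds and
#'   warnings.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "reconstruct",
                                    "metrics", "quantify")) {
  if (is.character(config) && length(config) == 1L)
    config <- read_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  geometry <- config_geometry(config)
  n_meas <- config$simulate$n_meas %||% 20L
  seed <- config$simulate$seed %||% 1L
  lambda <- config$recon$lambda %||% 0.1
  noise_cfg <- config$noise %||% list()
  noise <- noise_model(
    var_thermal = noise_cfg$var_thermal %||% 4,
    var_physio = noise_cfg$var_physio %||% 0,
    rho = noise_cfg$rho %||% 0,
    g_map = noise_cfg$g %||% 1)
  qp <- do.call(cbf_params, c(
    list(label_duration_ms = geometry$label_duration_ms,
         pld_ms = geometry$pld_ms),
    config$quant %||% list()))

  manifest <- list(config = config, seed = seed, outputs = list(),
                   stages = list(), version = as.character(
                     utils::packageVersion("sliderasl")))
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    warns <- character()
    res <- withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      warnings = warns)
    res
  }
  record <- function(key, path) {
    manifest$outputs[[key]] <<- path
    path
  }

  grid <- hr_grid(geometry)
  shape <- c(config$simulate$nx %||% 32L, config$simulate$ny %||% 32L,
             grid$n_slices)

  sim <- NULL; hr_perf <- NULL; hr_m0 <- NULL; phantom <- NULL
  if ("simulate" %in% stages) {
    sim <- timed("simulate", {
      phantom <- make_phantom(shape, seed = seed)
      if (is_reference(geometry))
        simulate_reference(phantom, geometry, noise, n_meas, seed = seed,
                           cbf_params = qp)
      else
        simulate_acquisition(phantom, geometry, noise, n_meas, seed = seed,
                             cbf_params = qp)
    })
    for (k in seq_along(sim$sets)) {
      write_volume_series(sim$sets[[k]],
        record(sprintf("set%d", k),
               file.path(out_dir, sprintf("set%d.nii.gz", k))))
      write_volume_series(sim$m0[[k]],
        record(sprintf("m0_set%d", k),
               file.path(out_dir, sprintf("m0_set%d.nii.gz", k))))
    }
    write_volume_series(
      volume_series(sim$truth$dm, frame_labels = "perfusion",
                    spacing_mm = phantom$spacing_mm),
      record("truth_dm", file.path(out_dir, "truth_dm.nii.gz")))
  }

  if ("reconstruct" %in% stages) {
    if (is.null(sim))
      stop("pipeline stage 'reconstruct': no simulated input available ",
           "(run the 'simulate' stage or supply data programmatically)",
           call. = FALSE)
    recon <- timed("reconstruct", {
      if (is_reference(geometry)) {
        perf <- merge_reference_passes(lapply(sim$sets, perfusion_frames))
        m0m <- merge_reference_passes(sim$m0)
        list(perf = perf, m0 = mean_volume(m0m))
      } else {
        inv <- tikhonov_inverse(sim$operator, lambda)
        perf <- reconstruct_series(lapply(sim$sets, perfusion_frames), inv)
        m0v <- reconstruct_volume(
          lapply(sim$m0, function(s) s$data[, , , 1L]), inv)
        jsonlite::write_json(
          recon_diagnostics(inv),
          record("diagnostics", file.path(out_dir, "recon_diagnostics.json")),
          auto_unbox = TRUE, digits = NA)
        list(perf = perf, m0 = m0v)
      }
    })
    hr_perf <- recon$perf
    hr_m0 <- recon$m0
    write_volume_series(hr_perf,
      record("hr_perfusion", file.path(out_dir, "hr_perfusion.nii.gz")))
    write_volume_series(
      volume_series(hr_m0, frame_labels = "m0",
                    spacing_mm = hr_perf$spacing_mm),
      record("hr_m0", file.path(out_dir, "hr_m0.nii.gz")))
  }

  if ("metrics" %in% stages) {
    if (is.null(hr_perf))
      stop("pipeline stage 'metrics': no reconstructed series available",
           call. = FALSE)
    report <- timed("metrics", {
      mask <- gm_mask(phantom$gm_probability)
      snr_report(hr_perf, mask,
                 condition = geometry$preset %||% "custom",
                 lambda = if (is_reference(geometry)) NA_real_ else lambda)
    })
    jsonlite::write_json(as.list(report),
      record("snr_report", file.path(out_dir, "snr_report.json")),
      auto_unbox = TRUE, digits = NA)
  }

  if ("quantify" %in% stages) {
    if (is.null(hr_perf))
      stop("pipeline stage 'quantify': no reconstructed series available",
           call. = FALSE)
    cbf <- timed("quantify", {
      quantify_cbf(mean_volume(hr_perf), hr_m0, qp,
                   slice_offsets_ms = hr_pld_offsets(geometry))
    })
    write_volume_series(
      volume_series(ifelse(is.na(cbf$cbf), 0, cbf$cbf),
                    spacing_mm = hr_perf$spacing_mm),
      record("cbf", file.path(out_dir, "cbf.nii.gz")))
    rois <- roi_means(cbf, phantom$labels,
                      roi_names = list(`1` = "gm", `2` = "wm", `3` = "csf"))
    jsonlite::write_json(rois,
      record("roi_means", file.path(out_dir, "roi_means.json")),
      auto_unbox = TRUE, digits = NA)
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  manifest$path <- manifest_path
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
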