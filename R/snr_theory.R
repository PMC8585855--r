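#' Noise budget for SNR-efficiency calculations
#'
#' Collects the quantities entering the analytic SNR-efficiency model of a
#' SLIDER acquisition versus a thin-slice reference: repetition counts,
#' their effective values under temporally correlated physiological noise,
#' the thermal and physiological variances, and the parallel-imaging
#' g-factors of the two conditions.
#'
#' The effective measurement numbers `n_meas_eff` / `n_full_eff` express how
#' much averaging actually reduces physiological noise: for white noise they
#' equal the repetition counts, while strong temporal correlation pushes
#' them toward 1.  [ar1_effective_n()] computes them for an AR(1) process.
#'
#' @param n_set Number of shifted acquisition sets.
#' @param n_meas Measurements (label/control pairs) per SLIDER acquisition.
#' @param n_full Measurements of the reference acquisition.
#' @param var_thermal Thermal noise variance per measurement.
#' @param var_physio Physiological noise variance.
#' @param g_slider g-factor of the SLIDER-SMS reconstruction (>= 1).
#' @param g_ref g-factor of the reference SMS acquisition (>= 1).
#' @param n_meas_eff,n_full_eff Effective measurement numbers in
#'   `[1, n_meas]` / `[1, n_full]`; default to the nominal counts (white
#'   physiological noise).
#' @return Object of class `noise_budget`.
#' @export
noise_budget <- function(n_set, n_meas, n_full,
                         var_thermal, var_physio = 0,
                         g_slider = 1, g_ref = 1,
                         n_meas_eff = n_meas, n_full_eff = n_full) {
  if (n_set < 1) stop("'n_set' must be >= 1", call. = FALSE)
  if (n_meas < 1 || n_full < 1)
    stop("measurement counts must be >= 1", call. = FALSE)
  if (var_thermal < 0 || var_physio < 0)
    stop("variances must be >= 0", call. = FALSE)
  if (g_slider < 1 || g_ref < 1)
    stop("g-factors must be >= 1", call. = FALSE)
  if (n_meas_eff < 1 || n_meas_eff > n_meas)
    stop("'n_meas_eff' must lie in [1, n_meas]", call. = FALSE)
  if (n_full_eff < 1 || n_full_eff > n_full)
    stop("'n_full_eff' must lie in [1, n_full]", call. = FALSE)
  structure(list(n_set = n_set, n_meas = n_meas, n_full = n_full,
                 var_thermal = var_thermal, var_physio = var_physio,
                 g_slider = g_slider, g_ref = g_ref,
                 n_meas_eff = n_meas_eff, n_full_eff = n_full_eff),
            class = "noise_budget")
}

#' Noise variance of an N-measurement average
#'
#' Thermal noise averages down as `1/N`; physiological noise only as
#' `1/N'` with the effective measurement number `N' <= N`:
#' `var = g^2 var_thermal / N + var_physio / N'`.
#'
#' @param budget A [noise_budget()].
#' @param condition `"slider"` (uses `n_meas`, `n_meas_eff`, `g_slider`) or
#'   `"reference"` (uses `n_full`, `n_full_eff`, `g_ref`).
#' @return The averaged noise variance.
#' @examples
#' b <- noise_budget(2, n_meas = 4, n_full = 4, var_thermal = 1)
#' averaged_noise_variance(b, "slider")  # 0.25
#' @export
averaged_noise_variance <- function(budget,
                                    condition = c("slider", "reference")) {
  stopifnot(inherits(budget, "noise_budget"))
  condition <- match.arg(condition)
  if (condition == "slider") {
    budget$g_slider^2 * budget$var_thermal / budget$n_meas +
      budget$var_physio / budget$n_meas_eff
  } else {
    budget$g_ref^2 * budget$var_thermal / budget$n_full +
      budget$var_physio / budget$n_full_eff
  }
}

#' SNR-efficiency ratio of SLIDER over the thin-slice reference
#'
#' The shifted sets sample every thin slice `n_set` times, contributing a
#' `sqrt(n_set)` factor; the remainder is the ratio of averaged noise SDs of
#' the two conditions:
#' `gain = sqrt(n_set) * sqrt(avg_var_reference / avg_var_slider)`.
#' With no physiological noise, equal g-factors and matched repetition
#' counts this reduces to `sqrt(n_set)`.  Note the ratio idealizes the
#' reconstruction: signal amplitudes are taken equal across conditions on
#' the reconstructed thin grid, and the slice-deconvolution noise shaping at
#' a given regularization level is not modeled (the simulator quantifies
#' that part).
#'
#' @param budget A [noise_budget()].
#' @return Dimensionless SNR gain (> 0).
#' @examples
#' snr_efficiency_ratio(noise_budget(4, 20, 40, var_thermal = 1,
#'                                   var_physio = 1,
#'                                   n_meas_eff = 5, n_full_eff = 5))
#' @export
snr_efficiency_ratio <- function(budget) {
  stopifnot(inherits(budget, "noise_budget"))
  v_ref <- averaged_noise_variance(budget, "reference")
  v_sli <- averaged_noise_variance(budget, "slider")
  if (v_ref <= 0 || v_sli <= 0)
    stop("total averaged noise variance must be positive in both conditions",
         call. = FALSE)
  sqrt(budget$n_set) * sqrt(v_ref / v_sli)
}

#' Effective number of measurements for AR(1) noise
#'
#' For `n` averaged measurements of a stationary AR(1) process with lag-1
#' correlation `rho`, the variance of the mean is `var/n * c(n, rho)` with
#' `c(n, rho) = 1 + 2 * sum_{k=1}^{n-1} (1 - k/n) rho^k`; the effective
#' measurement number is `n' = n / c(n, rho)`.  `method = "asymptotic"`
#' returns the large-`n` limit `n (1 - rho) / (1 + rho)`.
#'
#' @param n Number of measurements.
#' @param rho Lag-1 correlation, `0 <= rho < 1`.
#' @param method `"exact"` (finite-n, default) or `"asymptotic"`.
#' @return Effective measurement number in `[1, n]`.
#' @export
ar1_effective_n <- function(n, rho, method = c("exact", "asymptotic")) {
  method <- match.arg(method)
  if (rho < 0 || rho >= 1)
    stop("'rho' must satisfy 0 <= rho < 1", call. = FALSE)
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (rho == 0) return(n)
  if (method == "asymptotic") {
    return(max(1, n * (1 - rho) / (1 + rho)))
  }
  k <- seq_len(n - 1L)
  corr_factor <- 1 + 2 * sum((1 - k / n) * rho^k)
  max(1, n / corr_factor)
}

#' @export
print.noise_budget <- function(x, ...) {
  cat(sprintf(
    "noise_budget: n_set %g, N_meas %g (eff %.2f), N_full %g (eff %.2f)\n",
    x$n_set, x$n_meas, x$n_meas_eff, x$n_full, x$n_full_eff))
  cat(sprintf("  var_thermal %g, var_physio %g, g_slider %g, g_ref %g\n",
              x$var_thermal, x$var_physio, x$g_slider, x$g_ref))
  cat(sprintf("  SNR efficiency ratio: %.3f\n",
              tryCatch(snr_efficiency_ratio(x), error = function(e) NA)))
  invisible(x)
}
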