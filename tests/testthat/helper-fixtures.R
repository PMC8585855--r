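# Small geometries and simulations shared across test files.

# Minimal 2-shift geometry: 3 thick slices of 4 mm -> 6 thin slices of 2 mm.
tiny_geometry <- function(n_set = 2L, n_thick = 3L) {
  slider_geometry(n_set = n_set, thin_thickness_mm = 2,
                  mb_factor = 1, n_groups = n_thick)
}

# Dense forward matrix built entry-by-entry from the footprint definition,
# independent of build_forward_operator's loop structure: thick slice j of
# set k (0-based) covers thin indices j*stride + k .. + support-1, truncated
# to the slab, with equal weights 1/support.
brute_force_matrix <- function(geometry) {
  n_set <- geometry$n_set
  reference <- n_set == 1L
  stride <- if (reference) 2L else n_set
  support <- if (reference) 1L else n_set
  n_sets <- if (reference) 2L else n_set
  n_thick <- geometry$n_thick_slices
  n_hr <- hr_grid(geometry)$n_slices
  A <- matrix(0, n_sets * n_thick, n_hr)
  for (k in 0:(n_sets - 1L)) {
    for (j in 0:(n_thick - 1L)) {
      for (t in 0:(support - 1L)) {
        thin <- j * stride + k + t
        if (thin >= 0 && thin < n_hr)
          A[k * n_thick + j + 1L, thin + 1L] <- 1 / support
      }
    }
  }
  A
}

tiny_phantom <- function(geometry, seed = 1L, nxy = 20L) {
  make_phantom(c(nxy, nxy, hr_grid(geometry)$n_slices), seed = seed)
}

quiet_noise <- function() noise_model(0)
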