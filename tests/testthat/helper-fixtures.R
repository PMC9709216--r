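# Shared fixtures, built once per test run and memoised (phantom generation
# is the slow part of the suite).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small slab with an oblique uniform axis (HA 30, IA 10), clean orientations
slab_small <- function() {
  fixture("slab_small", function() {
    sp <- phantom_spec(shape = c(48, 48, 40), geometry_kind = "slab",
                       ha_endo_deg = 30, ia_deg = 10, seed = 7)
    ph <- make_slab_phantom(sp)
    ph$spec <- sp
    ph
  })
}

# small shell, +60/-60 linear HA law, no orientation noise
shell_small <- function() {
  fixture("shell_small", function() {
    sp <- phantom_spec(shape = rep(96, 3), Ra_um = 80, Rb_um = 48,
                       ha_endo_deg = 60, ha_epi_deg = -60, seed = 7)
    ph <- make_shell_phantom(sp)
    ph$spec <- sp
    ph
  })
}

# orientation estimate on the small slab at pipeline defaults
slab_orientation <- function() {
  fixture("slab_orientation", function() {
    ph <- slab_small()
    g <- compute_gradient(ph$volume, sigma_vox = 1)
    eigendecompose(compute_structure_tensor(g, 7, ph$mask), ph$mask)
  })
}

# per-voxel acute angle (degrees) between two sign-free axis fields at idx
axis_angle_deg <- function(v3, truth_axis, idx, n) {
  v <- cbind(v3[idx], v3[idx + n], v3[idx + 2 * n])
  tv <- cbind(truth_axis[idx], truth_axis[idx + n], truth_axis[idx + 2 * n])
  acos(pmin(abs(rowSums(v * tv)), 1)) * 180 / pi
}

# wrap a truth field as an orientation_field (tests metric code on exact axes)
truth_as_orientation <- function(ph, voxel_size_um = 2) {
  d <- dim(ph$mask)
  structure(
    list(l1 = array(1, d), l2 = array(1, d), l3 = array(0, d),
         v3 = ph$truth$axis, valid = !is.na(ph$truth$ha),
         voxel_size_um = rep(voxel_size_um, 3), tau = 0.05),
    class = "orientation_field"
  )
}
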