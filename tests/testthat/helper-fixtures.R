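# Shared fixtures: a small artery keeps the unit tests fast; the
# full-size Table-1 artery is built only where its dimensions are the
# point of the test.

small_spec <- function() {
  geometry_spec(lumen_radius_um = 400, wall_thickness_um = 300,
                length_um = 1000, margin_voxels = 4L)
}

small_artery <- function(capacity_fraction = 0.40) {
  build_artery(small_spec(), capacity_fraction = capacity_fraction)
}

# a sealed cubic test box (reflecting boundaries) for transport oracles
sealed_box_cache <- function(n = 13L) {
  mask <- array(TRUE, dim = c(n, n, n))
  atheroabm:::make_diffusion_cache(mask, sink_boundary = FALSE)
}

# minimal simulation state around a lattice, without running init_state
bare_state <- function(lattice, seed = 1L) {
  state <- new.env(parent = emptyenv())
  state$lattice <- lattice
  state$occupied <- array(0, dim = lattice$dims)
  state$fields <- species_fields(lattice)
  state$attract <- state$fields$TNFA + state$fields$IL1B
  state$agents <- agents_new()
  state$pending <- matrix(0L, lattice$dims[3], length(AGENT_TYPES))
  state$plane_vol_base <- rep(0, lattice$dims[3])
  state$tick <- 0L
  state$remodel_log <- list()
  set.seed(seed)
  state
}

# deterministic mid-wall voxel of a lattice (theta = 0, mid plane)
mid_wall_voxel <- function(lattice) {
  spec <- lattice$spec
  r_mid <- spec$lumen_radius_um + spec$patch_um +
    spec$wall_thickness_um / 2
  i <- round(lattice$axis_um[1] / spec$patch_um +
               r_mid / spec$patch_um + 0.5)
  atheroabm:::vox_index(lattice, i, round(lattice$dims[2] / 2),
                        round(lattice$dims[3] / 2))
}
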