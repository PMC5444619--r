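# Glagov remodeling: growth demand, directional growth proportions,
# lumen preservation below threshold and shell maintenance.

# seed a plane with enough agent volume to look like plaque
seed_plane <- function(st, z, n_patches, per_patch = 10) {
  lat <- st$lattice
  w <- which(lat$class[, , z] == 2L, arr.ind = TRUE)
  take <- w[seq_len(min(n_patches, nrow(w))), , drop = FALSE]
  for (r in seq_len(nrow(take))) {
    v <- atheroabm:::vox_index(lat, take[r, 1], take[r, 2], z)
    st$agents <- atheroabm:::agents_add(st$agents,
                                        rep(6L, per_patch), rep(v, per_patch))
  }
  st$occupied <- atheroabm:::recount_occupied(lat, st$agents)
  st
}

test_that("growth demand floors the pending volume", {
  lat <- small_artery()
  st <- bare_state(lat)
  expect_equal(growth_demand(st, 3), 0L)
  cap <- voxel_capacity(lat)
  # 1.5 capacities of pending foam volume -> 1 voxel
  nfoam <- ceiling(1.5 * cap / AGENT_VOLUME_UM3[["FOAM"]])
  st$pending[3, 6] <- nfoam
  excess <- nfoam * AGENT_VOLUME_UM3[["FOAM"]]
  expect_equal(growth_demand(st, 3), as.integer(floor(excess / cap)))
  expect_equal(growth_demand(st, 3), 1L)
})

test_that("demand from incremental tracking equals a from-scratch recount", {
  lat <- small_artery()
  st <- bare_state(lat, seed = 4)
  st <- seed_plane(st, 4, n_patches = 6, per_patch = 30)
  base <- st$plane_vol_base[4]
  v_now <- sum(st$occupied[, , 4])
  expect_equal(growth_demand(st, 4),
               as.integer(floor((v_now - base) / voxel_capacity(lat))))
})

test_that("below the Glagov threshold growth is outward only", {
  lat <- small_artery()
  st <- bare_state(lat, seed = 21)
  lum0 <- lumen_volume(st$lattice)
  st <- seed_plane(st, 5, n_patches = 4, per_patch = 40)  # ratio << 0.4
  st$lattice$occupied <- st$occupied
  pa <- plane_areas(st$lattice, 5)
  expect_lt(pa[["plaque"]] / pa[["lumen"]], 0.40)
  ev <- glagov_tick(st)
  expect_true(all(ev$direction == "outward"))
  expect_equal(lumen_volume(st$lattice), lum0)   # lumen preserved
  # EC shell closure still holds
  adj <- atheroabm:::has_face_neighbor(st$lattice$class, 0L)
  expect_false(any(adj & (st$lattice$class == 2L)))
})

test_that("above threshold growth splits ~65/35 inward/outward", {
  lat <- small_artery()
  st <- bare_state(lat, seed = 31)
  lum0 <- lumen_volume(lat)
  nz <- lat$dims[3]
  # make every plane exceed the threshold: occupy ~half the wall patches
  for (z in seq_len(nz)) st <- seed_plane(st, z, n_patches = 30,
                                          per_patch = 2)
  st$lattice$occupied <- st$occupied
  expect_gte(max_plane_ratio(st$lattice), 0.40)
  reset_base <- function(st) {
    vapply(seq_len(nz), function(z) sum(st$occupied[, , z]), 0)
  }
  st$plane_vol_base <- reset_base(st)
  # feed pending volume so every plane demands one voxel per round
  set.seed(31)
  events <- NULL
  for (rep in 1:30) {
    st$pending[, 6] <- 60L
    ev <- glagov_tick(st)
    events <- rbind(events, ev)
    st$pending[] <- 0L
    st$plane_vol_base <- reset_base(st)
  }
  n <- nrow(events)
  expect_gt(n, 250)
  frac_in <- mean(events$direction == "inward")
  se <- sqrt(0.65 * 0.35 / n)
  expect_lt(abs(frac_in - 0.65), 4 * se)
  # inward events each removed exactly one lumen voxel
  expect_equal(lum0 - lumen_volume(st$lattice),
               sum(events$direction == "inward"))
  # shell closed after all this surgery
  adj <- atheroabm:::has_face_neighbor(st$lattice$class, 0L)
  expect_false(any(adj & (st$lattice$class == 2L)))
})

test_that("threshold boundary: a 40% plane is eligible for inward growth", {
  lat <- small_artery()
  st <- bare_state(lat, seed = 8)
  z <- 5
  pa0 <- plane_areas(lat, z)
  need <- ceiling(0.40 * pa0[["lumen"]])
  st <- seed_plane(st, z, n_patches = need, per_patch = 2)
  st$lattice$occupied <- st$occupied
  pa <- plane_areas(st$lattice, z)
  expect_gte(pa[["plaque"]] / pa[["lumen"]], 0.40)
  st$plane_vol_base <- vapply(seq_len(lat$dims[3]), function(zz) {
    sum(st$occupied[, , zz])
  }, 0)
  st$pending[z, 6] <- 240L
  set.seed(123)
  ev <- glagov_tick(st)
  expect_true("inward" %in% ev$direction)
})
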