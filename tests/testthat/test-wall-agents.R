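# Chemotaxis under space constraints, cohort placement, differentiation,
# foam formation, aging and occupancy bookkeeping.

test_that("a leukocyte climbs the cytokine gradient to the source", {
  lat <- small_artery()
  st <- bare_state(lat)
  # producer fixed at a mid-wall voxel; leukocyte 5 voxels away along z
  src <- mid_wall_voxel(lat)
  co <- atheroabm:::vox_coords(lat, src)
  start <- atheroabm:::vox_index(lat, co[1], co[2], co[3] + 5L)
  expect_equal(lat$class[start], 2L)
  st$agents <- atheroabm:::agents_add(st$agents, 1L, start)
  st$occupied[start] <- AGENT_VOLUME_UM3[["NEUTROPHIL"]]
  reached <- NA_integer_
  dist_src <- function() {
    p <- atheroabm:::vox_coords(lat, st$agents$vox[1])
    sqrt(sum((p - co)^2))
  }
  for (tick in 1:10) {
    # the source produces monocyte-rate cytokines each tick, then diffuses
    st$fields$TNFA[src] <- st$fields$TNFA[src] + 6.7e-4
    st$fields$TNFA <- diffuse_tick(st$fields$TNFA, lat, 3e-11)
    st$attract <- st$fields$TNFA + st$fields$IL1B
    chemotaxis_tick(st)
    if (is.na(reached) && dist_src() <= 1) reached <- tick
  }
  # the cytokine maximum sits at (or within one voxel of) the source: the
  # cell reaches it by tick 8 at one patch per tick and then stays
  expect_false(is.na(reached))
  expect_lte(reached, 8)
  expect_gte(reached, 4)
  expect_lte(dist_src(), 1)
  final <- st$agents$vox[1]
  expect_equal(st$attract[final], max(st$attract))
})

test_that("no movement on a uniform field", {
  lat <- small_artery()
  st <- bare_state(lat)
  v <- mid_wall_voxel(lat)
  st$agents <- atheroabm:::agents_add(st$agents, 1L, v)
  st$occupied[v] <- AGENT_VOLUME_UM3[["NEUTROPHIL"]]
  st$attract <- array(1, dim = lat$dims)   # uniform
  chemotaxis_tick(st)
  expect_equal(st$agents$vox[1], v)
})

test_that("space constraints dominate the gradient", {
  lat <- small_artery()
  st <- bare_state(lat)
  v <- mid_wall_voxel(lat)
  st$agents <- atheroabm:::agents_add(st$agents, 1L, v)
  st$occupied[] <- voxel_capacity(lat)     # everything full
  st$occupied[v] <- AGENT_VOLUME_UM3[["NEUTROPHIL"]]
  st$attract <- array(stats::runif(prod(lat$dims)), dim = lat$dims)
  chemotaxis_tick(st)
  expect_equal(st$agents$vox[1], v)
})

test_that("chemotaxis moves are locally optimal and respect capacity", {
  lat <- small_artery()
  st <- bare_state(lat, seed = 11)
  wall <- which(lat$class == 2L)
  set.seed(11)
  start <- sample(wall, 120, replace = TRUE)
  for (v in start) {
    st$agents <- atheroabm:::agents_add(st$agents, 2L, v)
    st$occupied[v] <- st$occupied[v] + AGENT_VOLUME_UM3[["MONOCYTE"]]
  }
  st$attract <- array(stats::runif(prod(lat$dims)), dim = lat$dims)
  before_attract <- st$attract[st$agents$vox]
  chemotaxis_tick(st)
  # never downhill
  expect_true(all(st$attract[st$agents$vox] >= before_attract - 1e-12))
  # capacity respected everywhere
  expect_true(all(st$occupied <= voxel_capacity(lat) + 1e-6))
  # bookkeeping matches recount
  expect_equal(max(abs(st$occupied -
                         atheroabm:::recount_occupied(lat, st$agents))), 0)
})

test_that("cohorts share the first cell's destination until it fills", {
  lat <- small_artery(capacity_fraction = 0.04)
  st <- bare_state(lat, seed = 2)
  ec <- which(lat$class == 1L)[10]
  # capacity 0.04 fits floor(4e4 / 7238) = 5 monocyte-lineage cells
  place_cohort(st, ec, c(0, 8, 0))
  cen <- agents_census(st$agents)
  expect_equal(sum(cen[c("M1", "M2")]) + sum(st$pending), 8)
  placed_vox <- st$agents$vox
  # first destination holds exactly its capacity's worth
  first <- placed_vox[1]
  expect_lte(sum(placed_vox == first), 5)
  expect_true(all(st$occupied <= voxel_capacity(lat) + 1e-6))
})

test_that("monocytes differentiate 2:1 into M1 and M2 at entry", {
  lat <- small_artery()
  st <- bare_state(lat, seed = 5)
  ec_set <- which(lat$class == 1L)
  set.seed(5)
  n <- 0L
  for (ec in ec_set) {
    place_cohort(st, ec, c(0, 40, 0))
    n <- n + 40L
  }
  cen <- agents_census(st$agents)
  m1 <- cen[["M1"]]; m2 <- cen[["M2"]]
  placed <- m1 + m2
  expect_gt(placed, 2000)
  # binomial proportion oracle: 3 sigma band around 2/3
  se <- sqrt(2 / 9 / placed)
  expect_lt(abs(m1 / placed - 2 / 3), 4 * se)
})

test_that("macrophages become foam cells above the oxLDL threshold", {
  lat <- small_artery()
  st <- bare_state(lat)
  v1 <- mid_wall_voxel(lat)
  co <- atheroabm:::vox_coords(lat, v1)
  v2 <- atheroabm:::vox_index(lat, co[1], co[2], co[3] - 2L)
  st$agents <- atheroabm:::agents_add(st$agents, c(4L, 5L), c(v1, v2))
  st$occupied[c(v1, v2)] <- AGENT_VOLUME_UM3[["M1"]]
  st$fields$OXLDL[v1] <- 101
  st$fields$OXLDL[v2] <- 99
  differentiate_agents(st)
  expect_equal(st$agents$type, c(6L, 5L))
  # volume bookkeeping grew by the foam-monocyte difference
  expect_equal(st$occupied[v1],
               unname(AGENT_VOLUME_UM3[["FOAM"]]))
})

test_that("lifespans remove neutrophils at 72 and monocytes at 168 ticks", {
  lat <- small_artery()
  st <- bare_state(lat)
  v <- mid_wall_voxel(lat)
  st$agents <- atheroabm:::agents_add(st$agents, c(1L, 4L, 3L, 6L), v,
                                      age = 0L)
  st$agents$age <- c(72L, 167L, 167L, 10000L)
  st$occupied[v] <- sum(AGENT_VOLUME_UM3[c(1, 4, 3, 6)])
  age_and_die(st)                        # ages become 73/168/168/10001
  expect_equal(sort(st$agents$type), c(3L, 4L, 6L))
  age_and_die(st)                        # 169: monocyte lineage dies
  expect_equal(st$agents$type, 6L)       # foam persists
  expect_equal(st$occupied[v], unname(AGENT_VOLUME_UM3[["FOAM"]]))
  expect_equal(max(abs(st$occupied -
                         atheroabm:::recount_occupied(lat, st$agents))), 0)
})

test_that("without production the wall clears within the longest lifespan", {
  lat <- small_artery()
  st <- bare_state(lat, seed = 9)
  wall <- which(lat$class == 2L)
  st$agents <- atheroabm:::agents_add(st$agents,
                                      rep(c(1L, 3L, 4L), 20),
                                      sample(wall, 60, replace = TRUE))
  st$occupied <- atheroabm:::recount_occupied(lat, st$agents)
  for (t in 1:169) age_and_die(st)
  expect_equal(length(st$agents$type), 0)
  expect_equal(sum(st$occupied), 0)
})
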