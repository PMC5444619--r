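# Simulation driver: determinism, homeostasis, insult seeding, event
# ordering and bookkeeping audits.

small_sim_config <- function(duration_ticks = 24L, ...) {
  simulation_config(geometry = small_spec(),
                    duration_ticks = duration_ticks,
                    audit_every = 8L, ...)
}

test_that("a healthy artery stays quiescent: no TEM, no growth", {
  cfg <- small_sim_config()
  st <- run_simulation(cfg)
  cen <- census_table(st)
  expect_equal(sum(cen$tem), 0)
  expect_equal(sum(agents_census(st$agents)), 0)
  expect_equal(unique(cen$lumen), lumen_volume(build_artery(small_spec())))
  expect_equal(length(st$remodel_log), 0)
})

test_that("the insult preset seeds 15 leukocytes mid-wall at tick 0", {
  cfg <- small_sim_config(insult = 15L)
  st <- init_state(cfg)
  cen <- agents_census(st$agents)
  expect_equal(sum(cen), 15)
  # composed per blood proportions: 9 neutrophils, 1 monocyte (as M1),
  # 5 lymphocytes
  expect_equal(unname(cen[["NEUTROPHIL"]]), 9)
  expect_equal(unname(cen[["M1"]]), 1)
  expect_equal(unname(cen[["LYMPHOCYTE"]]), 5)
  expect_true(all(st$lattice$class[st$agents$vox] == 2L))
})

test_that("identical config and seed give identical runs", {
  cfg <- small_sim_config(insult = 15L, seed = 42L)
  c1 <- census_table(run_simulation(cfg))
  c2 <- census_table(run_simulation(cfg))
  expect_identical(c1, c2)
  t1 <- tem_table(run_simulation(cfg))
  t2 <- tem_table(run_simulation(cfg))
  expect_identical(t1, t2)
})

# a lesioned artery held at low shear: contact-activated endothelium with
# an in-domain WSS stimulus, so recruitment flows every tick
lesioned_low_shear_state <- function(seed, duration = 30L) {
  cfg <- small_sim_config(seed = seed, duration_ticks = 0L)
  cfg$plaque <- plaque_fixture(0.25, cfg$geometry)
  st <- init_state(cfg)
  st$wss <- healthy_wss(st$lattice, 0.6)
  for (t in seq_len(duration)) step_tick(st)
  st
}

test_that("different seeds decorrelate the stochastic draws", {
  c1 <- census_table(lesioned_low_shear_state(1L))
  c2 <- census_table(lesioned_low_shear_state(2L))
  expect_false(identical(c1, c2))
  expect_gt(sum(c1$tem), 0)
})

test_that("a recruiting run keeps populations and occupancy consistent", {
  st <- lesioned_low_shear_state(5L, duration = 48L)
  cen <- census_table(st)
  expect_gt(sum(cen$tem), 0)
  # monocyte-lineage cells exist only as M1/M2/foam in the wall
  expect_equal(cen$MONOCYTE[nrow(cen)], 0)
  expect_gt(sum(cen[nrow(cen), c("M1", "M2", "FOAM")]), 0)
  # capacity and occupancy audits pass at the end of the run
  expect_silent(atheroabm:::audit_state(st))
})

test_that("knockout removes the lineage and its derivatives", {
  cfg <- small_sim_config(insult = 15L, seed = 5L)
  res <- experiment_knockout(cfg, removed_type = "MONOCYTE",
                             duration_ticks = 30L)
  ko <- res$knockout
  cen <- census_table(ko)
  expect_equal(sum(cen$M1), 0)
  expect_equal(sum(cen$M2), 0)
  expect_true(is.finite(res$reduction))
})

test_that("WSS spikes on a quiescent artery cause no transmigration", {
  res <- experiment_spike_stability(small_sim_config(), spike = "wss",
                                    amplitude = 0.9, duration_ticks = 50L)
  expect_equal(res$tem_total, 0)
  expect_equal(res$lumen_change, 0)
  expect_equal(res$wall_change, 0)
})

test_that("an IL-10-only spike never increases transmigration", {
  res <- experiment_spike_stability(small_sim_config(), spike = "il10",
                                    amplitude = 5, duration_ticks = 50L)
  expect_equal(res$tem_total, 0)
  expect_equal(res$lumen_change, 0)
})

test_that("zero-amplitude spikes reproduce the baseline run exactly", {
  base <- experiment_spike_stability(small_sim_config(seed = 9L),
                                     spike = "tnfa", amplitude = 0,
                                     duration_ticks = 30L)
  expect_equal(base$tem_total, 0)
  expect_equal(base$wall_change, 0)
})

test_that("run outputs serialize: census, snapshots, manifest", {
  cfg <- small_sim_config(insult = 15L, duration_ticks = 10L)
  st <- run_simulation(cfg)
  p1 <- tempfile(fileext = ".csv"); write_voxel_csv(st, p1)
  expect_gt(nrow(utils::read.csv(p1)), 100)
  p2 <- tempfile(fileext = ".vtk"); write_vtk(st, p2)
  expect_match(readLines(p2, n = 1), "vtk")
  p3 <- tempfile(fileext = ".json"); write_manifest(st, p3)
  man <- jsonlite::read_json(p3)
  expect_equal(man$seed, 1)
  expect_equal(man$tick, 10)
})
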