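# Waveform, WSS backends against the Poiseuille closed form, policies,
# handshake scheduling, surface reconstruction and field import/export.

test_that("the default waveform covers one period at 0.01 s resolution", {
  w <- default_waveform()
  expect_equal(nrow(w$samples), 80)
  expect_equal(w$period_s, 0.8)
  expect_equal(w$mean_q, flow_for_wss(1.4, 1.8e-3), tolerance = 1e-12)
  expect_gte(w$peak_q, w$mean_q)           # max >= mean, any waveform
  expect_true(all(w$samples$q_m3s > 0))
})

test_that("constant waveform makes all policies coincide", {
  w <- flow_waveform(seq(0, 0.79, by = 0.01), rep(2e-6, 80))
  peak <- select_wss_policy(w, "peak_systole")
  stdy <- select_wss_policy(w, "steady_mean")
  full <- select_wss_policy(w, "full_cycle")
  expect_equal(peak$q_m3s, 2e-6)
  expect_equal(stdy$q_m3s, 2e-6)
  expect_equal(nrow(full), 80)
  expect_equal(unique(full$q_m3s), 2e-6)
})

test_that("both built-in backends recover Poiseuille on a straight tube", {
  lat <- build_artery(geometry_spec())
  blood <- blood_properties()
  q <- flow_for_wss(1.4, 1.8e-3)
  # effective radius from voxel counts differs slightly from the nominal
  # 1.8 mm; the closed form must use the same r_eff
  r_eff <- lumen_profile(lat)[1]
  tau_ref <- 4 * blood$viscosity * q / (pi * r_eff^3)
  f1 <- estimate_wss(lat, q, backend = "poiseuille")
  expect_equal(mean(f1$tau_z), tau_ref, tolerance = 1e-10)
  f2 <- estimate_wss(lat, q, backend = "axisym")
  mid <- 10:50
  expect_lt(max(abs(f2$tau_z[mid] - tau_ref)) / tau_ref, 0.05)
  expect_true(all(f1$tau >= 0) && all(f2$tau >= 0))
})

test_that("Poiseuille shear scales as the inverse cube of the radius", {
  blood <- blood_properties()
  q <- 1e-6
  lat1 <- build_artery(geometry_spec(1800, 600, 1000))
  lat2 <- build_artery(geometry_spec(900, 600, 1000, margin_voxels = 4L))
  t1 <- mean(estimate_wss(lat1, q, backend = "poiseuille")$tau_z)
  t2 <- mean(estimate_wss(lat2, q, backend = "poiseuille")$tau_z)
  r1 <- lumen_profile(lat1)[1]; r2 <- lumen_profile(lat2)[1]
  expect_equal(t2 / t1, (r1 / r2)^3, tolerance = 1e-10)
})

test_that("a stenosis raises throat shear and depresses it distally", {
  spec <- geometry_spec()
  lat <- build_artery(spec)
  pf <- plaque_fixture(1.5, spec)
  lat <- insert_spherical_plaque(lat, pf$center_um, pf$radius_um)
  q <- flow_for_wss(1.4, 1.8e-3)
  f <- estimate_wss(lat, q, backend = "axisym")
  throat <- which.min(lumen_profile(lat))
  expect_gt(f$tau_z[throat], 1.4)
  distal <- (throat + 5):55
  expect_lt(min(f$tau_z[distal]), 1.2)
  # more low-shear endothelium distal to the throat than at it
  ec_z <- atheroabm:::vox_plane(lat, f$ec_idx)
  low <- f$tau < 1.2
  expect_gt(sum(low & ec_z %in% distal), sum(low & ec_z == throat))
})

test_that("handshake schedule follows lumen-change accounting", {
  expect_false(handshake_schedule("per_lumen_change", 61200, 61200))
  expect_true(handshake_schedule("per_lumen_change", 61199, 61200))
  expect_false(handshake_schedule("accelerated", 61150, 61200, quota = 80))
  expect_true(handshake_schedule("accelerated", 61120, 61200, quota = 80))
})

test_that("the lumen mesh is watertight and sits at the lumen radius", {
  lat <- build_artery(geometry_spec(800, 300, 1200, margin_voxels = 3L))
  mesh <- lumen_surface_mesh(lat, m = 48L)
  # watertight: every edge shared by exactly two triangles
  tri <- mesh$triangles
  edges <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(key) == 2))
  # ring vertices within half a voxel of the lumen radius
  v <- mesh$vertices
  side <- v[seq_len(nrow(v) - 2), , drop = FALSE]
  r <- sqrt((side[, 1] - lat$axis_um[1])^2 + (side[, 2] - lat$axis_um[2])^2)
  expect_true(all(abs(r - 800) < 100))
})

test_that("smoothing reduces the total turning of the saw-toothed ring", {
  lat <- build_artery(geometry_spec(800, 300, 400, margin_voxels = 3L))
  cls <- lat$class[, , 2]
  ij <- which(cls == 1L, arr.ind = TRUE)
  x <- (ij[, 1] - 0.5) * 100 - lat$axis_um[1]
  y <- (ij[, 2] - 0.5) * 100 - lat$axis_um[2]
  turning <- function(px, py) {
    dx <- diff(c(px, px[1])); dy <- diff(c(py, py[1]))
    a <- atan2(dy, dx)
    da <- diff(c(a, a[1]))
    sum(abs(atan2(sin(da), cos(da))))
  }
  o <- order(atan2(y, x))
  raw <- turning(x[o], y[o])
  ring <- atheroabm:::smooth_ring(x, y, m = length(x))
  expect_lt(turning(ring[, 1], ring[, 2]), raw)
})

test_that("STL export writes a valid binary file", {
  lat <- build_artery(geometry_spec(400, 300, 600, margin_voxels = 3L))
  path <- tempfile(fileext = ".stl")
  export_lumen_surface(lat, path, m = 24L)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  nt <- readBin(con, "integer", 1, size = 4, endian = "little")
  expect_equal(file.info(path)$size, 84 + 50 * nt)
})

test_that("WSS fields survive a CSV round trip; gaps are rejected", {
  lat <- small_artery()
  f <- healthy_wss(lat, 1.1)
  f$tau <- f$tau + seq_along(f$tau) * 1e-4
  path <- tempfile(fileext = ".csv")
  write_wss_csv(f, lat, path)
  back <- estimate_wss(lat, q_m3s = NA, backend = "imported",
                       imported = read_wss_csv(path))
  expect_equal(back$tau, f$tau, tolerance = 1e-12)
  expect_equal(back$provenance, "IMPORTED")
  bad <- read_wss_csv(path)[-1, ]
  expect_error(estimate_wss(lat, q_m3s = NA, backend = "imported",
                            imported = bad), "cover")
})
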