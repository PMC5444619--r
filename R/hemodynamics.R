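# Wall shear stress: pulsatile coronary waveform, lumen surface export,
# built-in WSS backends (Poiseuille 1D and axisymmetric stream-function/
# vorticity), external field import, evaluation policies and the ABM<->WSS
# handshake schedule.

#' Blood properties
#'
#' Homogeneous, incompressible, Newtonian blood.
#'
#' @param density_kg_m3 Density (kg/m^3).
#' @param viscosity_pa_s Dynamic viscosity (Pa s).
#' @return List of blood properties.
#' @export
blood_properties <- function(density_kg_m3 = 1060, viscosity_pa_s = 3.5e-3) {
  list(density = density_kg_m3, viscosity = viscosity_pa_s,
       rheology = "newtonian")
}

#' Flow rate giving a target Poiseuille wall shear stress
#'
#' @param tau_pa Target wall shear stress (Pa).
#' @param radius_m Tube radius (m).
#' @param blood [blood_properties()].
#' @return Volumetric flow rate (m^3/s).
#' @export
flow_for_wss <- function(tau_pa = 1.4, radius_m = 1.8e-3,
                         blood = blood_properties()) {
  tau_pa * pi * radius_m^3 / (4 * blood$viscosity)
}

#' Pulsatile coronary flow waveform
#'
#' Construct a waveform from sampled (time, flow) pairs. Samples must cover
#' one full period.
#'
#' @param t_s Sample times (s), starting at 0.
#' @param q_m3s Flow rates (m^3/s).
#' @param period_s Cardiac period (s).
#' @return Object of class `flow_waveform` with derived `mean_q` and
#'   `peak_q`.
#' @export
flow_waveform <- function(t_s, q_m3s, period_s = 0.8) {
  stopifnot(length(t_s) == length(q_m3s), all(q_m3s >= 0),
            all(diff(t_s) > 0), t_s[1] >= 0, max(t_s) < period_s)
  structure(list(period_s = period_s,
                 samples = data.frame(t_s = t_s, q_m3s = q_m3s),
                 mean_q = mean(q_m3s), peak_q = max(q_m3s)),
            class = "flow_waveform")
}

#' Default left-coronary-like waveform
#'
#' A biphasic, diastole-dominant waveform with cardiac period 0.8 s sampled
#' every 0.01 s (80 samples): peak flow in early diastole (about 1.85 times
#' the mean), a deep early-systolic trough (about 0.22 of the mean, when
#' myocardial contraction impedes coronary inflow) with a partial systolic
#' recovery, then refilling through diastole. The curve is normalized so
#' its time average equals `q_mean_m3s`; the default mean makes the healthy
#' 1800 um artery run at a mean wall shear stress of 1.4 Pa.
#'
#' @param q_mean_m3s Mean flow over the cycle (m^3/s).
#' @param period_s Cardiac period (s).
#' @param dt_s Sampling interval (s).
#' @return A [flow_waveform()].
#' @export
default_waveform <- function(q_mean_m3s = flow_for_wss(), period_s = 0.8,
                             dt_s = 0.01) {
  knots_phi <- c(0, 0.06, 0.15, 0.25, 0.33, 0.40, 0.48, 0.60, 0.75,
                 0.90, 1.00)
  knots_q <- c(1.55, 1.85, 1.45, 0.80, 0.22, 0.65, 0.90, 1.05, 1.35,
               1.65, 1.55)
  f <- stats::splinefun(knots_phi, knots_q, method = "monoH.FC")
  phi <- seq(0, period_s - dt_s, by = dt_s) / period_s
  q <- pmax(f(phi), 0.05)
  q <- q / mean(q) * q_mean_m3s
  flow_waveform(phi * period_s, q, period_s)
}

#' Per-plane effective lumen radius
#'
#' Effective radius (m) from the lumen patch count of each axial plane
#' (area-equivalent circle).
#'
#' @param lattice An `artery_lattice`.
#' @return Numeric vector of length nz (m).
#' @export
lumen_profile <- function(lattice) {
  nz <- lattice$dims[3]
  cnt <- vapply(seq_len(nz),
                function(z) sum(lattice$class[, , z] == CLASS_LUMEN), 0)
  sqrt(cnt * (lattice$patch_um * 1e-6)^2 / pi)
}

ec_indices <- function(lattice) {
  cache <- lattice$cache
  if (is.null(cache$ec_idx)) cache$ec_idx <- which(lattice$class == CLASS_EC)
  cache$ec_idx
}

# map per-plane tau to EC voxels with azimuthal modulation by wall
# proximity: patches protruding toward the axis (the plaque cap) see more
# shear than patches on the far wall; rescaled so the plane mean equals the
# axisymmetric value
map_tau_to_ec <- function(lattice, tau_z) {
  cache <- lattice$cache
  if (is.null(cache$ec_w)) {
    ec <- ec_indices(lattice)
    co <- vox_coords(lattice, ec)
    r_vox <- lattice$radial_um[cbind(co[, 1], co[, 2])]
    z <- co[, 3]
    rbar <- rowsum(r_vox, z) / as.vector(table(z))
    w <- (rbar[as.character(z), 1] / r_vox)^2
    wbar <- rowsum(w, z) / as.vector(table(z))
    cache$ec_w <- w / wbar[as.character(z), 1]
    cache$ec_z <- z
  }
  tau_z[cache$ec_z] * cache$ec_w
}

#' Estimate the wall shear stress field
#'
#' Computes per-endothelial-patch wall shear stress for a given flow rate.
#' The `"poiseuille"` backend applies the closed-form fully developed law
#' `tau(z) = 4 mu Q / (pi r_eff(z)^3)` plane by plane. The `"axisym"`
#' backend solves steady laminar axisymmetric Navier-Stokes (stream
#' function / vorticity form) on the area-equivalent profile, capturing
#' post-stenotic shear undershoot and recirculation; the magnitude of the
#' wall-normal velocity gradient gives tau. Both map plane values onto EC
#' voxels with an azimuthal wall-proximity modulation. `"imported"` uses a
#' table read with [read_wss_csv()].
#'
#' @param lattice An `artery_lattice`.
#' @param q_m3s Volumetric flow rate (m^3/s).
#' @param blood [blood_properties()].
#' @param backend `"axisym"`, `"poiseuille"` or `"imported"`.
#' @param imported Data frame from [read_wss_csv()] when
#'   `backend = "imported"`.
#' @param cache Optional environment reused across calls to warm-start the
#'   axisymmetric solver (much faster for repeated solves on slowly
#'   changing geometry).
#' @param phase Label stored in the field (waveform phase or policy name).
#' @return Object of class `wss_field`: per-EC-voxel `tau` (Pa, >= 0),
#'   the EC voxel indices, per-plane `tau_z`, provenance and phase.
#' @export
estimate_wss <- function(lattice, q_m3s, blood = blood_properties(),
                         backend = c("axisym", "poiseuille", "imported"),
                         imported = NULL, cache = NULL, phase = NA) {
  backend <- match.arg(backend)
  ec <- ec_indices(lattice)
  if (backend == "imported") {
    stopifnot(is.data.frame(imported))
    idx <- vox_index(lattice, imported$x, imported$y, imported$z)
    tau <- imported$tau_pa[match(ec, idx)]
    if (anyNA(tau)) stop("imported WSS table does not cover every EC voxel")
    tau_z <- tapply(tau, vox_plane(lattice, ec), mean)
    return(structure(list(tau = pmax(tau, 0), ec_idx = ec,
                          tau_z = as.numeric(tau_z),
                          provenance = "IMPORTED", phase = phase),
                     class = "wss_field"))
  }
  r_eff <- lumen_profile(lattice)
  if (any(r_eff <= 0)) stop("empty lumen cross-section")
  if (backend == "poiseuille") {
    tau_z <- 4 * blood$viscosity * q_m3s / (pi * r_eff^3)
    prov <- "BUILTIN_1D"
  } else {
    tau_z <- axisym_tau(r_eff, q_m3s, blood, lattice$patch_um, cache)
    prov <- "BUILTIN_AXISYM"
  }
  structure(list(tau = pmax(map_tau_to_ec(lattice, tau_z), 0), ec_idx = ec,
                 tau_z = tau_z, provenance = prov, phase = phase),
            class = "wss_field")
}

#' Uniform healthy wall shear stress field
#'
#' @param lattice An `artery_lattice`.
#' @param tau_pa Uniform shear stress (Pa); 1.4 Pa is the healthy baseline.
#' @return A `wss_field`.
#' @export
healthy_wss <- function(lattice, tau_pa = 1.4) {
  ec <- ec_indices(lattice)
  structure(list(tau = rep(tau_pa, length(ec)), ec_idx = ec,
                 tau_z = rep(tau_pa, lattice$dims[3]),
                 provenance = "BUILTIN_1D", phase = "healthy"),
            class = "wss_field")
}

# per-plane tau from the axisymmetric solver, with straight inlet/outlet
# buffer extensions and 2x axial refinement
axisym_tau <- function(r_eff_m, q_m3s, blood, patch_um, cache = NULL,
                       neta = 33L) {
  nz <- length(r_eff_m)
  dxi <- patch_um * 1e-6 / 2
  n_in <- 20L; n_out <- 40L
  z_plane <- (seq_len(nz) - 0.5) * patch_um * 1e-6
  z_fine <- seq(0.5 * dxi, nz * patch_um * 1e-6 - 0.5 * dxi, by = dxi)
  r_fine <- stats::approx(z_plane, r_eff_m, xout = z_fine, rule = 2)$y
  Rz <- c(rep(r_fine[1], n_in), r_fine, rep(r_fine[length(r_fine)], n_out))
  warm_psi <- NULL; warm_chi <- NULL
  if (!is.null(cache) && !is.null(cache$psi) &&
      nrow(cache$psi) == length(Rz)) {
    s <- q_m3s / cache$q              # Stokes-scale the previous solution
    warm_psi <- cache$psi * s; warm_chi <- cache$chi * s
  }
  sol <- axisym_solve_cpp(Rz, dxi, q_m3s, blood$viscosity, blood$density,
                          as.integer(neta), 60000L, 3e-4,
                          warm_psi, warm_chi)
  if (!is.null(cache)) {
    cache$psi <- sol$psi; cache$chi <- sol$chi; cache$q <- q_m3s
  }
  tau_fine <- abs(sol$tau[(n_in + 1):(n_in + length(r_fine))])
  # average the two fine nodes per plane
  0.5 * (tau_fine[seq(1, length(tau_fine), by = 2)] +
           tau_fine[seq(2, length(tau_fine), by = 2)])
}

#' Wall shear stress evaluation plan for a waveform
#'
#' `peak_systole` evaluates one field at the phase of maximum flow,
#' `steady_mean` one field at the time-averaged flow, `full_cycle` one
#' field per waveform sample (80 at the default 0.01 s resolution).
#'
#' @param waveform A [flow_waveform()].
#' @param policy One of `"peak_systole"`, `"steady_mean"`, `"full_cycle"`.
#' @return Data frame of evaluation phases with columns `t_s` and `q_m3s`.
#' @export
select_wss_policy <- function(waveform,
                              policy = c("peak_systole", "steady_mean",
                                         "full_cycle")) {
  policy <- match.arg(policy)
  s <- waveform$samples
  switch(policy,
         peak_systole = s[which.max(s$q_m3s), , drop = FALSE],
         steady_mean = data.frame(t_s = NA_real_, q_m3s = waveform$mean_q),
         full_cycle = s)
}

#' Should the WSS field be recomputed?
#'
#' In `per_lumen_change` mode an update is due whenever the total lumen
#' voxel count differs from the count at the last update. In `accelerated`
#' mode the update waits until the cumulative change reaches the
#' patch-change quota for the plaque-severity class (defaults 80 / 35 / 10
#' lumen patches for small / medium / big plaques).
#'
#' @param mode `"per_lumen_change"` or `"accelerated"`.
#' @param lumen_now Current total lumen voxel count.
#' @param lumen_at_update Count at the last WSS update.
#' @param quota Patch-change quota for accelerated mode.
#' @return `TRUE` if a WSS update is due.
#' @export
handshake_schedule <- function(mode = c("per_lumen_change", "accelerated"),
                               lumen_now, lumen_at_update, quota = 80L) {
  mode <- match.arg(mode)
  delta <- abs(lumen_now - lumen_at_update)
  if (mode == "per_lumen_change") delta > 0 else delta >= quota
}

# ---------------------------------------------------------------------------
# Lumen surface reconstruction and STL export
# ---------------------------------------------------------------------------

# smoothed ring of the EC centroids of one plane: azimuthal sort,
# consecutive-pair averaging, circular moving average, resampling to m
# points at uniform azimuth
smooth_ring <- function(x, y, m = 72L, window = 5L) {
  if (length(x) < 8) stop("non-closed EC ring: too few endothelial patches")
  th <- atan2(y, x)
  o <- order(th)
  x <- x[o]; y <- y[o]
  # consecutive-pair averaging (circular)
  x <- (x + c(x[-1], x[1])) / 2
  y <- (y + c(y[-1], y[1])) / 2
  circ_ma <- function(v) {
    k <- (window - 1L) %/% 2L
    n <- length(v)
    ext <- c(v[(n - k + 1):n], v, v[1:k])
    stats::filter(ext, rep(1 / window, window), sides = 2)[(k + 1):(k + n)]
  }
  x <- as.numeric(circ_ma(x)); y <- as.numeric(circ_ma(y))
  th <- atan2(y, x); r <- sqrt(x^2 + y^2)
  o <- order(th); th <- th[o]; r <- r[o]
  th_ext <- c(th, th[1] + 2 * pi)
  r_ext <- c(r, r[1])
  tq <- seq(-pi, pi, length.out = m + 1)[-(m + 1)]
  tq_shift <- ifelse(tq < th_ext[1], tq + 2 * pi, tq)
  rq <- stats::approx(th_ext, r_ext, xout = tq_shift, rule = 2)$y
  cbind(x = rq * cos(tq), y = rq * sin(tq))
}

#' Reconstruct and triangulate the lumen surface
#'
#' Per z-plane, EC patch centroids are sorted azimuthally, smoothed
#' (consecutive-pair averaging followed by a circular moving average) and
#' resampled; rings of adjacent planes are stitched into a watertight
#' triangle mesh capped at both ends.
#'
#' @param lattice An `artery_lattice`.
#' @param m Vertices per ring.
#' @return List with `vertices` (n x 3, um) and `triangles` (n x 3,
#'   1-based vertex indices).
#' @export
lumen_surface_mesh <- function(lattice, m = 72L) {
  d <- lattice$dims; h <- lattice$patch_um
  nz <- d[3]
  verts <- NULL
  for (z in seq_len(nz)) {
    cls <- lattice$class[, , z]
    ij <- which(cls == CLASS_EC, arr.ind = TRUE)
    x <- (ij[, 1] - 0.5) * h - lattice$axis_um[1]
    y <- (ij[, 2] - 0.5) * h - lattice$axis_um[2]
    ring <- smooth_ring(x, y, m = m)
    verts <- rbind(verts, cbind(ring[, 1] + lattice$axis_um[1],
                                ring[, 2] + lattice$axis_um[2],
                                (z - 0.5) * h))
  }
  tri <- NULL
  for (z in seq_len(nz - 1)) {
    a <- (z - 1) * m + seq_len(m)
    b <- z * m + seq_len(m)
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    tri <- rbind(tri, cbind(a, b, a2), cbind(a2, b, b2))
  }
  # end caps (fan to plane centroid)
  n_side <- nrow(verts)
  c0 <- colMeans(verts[seq_len(m), , drop = FALSE])
  c1 <- colMeans(verts[(nz - 1) * m + seq_len(m), , drop = FALSE])
  verts <- rbind(verts, c0, c1)
  a <- seq_len(m); a2 <- c(a[-1], a[1])
  tri <- rbind(tri, cbind(a2, a, n_side + 1))
  b <- (nz - 1) * m + seq_len(m); b2 <- c(b[-1], b[1])
  tri <- rbind(tri, cbind(b, b2, n_side + 2))
  list(vertices = verts, triangles = tri)
}

#' Write a triangle mesh as binary STL
#'
#' @param mesh List with `vertices` and `triangles` as from
#'   [lumen_surface_mesh()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "voxel lumen surface"))[1:80]
  writeBin(header, con)
  nt <- nrow(mesh$triangles)
  writeBin(as.integer(nt), con, size = 4, endian = "little")
  v <- mesh$vertices
  for (t in seq_len(nt)) {
    p <- v[mesh$triangles[t, ], , drop = FALSE]
    n <- c((p[2, 2] - p[1, 2]) * (p[3, 3] - p[1, 3]) -
             (p[2, 3] - p[1, 3]) * (p[3, 2] - p[1, 2]),
           (p[2, 3] - p[1, 3]) * (p[3, 1] - p[1, 1]) -
             (p[2, 1] - p[1, 1]) * (p[3, 3] - p[1, 3]),
           (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
             (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeBin(as.numeric(c(n, t(p))), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Export the lumen surface to a binary STL file
#'
#' @param lattice An `artery_lattice`.
#' @param path Output file path.
#' @param m Vertices per ring.
#' @return `path`, invisibly.
#' @export
export_lumen_surface <- function(lattice, path, m = 72L) {
  write_stl(lumen_surface_mesh(lattice, m = m), path)
}

#' Write / read a per-voxel WSS table
#'
#' CSV with columns `x`, `y`, `z` (1-based voxel indices) and `tau_pa`.
#'
#' @param field A `wss_field`.
#' @param lattice The lattice the field belongs to.
#' @param path CSV path.
#' @return `path` (write) or a data frame (read).
#' @export
write_wss_csv <- function(field, lattice, path) {
  co <- vox_coords(lattice, field$ec_idx)
  utils::write.csv(data.frame(x = co[, 1], y = co[, 2], z = co[, 3],
                              tau_pa = field$tau),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wss_csv
#' @export
read_wss_csv <- function(path) {
  utils::read.csv(path)
}
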