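# Snapshot and manifest output: voxel tables (CSV), legacy VTK structured
# points for visualization, and a JSON run manifest.

#' Write a voxel snapshot table
#'
#' One row per wall/EC voxel: indices, class, per-type cell counts and
#' species concentrations.
#'
#' @param state Simulation state.
#' @param path CSV path.
#' @param all_voxels Include lumen/exterior voxels too.
#' @return `path`, invisibly.
#' @export
write_voxel_csv <- function(state, path, all_voxels = FALSE) {
  lat <- state$lattice
  keep <- if (all_voxels) seq_len(prod(lat$dims)) else
    which(lat$class == CLASS_WALL | lat$class == CLASS_EC)
  co <- vox_coords(lat, keep)
  df <- data.frame(x = co[, 1], y = co[, 2], z = co[, 3],
                   class = c("LUMEN", "EC", "WALL",
                             "EXTERIOR")[lat$class[keep] + 1L])
  ag <- state$agents
  for (k in seq_along(AGENT_TYPES)) {
    cntk <- integer(length(keep))
    sel <- ag$type == k
    if (any(sel)) {
      tb <- table(ag$vox[sel])
      m <- match(as.integer(names(tb)), keep)
      ok <- !is.na(m)
      cntk[m[ok]] <- as.integer(tb)[ok]
    }
    df[[AGENT_TYPES[k]]] <- cntk
  }
  for (s in SPECIES) df[[s]] <- state$fields[[s]][keep]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a legacy VTK structured-points snapshot
#'
#' Voxel classes and total cell counts on the full lattice, readable by
#' ParaView and similar viewers.
#'
#' @param state Simulation state.
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(state, path) {
  lat <- state$lattice
  d <- lat$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "artery lattice snapshot", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", lat$patch_um, lat$patch_um,
                       lat$patch_um),
               sprintf("POINT_DATA %d", prod(d)),
               "SCALARS class int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.integer(lat$class), collapse = " "), con)
  cnt <- array(0L, dim = d)
  if (agents_count(state$agents) > 0) {
    tb <- table(state$agents$vox)
    cnt[as.integer(names(tb))] <- as.integer(tb)
  }
  writeLines(c("SCALARS cells int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.integer(cnt), collapse = " "), con)
  invisible(path)
}

#' Write the run manifest
#'
#' Configuration (geometry, rule constants, seeds, backend and policy
#' choices) serialized as JSON next to the run outputs, so every output is
#' reproducible from its manifest.
#'
#' @param state Simulation state.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(state, path) {
  cfg <- state$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("atheroabm")),
    seed = cfg$seed,
    geometry = unclass(cfg$geometry),
    capacity_fraction = cfg$capacity_fraction,
    wss = list(backend = cfg$wss_backend, policy = cfg$wss_policy,
               handshake = cfg$handshake, quota = cfg$handshake_quota),
    recruitment = unclass(cfg$recruitment),
    remodeling = unclass(cfg$remodeling),
    c0_ldl = cfg$c0_ldl,
    insult = cfg$insult,
    duration_ticks = cfg$duration_ticks,
    tick = state$tick
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
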