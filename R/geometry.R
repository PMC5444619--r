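# Voxelized artery lattice: classes, construction, plaque insertion,
# per-plane bookkeeping.

# voxel class codes
CLASS_LUMEN    <- 0L
CLASS_EC       <- 1L
CLASS_WALL     <- 2L
CLASS_EXTERIOR <- 3L

#' Geometry specification for a straight coronary segment
#'
#' All lengths are in micrometres and must be positive multiples of the
#' patch size (100 um). Defaults describe a left-anterior-descending-like
#' artery: lumen radius 1800 um, wall (media + adventitia) 600 um, length
#' 6000 um.
#'
#' @param lumen_radius_um Lumen radius (um).
#' @param wall_thickness_um Wall thickness beyond the endothelial shell (um).
#' @param length_um Axial length (um); the z axis is the flow direction,
#'   inlet at z = 0.
#' @param patch_um Cubic patch edge length (um).
#' @param margin_voxels Extra exterior shells kept around the wall so the
#'   artery (and outward-bulging lesions) can remodel outward without
#'   resizing the lattice.
#' @return An object of class `geometry_spec`.
#' @export
geometry_spec <- function(lumen_radius_um = 1800, wall_thickness_um = 600,
                          length_um = 6000, patch_um = 100,
                          margin_voxels = 14L) {
  stopifnot(lumen_radius_um > 0, wall_thickness_um > 0, length_um > 0)
  for (v in c(lumen_radius_um, wall_thickness_um, length_um)) {
    if (abs(v / patch_um - round(v / patch_um)) > 1e-9 || v < patch_um) {
      stop("geometry lengths must be positive multiples of the patch size")
    }
  }
  if (wall_thickness_um < patch_um) {
    stop("wall must contain at least one patch shell")
  }
  structure(list(lumen_radius_um = lumen_radius_um,
                 wall_thickness_um = wall_thickness_um,
                 length_um = length_um,
                 patch_um = patch_um,
                 margin_voxels = as.integer(margin_voxels)),
            class = "geometry_spec")
}

#' Build the voxelized artery
#'
#' Voxels whose centre lies within the lumen radius of the axis are LUMEN;
#' the single shell of wall voxels face-adjacent to the lumen is EC
#' (endothelium); the remaining voxels out to lumen radius + one patch +
#' wall thickness are WALL; everything else is EXTERIOR. Construction is
#' deterministic.
#'
#' @param spec A [geometry_spec()].
#' @param capacity_fraction Fraction of each wall patch volume available to
#'   cells (the rest is fixed extracellular matrix). 0.40 in the standard
#'   model, 0.04 in accelerated mode.
#' @return An object of class `artery_lattice`.
#' @export
build_artery <- function(spec = geometry_spec(), capacity_fraction = 0.40) {
  h <- spec$patch_um
  r_vox <- spec$lumen_radius_um / h
  w_vox <- spec$wall_thickness_um / h
  nz <- as.integer(spec$length_um / h)
  half <- r_vox + 1 + w_vox + spec$margin_voxels
  nx <- ny <- as.integer(2 * half)
  axis_um <- c(nx, ny) * h / 2

  xc <- (seq_len(nx) - 0.5) * h - axis_um[1]
  yc <- (seq_len(ny) - 0.5) * h - axis_um[2]
  d_um <- sqrt(outer(xc^2, yc^2, `+`))          # nx x ny radial distance
  lumen2d <- d_um < spec$lumen_radius_um
  solid2d <- d_um < spec$lumen_radius_um + h + spec$wall_thickness_um

  cls2d <- matrix(CLASS_EXTERIOR, nx, ny)
  cls2d[solid2d] <- CLASS_WALL
  cls2d[lumen2d] <- CLASS_LUMEN

  cls <- array(rep(cls2d, nz), dim = c(nx, ny, nz))
  lat <- structure(list(
    patch_um = h,
    dims = c(nx, ny, nz),
    class = cls,
    occupied = array(0, dim = c(nx, ny, nz)),
    ecm_fraction = 1 - 0.40,
    capacity_fraction = capacity_fraction,
    axis_um = axis_um,
    radial_um = d_um,
    azimuth = atan2(rep(yc, each = nx), rep(xc, times = ny)),
    lumen_radius_um = spec$lumen_radius_um,
    wall_thickness_um = spec$wall_thickness_um,
    spec = spec,
    cache = new.env(parent = emptyenv())
  ), class = "artery_lattice")
  dim(lat$azimuth) <- c(nx, ny)

  lat <- reclassify_shell(lat)
  lat$ref_lumen_per_plane <- sum(lat$class[, , 1] == CLASS_LUMEN)
  lat
}

#' Per-voxel cell capacity in cubic micrometres
#' @param lattice An `artery_lattice`.
#' @return Scalar capacity (um^3) of one wall patch.
#' @export
voxel_capacity <- function(lattice) {
  lattice$capacity_fraction * lattice$patch_um^3  # (100 um)^3 = 1e6 um3
}

# copy of `a` shifted so out[i,j,k] = a[i+dx, j+dy, k+dz]; outside = `fill`
shift3 <- function(a, dx, dy, dz, fill) {
  d <- dim(a)
  out <- array(fill, dim = d)
  xs <- max(1, 1 - dx):min(d[1], d[1] - dx)
  ys <- max(1, 1 - dy):min(d[2], d[2] - dy)
  zs <- max(1, 1 - dz):min(d[3], d[3] - dz)
  out[xs, ys, zs] <- a[xs + dx, ys + dy, zs + dz]
  out
}

# TRUE where voxel has >=1 face neighbour with class `what`
has_face_neighbor <- function(cls, what) {
  res <- array(FALSE, dim = dim(cls))
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    res <- res | (shift3(cls, s[1], s[2], s[3], fill = -1L) == what)
  }
  res
}

#' Re-establish the endothelial shell
#'
#' Every wall voxel face-adjacent to the lumen becomes EC; every EC voxel
#' no longer adjacent to the lumen reverts to WALL. Called after every
#' geometry edit so the endothelium stays a closed surface.
#'
#' @param lattice An `artery_lattice`.
#' @return The lattice with a consistent EC shell.
#' @export
reclassify_shell <- function(lattice) {
  cls <- lattice$class
  adj_lumen <- has_face_neighbor(cls, CLASS_LUMEN)
  cls[cls == CLASS_EC & !adj_lumen] <- CLASS_WALL
  cls[cls == CLASS_WALL & adj_lumen] <- CLASS_EC
  lattice$class <- cls
  invalidate_cache(lattice)
}

invalidate_cache <- function(lattice) {
  rm(list = ls(lattice$cache), envir = lattice$cache)
  lattice
}

#' Insert a spherical plaque lesion
#'
#' Lumen and exterior voxels whose centre falls inside the sphere become
#' WALL: the lumen-side cap is the stenosis and the exterior-side cap is
#' the compensatory outward bulge of the remodeled wall (a largely
#' intramural lesion can have near-zero stenosis). The endothelial shell
#' is rebuilt over the new lumen surface. The indices of all wall voxels
#' inside the sphere (excluding the new EC shell) are attached as
#' attribute `"plaque_voxels"` so callers can seed them with plaque
#' agents.
#'
#' @param lattice An `artery_lattice`.
#' @param center_um Sphere centre, physical coordinates (x, y, z) in um
#'   measured from the lattice origin.
#' @param radius_um Sphere radius (um); 0 leaves the lattice unchanged.
#' @return The edited lattice.
#' @export
insert_spherical_plaque <- function(lattice, center_um, radius_um) {
  if (radius_um <= 0) {
    attr(lattice, "plaque_voxels") <- integer(0)
    return(lattice)
  }
  d <- lattice$dims; h <- lattice$patch_um
  idx <- arrayInd(seq_len(prod(d)), d)
  cx <- (idx[, 1] - 0.5) * h; cy <- (idx[, 2] - 0.5) * h
  cz <- (idx[, 3] - 0.5) * h
  inside <- (cx - center_um[1])^2 + (cy - center_um[2])^2 +
    (cz - center_um[3])^2 < radius_um^2
  cls <- lattice$class
  conv <- inside & (as.vector(cls) == CLASS_LUMEN |
                      as.vector(cls) == CLASS_EXTERIOR)
  cls[conv] <- CLASS_WALL
  lattice$class <- cls
  # total occlusion check
  for (z in seq_len(d[3])) {
    if (sum(lattice$class[, , z] == CLASS_LUMEN) == 0) {
      stop("plaque occludes an entire plane; total occlusion unsupported")
    }
  }
  lattice <- reclassify_shell(lattice)
  pv <- which(inside & (as.vector(lattice$class) == CLASS_WALL))
  attr(lattice, "plaque_voxels") <- pv
  lattice
}

#' Lumen and plaque patch counts for one axial plane
#'
#' Lumen area is the number of lumen patches in the plane; plaque area is
#' the number of wall patches in the plane containing at least one
#' leukocyte-derived agent (tracked through occupied volume).
#'
#' @param lattice An `artery_lattice`.
#' @param z Plane index (1-based).
#' @return Named numeric vector with `lumen` and `plaque` patch counts.
#' @export
plane_areas <- function(lattice, z) {
  stopifnot(z >= 1, z <= lattice$dims[3])
  cls <- lattice$class[, , z]
  occ <- lattice$occupied[, , z]
  c(lumen = sum(cls == CLASS_LUMEN),
    plaque = sum(cls == CLASS_WALL & occ > 1))
}

#' Per-plane stenosis severity
#'
#' Severity is 1 - lumen patch count / healthy reference count for each
#' axial plane.
#'
#' @param lattice An `artery_lattice`.
#' @return Numeric vector of length nz.
#' @export
stenosis_severity <- function(lattice) {
  nz <- lattice$dims[3]
  lum <- vapply(seq_len(nz),
                function(z) sum(lattice$class[, , z] == CLASS_LUMEN), 0)
  1 - lum / lattice$ref_lumen_per_plane
}

#' Total lumen volume in patches
#' @param lattice An `artery_lattice`.
#' @return Integer count of lumen voxels.
#' @export
lumen_volume <- function(lattice) sum(lattice$class == CLASS_LUMEN)

# linear voxel index helpers
vox_index <- function(lattice, i, j, k) {
  d <- lattice$dims
  as.integer(i + (j - 1) * d[1] + (k - 1) * d[1] * d[2])
}

vox_coords <- function(lattice, idx) {
  arrayInd(idx, lattice$dims)
}

# plane (z) of a linear index
vox_plane <- function(lattice, idx) {
  d <- lattice$dims
  as.integer((idx - 1) %/% (d[1] * d[2])) + 1L
}
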