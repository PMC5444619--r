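# Reaction-diffusion of soluble species (TNF-alpha, IL-1beta, IL-10, LDL,
# oxidized LDL) on the wall voxels of the lattice. Transport follows Fick's
# law; the lumen-facing and outer-wall boundaries are perfect sinks (the
# flowing blood and vasa vasorum convect cytokines away). One tick is one
# simulated hour, split into explicit sub-steps with D dt / h^2 <= 1/8 --
# inside the 1/6 stability limit and far enough from it that the
# oscillatory high-frequency modes of the scheme decay immediately.

SPECIES <- c("TNFA", "IL1B", "IL10", "LDL", "OXLDL")

#' Transport parameters for the soluble species
#'
#' Cytokines diffuse at 3e-11 m^2/s and LDL at 2.5e-11 m^2/s; oxidized LDL
#' is immobile (it is generated and consumed locally). Concentrations are
#' U/ml for cytokines and ng/ul (= ug/ml) for LDL and oxLDL.
#'
#' @param tick_s Tick duration (s).
#' @return Named list of parameters.
#' @export
species_params <- function(tick_s = 3600) {
  list(diffusivity = c(TNFA = 3e-11, IL1B = 3e-11, IL10 = 3e-11,
                       LDL = 2.5e-11, OXLDL = 0),
       tick_s = tick_s)
}

#' Empty species fields for a lattice
#'
#' @param lattice An `artery_lattice`.
#' @return Named list of zero arrays, one per species.
#' @export
species_fields <- function(lattice) {
  z <- array(0, dim = lattice$dims)
  stats::setNames(lapply(SPECIES, function(s) z), SPECIES)
}

# packed active-voxel neighbour table for the diffusion kernel.
# mask: logical array of voxels carrying concentration; sink_boundary:
# faces into non-mask voxels (or out of the array) absorb (TRUE) or
# reflect (FALSE). Encoding: 0-based packed neighbour index; n_active for
# a sink face (phantom zero voxel); the voxel's own index for a sealed
# face.
make_diffusion_cache <- function(mask, sink_boundary = TRUE) {
  d <- dim(mask)
  active <- which(mask)
  n <- length(active)
  pos <- integer(prod(d)); pos[active] <- seq_len(n)
  idx <- arrayInd(active, d)
  nbr <- matrix(0L, n, 6)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  self <- seq_len(n) - 1L
  for (k in 1:6) {
    ii <- idx[, 1] + shifts[k, 1]
    jj <- idx[, 2] + shifts[k, 2]
    kk <- idx[, 3] + shifts[k, 3]
    inb <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
    p <- if (sink_boundary) rep(n, n) else self
    lin <- ii[inb] + (jj[inb] - 1) * d[1] + (kk[inb] - 1) * d[1] * d[2]
    hit <- pos[lin]
    pin <- ifelse(hit > 0L, hit - 1L, if (sink_boundary) n else NA_integer_)
    pin[is.na(pin)] <- self[inb][is.na(pin)]
    p[inb] <- pin
    nbr[, k] <- as.integer(p)
  }
  list(active = active, nbr = nbr, sink_boundary = sink_boundary, dims = d)
}

# lattice-wide cache over wall + endothelium, plus cropped sub-caches for
# spatially localized fields (bounding box of the non-zero support plus a
# diffusion halo, quantized to reduce rebuilds)
diffusion_cache <- function(lattice) {
  cache <- lattice$cache
  if (is.null(cache$diff)) {
    mask <- lattice$class == CLASS_EC | lattice$class == CLASS_WALL
    cache$diff <- make_diffusion_cache(mask, sink_boundary = TRUE)
  }
  cache$diff
}

cropped_cache <- function(lattice, conc, halo) {
  d <- dim(conc)
  nz <- which(conc > 0)
  if (length(nz) == 0) return(NULL)
  co <- arrayInd(nz, d)
  lo <- pmax(apply(co, 2, min) - halo, 1L)
  hi <- pmin(apply(co, 2, max) + halo, d)
  # quantize outward to multiples of 8 so consecutive ticks reuse the box
  lo <- pmax(1L, (lo - 1L) %/% 8L * 8L + 1L)
  hi <- pmin(d, ((hi + 7L) %/% 8L) * 8L)
  full <- diffusion_cache(lattice)
  if (prod(hi - lo + 1) > 0.6 * prod(d)) return(full)
  cache <- lattice$cache
  key <- paste(lo, hi, collapse = "-")
  if (!is.null(cache$diffbox[[key]])) return(cache$diffbox[[key]])
  mask <- array(FALSE, dim = d)
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  mask <- mask & (lattice$class == CLASS_EC | lattice$class == CLASS_WALL)
  sub <- make_diffusion_cache(mask, sink_boundary = TRUE)
  if (is.null(cache$diffbox) || length(cache$diffbox) > 6) {
    cache$diffbox <- list()
  }
  cache$diffbox[[key]] <- sub
  sub
}

#' One tick of Fickian diffusion
#'
#' Applies one simulated hour of diffusion on the wall-and-endothelium
#' voxel set (or an explicit mask), with sink boundaries toward lumen and
#' exterior. The tick is split into `ceiling(8 D tick / h^2)` explicit
#' sub-steps, keeping every sub-step inside the stability limit with
#' margin against oscillatory modes.
#'
#' @param conc Concentration array (same dims as the lattice, >= 0).
#' @param lattice An `artery_lattice`, or `NULL` when `cache` is supplied.
#' @param diffusivity Diffusivity (m^2/s).
#' @param tick_s Tick duration (s).
#' @param cache Optional neighbour table from `make_diffusion_cache()`
#'   (used directly, e.g. for sealed test boxes).
#' @param crop Restrict the update to the bounding box of the non-zero
#'   support plus a diffusion halo (exact to the truncated far tail of the
#'   one-tick kernel; a large saving for spatially localized fields).
#' @return Concentration array after one tick, with the total sink outflux
#'   attached as attribute `"outflux"`.
#' @export
diffuse_tick <- function(conc, lattice, diffusivity, tick_s = 3600,
                         cache = NULL, crop = FALSE) {
  if (any(conc < 0)) stop("negative input concentration")
  if (diffusivity == 0) {
    attr(conc, "outflux") <- 0
    return(conc)
  }
  h_m <- if (!is.null(lattice)) lattice$patch_um * 1e-6 else 100e-6
  fo <- diffusivity * tick_s / h_m^2
  if (is.null(cache)) {
    cache <- if (crop) {
      cropped_cache(lattice, conc, halo = ceiling(4.5 * sqrt(2 * fo)))
    } else diffusion_cache(lattice)
    if (is.null(cache)) {          # empty field
      attr(conc, "outflux") <- 0
      return(conc)
    }
  }
  nsub <- max(1L, as.integer(ceiling(8 * fo)))
  alpha <- fo / nsub
  res <- diffuse_sub_cpp(matrix(conc[cache$active], ncol = 1), cache$nbr,
                         alpha, nsub)
  out <- conc
  out[cache$active] <- res$conc[, 1]
  attr(out, "outflux") <- res$outflux[1]
  out
}

# diffuse several same-diffusivity species in one kernel sweep, sharing a
# cropped neighbour table covering their joint support
diffuse_tick_multi <- function(concs, lattice, diffusivity, tick_s = 3600,
                               crop = TRUE) {
  h_m <- lattice$patch_um * 1e-6
  fo <- diffusivity * tick_s / h_m^2
  support <- Reduce(`+`, concs)
  cache <- if (crop) {
    cropped_cache(lattice, support, halo = ceiling(4.5 * sqrt(2 * fo)))
  } else diffusion_cache(lattice)
  if (is.null(cache)) return(concs)
  nsub <- max(1L, as.integer(ceiling(8 * fo)))
  alpha <- fo / nsub
  mat <- vapply(concs, function(cc) cc[cache$active],
                numeric(length(cache$active)))
  res <- diffuse_sub_cpp(mat, cache$nbr, alpha, nsub)
  for (k in seq_along(concs)) {
    concs[[k]][cache$active] <- res$conc[, k]
    attr(concs[[k]], "outflux") <- res$outflux[k]
  }
  concs
}

#' Reference implicit diffusion step (dense Crank-Nicolson)
#'
#' Unconditionally stable dense Crank-Nicolson steps over the tick;
#' intended as an independent numerical cross-check of the sub-stepped
#' explicit scheme on small domains.
#'
#' @inheritParams diffuse_tick
#' @param cache Neighbour table from `make_diffusion_cache()`.
#' @param nsteps Number of implicit sub-steps (improves transient accuracy).
#' @return Concentration array after one tick.
#' @export
diffuse_tick_implicit <- function(conc, lattice, diffusivity, tick_s = 3600,
                                  cache = NULL, nsteps = 1L) {
  if (is.null(cache)) cache <- diffusion_cache(lattice)
  n <- length(cache$active)
  if (n > 5000) stop("dense reference limited to small domains")
  h_m <- if (!is.null(lattice)) lattice$patch_um * 1e-6 else 100e-6
  fo <- diffusivity * (tick_s / nsteps) / h_m^2
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in 1:6) {
      j <- cache$nbr[i, k]
      if (j == i - 1L) next            # sealed face: zero flux
      L[i, i] <- L[i, i] - 1
      if (j < n) L[i, j + 1] <- L[i, j + 1] + 1
      # j == n: sink face, neighbour held at zero
    }
  }
  A <- diag(n) - 0.5 * fo * L
  B <- diag(n) + 0.5 * fo * L
  M <- solve(A, B)                 # one dense factorization, reused
  x <- conc[cache$active]
  for (s in seq_len(nsteps)) x <- M %*% x
  x <- as.numeric(x)
  out <- conc
  out[] <- 0
  out[cache$active] <- x
  out
}

#' Apply the LDL boundary condition at the endothelium
#'
#' Sets the LDL concentration of every EC voxel to the shear-gated
#' wall-surface influx value `0.7 c0 P(wss)` (a Dirichlet boundary imposed
#' before diffusion).
#'
#' @param ldl LDL concentration array.
#' @param wss A `wss_field`.
#' @param c0_blood Luminal LDL concentration (ng/ul).
#' @param literal_cubic Polynomial reading flag, see [ldl_wall_influx()].
#' @return Updated LDL array.
#' @export
apply_ldl_boundary <- function(ldl, wss, c0_blood = 960,
                               literal_cubic = FALSE) {
  ldl[wss$ec_idx] <- ldl_wall_influx(wss$tau, c0_blood,
                                     literal_cubic)$influx
  ldl
}
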