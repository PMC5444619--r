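# Glagov compensatory remodeling: planes whose plaque burden demands new
# tissue volume grow outward while plaque area is below 40% of lumen area,
# and grow 65% inward / 35% outward once the threshold is reached. The
# endothelial shell is re-established after every inward event.

#' Remodeling policy
#'
#' @param glagov_threshold Plaque/lumen area ratio at which inward growth
#'   becomes possible.
#' @param inward_fraction Probability that a growth event above threshold
#'   goes inward (the complement grows outward).
#' @return Object of class `remodeling_policy`.
#' @export
remodeling_policy <- function(glagov_threshold = 0.40,
                              inward_fraction = 0.65) {
  structure(list(glagov_threshold = glagov_threshold,
                 inward_fraction = inward_fraction,
                 outward_fraction = 1 - inward_fraction),
            class = "remodeling_policy")
}

#' Growth demand of one plane
#'
#' Number of new voxels the plane's plaque requires: the accumulated
#' plaque-volume increase since the last remodel event (placed agents plus
#' cells still waiting for space), in capacity-equivalents of one voxel,
#' rounded down. Growth is ratcheted: transient volume loss (cell death)
#' does not shrink the wall.
#'
#' @param state Simulation state environment.
#' @param z Plane index.
#' @return Integer voxel demand.
#' @export
growth_demand <- function(state, z) {
  d <- state$lattice$dims
  v_now <- sum(state$occupied[, , z]) +
    sum(state$pending[z, ] * AGENT_VOLUME_UM3)
  excess <- v_now - state$plane_vol_base[z]
  max(0L, as.integer(floor(excess / voxel_capacity(state$lattice))))
}

# plaque burden around each in-plane position: total agent volume in wall
# voxels within Chebyshev distance 2 (same plane)
plane_burden <- function(state, z) {
  occ <- state$occupied[, , z]
  k <- matrix(1, 5, 5)
  d <- dim(occ)
  out <- matrix(0, d[1], d[2])
  # small 2D box filter via cumulative sums
  cs <- apply(apply(occ, 2, cumsum), 1, cumsum)  # transposed cumsum
  cs <- t(cs)
  pad <- function(i, n) pmin(pmax(i, 0L), n)
  i1 <- pad(seq_len(d[1]) - 3L, d[1]); i2 <- pad(seq_len(d[1]) + 2L, d[1])
  j1 <- pad(seq_len(d[2]) - 3L, d[2]); j2 <- pad(seq_len(d[2]) + 2L, d[2])
  csz <- rbind(0, cbind(0, cs))
  out <- csz[i2 + 1L, j2 + 1L] - csz[i1 + 1L, j2 + 1L] -
    csz[i2 + 1L, j1 + 1L] + csz[i1 + 1L, j1 + 1L]
  out
}

# pick an in-plane voxel from candidates (arr indices) maximizing burden;
# uniform random among ties
pick_by_burden <- function(burden, cand_ij) {
  b <- burden[cand_ij]
  best <- which(b == max(b))
  if (length(best) > 1) best <- sample(best, 1)
  cand_ij[best, , drop = FALSE]
}

# place pending agents of plane z into a newly available wall voxel
settle_pending <- function(state, z, vox) {
  cap <- voxel_capacity(state$lattice)
  occ_v <- state$occupied[vox]
  n_by_type <- integer(length(AGENT_TYPES))
  for (ty in seq_along(AGENT_TYPES)) {
    vol <- AGENT_VOLUME_UM3[ty]
    fit <- min(state$pending[z, ty],
               max(0, floor((cap + 1e-9 - occ_v) / vol)))
    if (fit > 0) {
      n_by_type[ty] <- fit
      occ_v <- occ_v + fit * vol
    }
  }
  n_tot <- sum(n_by_type)
  if (n_tot > 0) {
    state$agents <- agents_add(state$agents,
                               rep(seq_along(AGENT_TYPES), n_by_type), vox)
    state$occupied[vox] <- occ_v
    state$pending[z, ] <- state$pending[z, ] - n_by_type
  }
  invisible(NULL)
}

# one outward growth event: EXTERIOR voxel adjacent to the plane's most
# burdened wall sector becomes WALL
grow_outward <- function(state, z, burden) {
  lat <- state$lattice
  cls <- lat$class[, , z]
  d <- dim(cls)
  wall <- cls == CLASS_WALL
  adj <- matrix(FALSE, d[1], d[2])
  adj[-1, ] <- adj[-1, ] | wall[-d[1], ]
  adj[-d[1], ] <- adj[-d[1], ] | wall[-1, ]
  adj[, -1] <- adj[, -1] | wall[, -d[2]]
  adj[, -d[2]] <- adj[, -d[2]] | wall[, -1]
  cand <- which(cls == CLASS_EXTERIOR & adj, arr.ind = TRUE)
  if (nrow(cand) == 0) stop("lattice margin exhausted during outward growth")
  pick <- pick_by_burden(burden, cand)
  vox <- vox_index(lat, pick[1], pick[2], z)
  state$lattice$class[vox] <- CLASS_WALL
  # outward growth leaves lumen, endothelium and their caches untouched;
  # the diffusion table picks the voxel up at the next scheduled rebuild
  state$grow_stale <- TRUE
  settle_pending(state, z, vox)
  vox
}

# one inward growth event: the lumen voxel in front of the most burdened
# EC patch becomes the new endothelium and the EC patch behind it becomes
# plaque-bearing wall
grow_inward <- function(state, z, burden) {
  lat <- state$lattice
  cls <- lat$class[, , z]
  if (sum(cls == CLASS_LUMEN) <= 1) {
    stop("inward growth would occlude a plane")
  }
  ec <- which(cls == CLASS_EC, arr.ind = TRUE)
  # only EC patches with an in-plane lumen neighbour can protrude
  ok <- vapply(seq_len(nrow(ec)), function(r) {
    i <- ec[r, 1]; j <- ec[r, 2]
    (i > 1 && cls[i - 1, j] == CLASS_LUMEN) ||
      (i < nrow(cls) && cls[i + 1, j] == CLASS_LUMEN) ||
      (j > 1 && cls[i, j - 1] == CLASS_LUMEN) ||
      (j < ncol(cls) && cls[i, j + 1] == CLASS_LUMEN)
  }, TRUE)
  ec <- ec[ok, , drop = FALSE]
  if (nrow(ec) == 0) stop("no endothelial patch can protrude in plane")
  pick <- pick_by_burden(burden, ec)
  i <- pick[1]; j <- pick[2]
  # face-adjacent lumen voxel of the chosen EC patch
  lum <- NULL
  for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    ii <- i + s[1]; jj <- j + s[2]
    if (ii >= 1 && ii <= nrow(cls) && jj >= 1 && jj <= ncol(cls) &&
        cls[ii, jj] == CLASS_LUMEN) {
      lum <- rbind(lum, c(ii, jj))
    }
  }
  if (is.null(lum)) stop("chosen EC patch has no in-plane lumen neighbour")
  r <- if (nrow(lum) > 1) lum[sample(nrow(lum), 1), ] else lum[1, ]
  vox_l <- vox_index(lat, r[1], r[2], z)
  vox_e <- vox_index(lat, i, j, z)
  state$lattice$class[vox_l] <- CLASS_WALL
  state$lattice <- reclassify_shell(state$lattice)
  host <- if (state$lattice$class[vox_e] == CLASS_WALL) vox_e else
    if (state$lattice$class[vox_l] == CLASS_WALL) vox_l else NA_integer_
  if (!is.na(host)) settle_pending(state, z, host)
  vox_l
}

#' One tick of Glagov remodeling
#'
#' For every plane whose pending plaque volume demands new voxels: while
#' plaque area is below the Glagov threshold (40% of lumen area) the plane
#' grows outward; at or above threshold each growth event goes inward with
#' probability 0.65 (new endothelium laid over the protrusion) and outward
#' otherwise.
#'
#' @param state Simulation state environment.
#' @param policy A [remodeling_policy()].
#' @return Invisibly, a data frame of growth events (tick, plane,
#'   direction) or `NULL` when nothing grew.
#' @export
glagov_tick <- function(state, policy = remodeling_policy()) {
  nz <- state$lattice$dims[3]
  events <- list()
  cap <- voxel_capacity(state$lattice)
  for (z in seq_len(nz)) {
    demand <- growth_demand(state, z)
    if (demand == 0) next
    burden <- plane_burden(state, z)
    state$plane_vol_base[z] <- state$plane_vol_base[z] + demand * cap
    for (g in seq_len(demand)) {
      state$lattice$occupied <- state$occupied
      pa <- plane_areas(state$lattice, z)
      ratio <- pa[["plaque"]] / pa[["lumen"]]
      inward <- ratio >= policy$glagov_threshold &&
        stats::runif(1) < policy$inward_fraction
      vox <- if (inward) grow_inward(state, z, burden)
             else grow_outward(state, z, burden)
      events[[length(events) + 1]] <-
        data.frame(tick = state$tick, plane = z,
                   direction = if (inward) "inward" else "outward",
                   vox = vox)
    }
  }
  if (length(events) == 0) return(invisible(NULL))
  invisible(do.call(rbind, events))
}
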