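# Leukocytes inside the artery wall: placement of transmigrated cohorts,
# space-constrained chemotaxis, monocyte differentiation (M1:M2 = 2:1),
# foam-cell formation above the oxLDL threshold, aging and death.

#' Empty agent population
#'
#' Agents are stored column-wise: integer `type` (index into
#' [AGENT_TYPES]), linear voxel index `vox`, and `age` in ticks.
#'
#' @return An `agent_set`.
#' @export
agents_new <- function() {
  structure(list(type = integer(0), vox = integer(0), age = integer(0)),
            class = "agent_set")
}

agents_add <- function(agents, type, vox, age = 0L) {
  agents$type <- c(agents$type, as.integer(type))
  agents$vox <- c(agents$vox, rep_len(as.integer(vox), length(type)))
  agents$age <- c(agents$age, rep_len(as.integer(age), length(type)))
  agents
}

agents_count <- function(agents) length(agents$type)

#' Census of agents by type
#' @param agents An `agent_set`.
#' @return Named integer vector over [AGENT_TYPES].
#' @export
agents_census <- function(agents) {
  stats::setNames(tabulate(agents$type, nbins = length(AGENT_TYPES)),
                  AGENT_TYPES)
}

agent_volumes <- function(agents) AGENT_VOLUME_UM3[agents$type]

# recompute occupied-volume array from scratch (audit / reset)
recount_occupied <- function(lattice, agents) {
  occ <- array(0, dim = lattice$dims)
  if (agents_count(agents) > 0) {
    s <- rowsum(agent_volumes(agents), agents$vox)
    occ[as.integer(rownames(s))] <- s[, 1]
  }
  occ
}

# face-adjacent wall voxels of an EC voxel (linear indices)
wall_neighbors <- function(lattice, ec_vox) {
  d <- lattice$dims
  co <- vox_coords(lattice, ec_vox)
  out <- integer(0)
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    i <- co[1] + s[1]; j <- co[2] + s[2]; k <- co[3] + s[3]
    if (i < 1 || i > d[1] || j < 1 || j > d[2] || k < 1 || k > d[3]) next
    v <- vox_index(lattice, i, j, k)
    if (lattice$class[v] == CLASS_WALL) out <- c(out, v)
  }
  out
}

#' Place a cohort of transmigrated leukocytes entering at one EC patch
#'
#' The first cell picks, among the wall voxels adjacent to the entry patch
#' with free capacity, the one with the highest chemoattractant (ties
#' broken at random); subsequent cells of the cohort reuse that destination
#' until its capacity fills, then fall back to individual selection. Cells
#' that find no space anywhere adjacent join the plane's pending pool,
#' which drives compensatory growth. Monocytes differentiate to M1 (2/3)
#' or M2 (1/3) at the moment of entry.
#'
#' @param state Simulation state environment.
#' @param ec_vox Entry EC voxel (linear index).
#' @param counts Length-3 vector of transmigration counts by leukocyte
#'   type (`NEUTROPHIL`, `MONOCYTE`, `LYMPHOCYTE`).
#' @return Invisibly, the number of cells placed (rest went pending).
#' @export
place_cohort <- function(state, ec_vox, counts) {
  place_cohorts(state, list(ec_vox), matrix(counts, 1))
}

# batched cohort placement for one tick: a single occupancy copy and a
# single agent append, however many cohorts arrive
place_cohorts <- function(state, ec_list, counts_mat) {
  lat <- state$lattice
  cap <- voxel_capacity(lat)
  attract <- state$attract
  occ <- state$occupied
  pending <- state$pending
  new_type <- integer(0)
  new_vox <- integer(0)
  placed <- 0L
  for (ci in seq_along(ec_list)) {
    ec_vox <- ec_list[[ci]]
    cands <- wall_neighbors(lat, ec_vox)
    plane <- vox_plane(lat, ec_vox)
    types <- rep(1:3, times = counts_mat[ci, ])
    # monocytes become macrophages on entry: 2:1 M1:M2
    is_mono <- types == 2L
    if (any(is_mono)) {
      m1 <- stats::runif(sum(is_mono)) < 2 / 3
      types[is_mono] <- ifelse(m1, 4L, 5L)
    }
    shared <- NA_integer_
    for (ty in types) {
      vol <- AGENT_VOLUME_UM3[[ty]]
      dest <- NA_integer_
      if (!is.na(shared) && occ[shared] + vol <= cap + 1e-9) {
        dest <- shared
      } else if (length(cands) > 0) {
        free <- occ[cands] + vol <= cap + 1e-9
        if (any(free)) {
          ok <- cands[free]
          a <- attract[ok]
          best <- ok[a == max(a)]
          dest <- if (length(best) == 1) best else sample(best, 1)
          if (is.na(shared)) shared <- dest
        }
      }
      if (is.na(dest)) {
        pending[plane, ty] <- pending[plane, ty] + 1L
      } else {
        new_type <- c(new_type, ty)
        new_vox <- c(new_vox, dest)
        occ[dest] <- occ[dest] + vol
        placed <- placed + 1L
      }
    }
  }
  if (placed > 0) {
    state$agents <- agents_add(state$agents, new_type, new_vox)
  }
  state$occupied <- occ
  state$pending <- pending
  invisible(placed)
}

#' One chemotaxis step for all mobile wall agents
#'
#' Every non-foam agent surveys its 26-connected neighbourhood and moves to
#' the wall voxel with free capacity and the strictly highest
#' pro-inflammatory chemoattractant (TNF-alpha + IL-1beta); agents at a
#' local maximum, or walled in by full neighbours, stay put. Processing
#' order is randomized each tick.
#'
#' @param state Simulation state environment.
#' @return Invisibly, `NULL`.
#' @export
chemotaxis_tick <- function(state) {
  ag <- state$agents
  n <- agents_count(ag)
  if (n == 0) return(invisible(NULL))
  mobile <- which(ag$type != 6L)
  if (length(mobile) == 0) return(invisible(NULL))
  ord <- sample.int(length(mobile)) - 1L
  res <- chemotaxis_step_cpp(ag$vox[mobile], AGENT_VOLUME_UM3[ag$type[mobile]],
                             ord, state$occupied,
                             as.integer(state$lattice$class),
                             state$attract, state$lattice$dims,
                             voxel_capacity(state$lattice))
  state$agents$vox[mobile] <- res$vox
  state$occupied <- array(res$occupied, dim = state$lattice$dims)
  invisible(NULL)
}

#' Foam-cell formation
#'
#' M1 and M2 macrophages sitting in a voxel whose oxidized-LDL
#' concentration exceeds 100 ug/ml become foam cells (volume grows to the
#' 25 um sphere; the conversion is irreversible and foam cells are
#' immobile and persistent).
#'
#' @param state Simulation state environment.
#' @return Invisibly, the number of conversions.
#' @export
differentiate_agents <- function(state) {
  ag <- state$agents
  mac <- which(ag$type %in% c(4L, 5L))
  if (length(mac) == 0) return(invisible(0L))
  cand <- mac[state$fields$OXLDL[ag$vox[mac]] > 100]
  if (length(cand) == 0) return(invisible(0L))
  # conversion swells the cell; defer conversions that would overfill the
  # voxel until space frees up
  cap <- voxel_capacity(state$lattice)
  occ <- state$occupied
  nconv <- 0L
  for (a in cand) {
    v <- ag$vox[a]
    dv <- AGENT_VOLUME_UM3[["FOAM"]] - AGENT_VOLUME_UM3[ag$type[a]]
    if (occ[v] + dv <= cap + 1e-9) {
      state$agents$type[a] <- 6L
      occ[v] <- occ[v] + dv
      nconv <- nconv + 1L
    }
  }
  state$occupied <- occ
  invisible(nconv)
}

#' Aging and death
#'
#' Ages increment by one tick; neutrophils die beyond 72 ticks, monocyte
#' lineage (M1/M2) and lymphocytes beyond 168; foam cells persist. Removed
#' agents free their voxel volume.
#'
#' @param state Simulation state environment.
#' @return Invisibly, the number of deaths.
#' @export
age_and_die <- function(state) {
  ag <- state$agents
  if (agents_count(ag) == 0) return(invisible(0L))
  age <- ag$age + 1L
  keep <- age <= AGENT_LIFESPAN_TICKS[ag$type]
  ndead <- sum(!keep)
  if (ndead > 0) {
    dead_vol <- rowsum(AGENT_VOLUME_UM3[ag$type[!keep]], ag$vox[!keep])
    idx <- as.integer(rownames(dead_vol))
    state$occupied[idx] <- pmax(0, state$occupied[idx] - dead_vol[, 1])
  }
  state$agents <- structure(list(type = ag$type[keep], vox = ag$vox[keep],
                                 age = age[keep]), class = "agent_set")
  invisible(ndead)
}
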