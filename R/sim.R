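# Simulation driver: configuration, named RNG streams, the per-tick update
# order (transport -> recruitment/TEM -> chemotaxis -> differentiation and
# death -> remodeling -> conditional WSS update), experiment presets and
# run outputs.

#' Simulation configuration
#'
#' All rule constants default to the model's published values; overrides
#' are recorded in the run manifest.
#'
#' @param geometry A [geometry_spec()].
#' @param duration_ticks Number of 1-hour ticks to run.
#' @param capacity_fraction 0.40 for the standard model, 0.04 for
#'   accelerated growth-and-remodeling runs.
#' @param seed Master seed; every module stream derives from it.
#' @param wss_backend `"axisym"`, `"poiseuille"` or `"imported"`.
#' @param wss_policy `"peak_systole"`, `"steady_mean"` or `"full_cycle"`.
#' @param handshake `"per_lumen_change"` or `"accelerated"`.
#' @param handshake_quota Lumen-patch quota for accelerated handshakes.
#' @param cycle_stride Under the `full_cycle` policy, keep every
#'   `cycle_stride`-th waveform sample for the per-tick cycle-averaged
#'   recruitment (1 = all 80 samples).
#' @param waveform A [flow_waveform()].
#' @param recruitment A [recruitment_config()].
#' @param remodeling A [remodeling_policy()].
#' @param c0_ldl Luminal LDL concentration (ng/ul).
#' @param insult Number of leukocytes seeded mid-wall at tick 0 (0 for
#'   none); composed per blood proportions.
#' @param plaque Optional list(center_um, radius_um) spherical plaque
#'   fixture inserted (and seeded with foam cells) before the run.
#' @param extended_producers Macrophages/foam produce cytokines (see
#'   [produce_cytokines()]).
#' @param audit_every Reconcile occupancy against a from-scratch recount
#'   every this many ticks (0 disables).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(geometry = geometry_spec(),
                              duration_ticks = 24L,
                              capacity_fraction = 0.40,
                              seed = 1L,
                              wss_backend = "axisym",
                              wss_policy = "peak_systole",
                              handshake = "per_lumen_change",
                              handshake_quota = 80L,
                              cycle_stride = 8L,
                              waveform = default_waveform(),
                              recruitment = recruitment_config(),
                              remodeling = remodeling_policy(),
                              c0_ldl = 960,
                              insult = 0L,
                              plaque = NULL,
                              extended_producers = TRUE,
                              audit_every = 24L) {
  structure(as.list(environment()), class = "simulation_config")
}

# named RNG streams derived from one master seed
init_streams <- function(seed, names = c("recruitment", "chemotaxis",
                                         "differentiation", "remodeling",
                                         "misc")) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  streams <- list()
  for (k in seq_along(names)) {
    set.seed((as.integer(seed) * 97L + k * 1009L) %% .Machine$integer.max)
    streams[[names[k]]] <- get(".Random.seed", .GlobalEnv)
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  streams
}

with_stream <- function(state, name, expr) {
  assign(".Random.seed", state$streams[[name]], .GlobalEnv)
  on.exit(state$streams[[name]] <- get(".Random.seed", .GlobalEnv))
  expr
}

#' Initialize a simulation state
#'
#' Builds the lattice, inserts the optional plaque fixture (wall voxels
#' inside the sphere are filled to capacity with foam cells), seeds the
#' optional mid-wall leukocyte insult, zeroes the species fields and sets
#' the healthy uniform 1.4 Pa shear field.
#'
#' @param config A [simulation_config()].
#' @return A simulation state (environment).
#' @export
init_state <- function(config) {
  state <- new.env(parent = emptyenv())
  state$config <- config
  state$lattice <- build_artery(config$geometry,
                                capacity_fraction = config$capacity_fraction)
  state$streams <- init_streams(config$seed)
  state$agents <- agents_new()
  state$occupied <- array(0, dim = state$lattice$dims)
  state$fields <- species_fields(state$lattice)
  state$pending <- matrix(0L, state$lattice$dims[3], length(AGENT_TYPES))
  state$tick <- 0L
  state$tem_log <- list()
  state$census <- list()
  state$remodel_log <- list()
  state$solver_cache <- new.env(parent = emptyenv())
  state$ldl_steady <- FALSE
  state$ldl_prev <- NULL

  if (!is.null(config$plaque)) {
    state$lattice <- insert_spherical_plaque(state$lattice,
                                             config$plaque$center_um,
                                             config$plaque$radius_um)
    pv <- attr(state$lattice, "plaque_voxels")
    cap <- voxel_capacity(state$lattice)
    nfoam <- floor(cap / AGENT_VOLUME_UM3[["FOAM"]])
    if (length(pv) > 0 && nfoam > 0) {
      vox <- rep(pv, each = nfoam)
      state$agents <- agents_add(state$agents, rep(6L, length(vox)), vox)
      state$occupied[pv] <- nfoam * AGENT_VOLUME_UM3[["FOAM"]]
    }
  }
  if (config$insult > 0) {
    state <- seed_insult(state, config$insult)
  }
  state$wss <- healthy_wss(state$lattice)
  state$wss_cycle <- NULL
  nz <- state$lattice$dims[3]
  state$plane_vol_base <- vapply(seq_len(nz), function(z) {
    sum(state$occupied[, , z])
  }, 0)
  state$lumen_at_update <- lumen_volume(state$lattice)
  state$lumen_initial <- state$lumen_at_update
  state$cum_lumen_change <- 0L
  state$attract <- state$fields$TNFA + state$fields$IL1B
  state
}

# place the initial insult mid-wall, composed per the configured blood
# proportions (so lineage knockouts also remove the lineage's insult seed)
seed_insult <- function(state, n = 15L) {
  conc <- state$config$recruitment$blood_conc
  props <- conc / sum(conc)
  counts <- round(props * n)
  counts[1] <- n - sum(counts[-1])
  lat <- state$lattice
  d <- lat$dims
  # mid-wall voxel at theta = 0, z = middle
  r_mid <- lat$lumen_radius_um + lat$patch_um + lat$wall_thickness_um / 2
  i <- round(lat$axis_um[1] / lat$patch_um + r_mid / lat$patch_um + 0.5)
  vox <- vox_index(lat, i, round(d[2] / 2), round(d[3] / 2))
  stopifnot(lat$class[vox] == CLASS_WALL)
  types <- rep(c(1L, 4L, 3L), times = counts)  # monocytes enter as M1
  # spread across the voxel and its wall neighbours to respect capacity
  cap <- voxel_capacity(lat)
  co <- vox_coords(lat, vox)
  cands <- vox
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    v <- vox_index(lat, co[1] + dx, co[2] + dy, co[3] + dz)
    if (lat$class[v] == CLASS_WALL && v != vox) cands <- c(cands, v)
  }
  ci <- 1
  for (ty in types) {
    while (state$occupied[cands[ci]] + AGENT_VOLUME_UM3[ty] > cap &&
           ci < length(cands)) ci <- ci + 1
    state$agents <- agents_add(state$agents, ty, cands[ci])
    state$occupied[cands[ci]] <- state$occupied[cands[ci]] +
      AGENT_VOLUME_UM3[ty]
  }
  state
}

# flow rate for the configured policy phase
policy_flow <- function(config) {
  plan <- select_wss_policy(config$waveform, config$wss_policy)
  plan$q_m3s[1]
}

# recompute the WSS field(s) at the configured policy
update_wss <- function(state) {
  cfg <- state$config
  if (cfg$wss_policy == "full_cycle") {
    s <- cfg$waveform$samples
    keep <- seq(1, nrow(s), by = cfg$cycle_stride)
    state$wss_cycle <- lapply(keep, function(i) {
      estimate_wss(state$lattice, s$q_m3s[i], backend = cfg$wss_backend,
                   cache = state$solver_cache, phase = s$t_s[i])
    })
    avg <- state$wss_cycle[[1]]
    avg$tau <- Reduce(`+`, lapply(state$wss_cycle, `[[`, "tau")) /
      length(state$wss_cycle)
    avg$tau_z <- Reduce(`+`, lapply(state$wss_cycle, `[[`, "tau_z")) /
      length(state$wss_cycle)
    avg$phase <- "cycle_mean"
    state$wss <- avg
  } else {
    state$wss_cycle <- NULL
    state$wss <- estimate_wss(state$lattice, policy_flow(cfg),
                              backend = cfg$wss_backend,
                              cache = state$solver_cache,
                              phase = cfg$wss_policy)
  }
  state$lumen_at_update <- lumen_volume(state$lattice)
  state$ldl_steady <- FALSE
  invisible(state)
}

# remap stale fields onto a changed EC shell using per-plane means
remap_wss <- function(state) {
  lat <- state$lattice
  ec <- ec_indices(lat)
  remap1 <- function(w) {
    w$tau <- pmax(map_tau_to_ec(lat, w$tau_z), 0)
    w$ec_idx <- ec
    w
  }
  state$wss <- remap1(state$wss)
  if (!is.null(state$wss_cycle)) {
    state$wss_cycle <- lapply(state$wss_cycle, remap1)
  }
  invisible(state)
}

# one tick of soluble-species transport: production, boundary LDL,
# diffusion, IL-10 clearance, oxidation
transport_tick <- function(state) {
  cfg <- state$config
  ag <- state$agents
  f <- state$fields
  if (agents_count(ag) > 0) {
    uvox <- sort(unique(ag$vox))
    cnt <- function(tt) {
      sel <- ag$type %in% tt
      if (!any(sel)) return(numeric(length(uvox)))
      tabulate(match(ag$vox[sel], uvox), nbins = length(uvox))
    }
    counts <- list(NEUTROPHIL = cnt(1L), MONOCYTE = cnt(2L),
                   LYMPHOCYTE = cnt(3L), M1 = cnt(4L), M2 = cnt(5L),
                   FOAM = cnt(6L))
    inc <- produce_cytokines(counts, extended = cfg$extended_producers)
    for (s in c("TNFA", "IL1B", "IL10")) {
      if (any(inc[[s]] != 0)) f[[s]][uvox] <- f[[s]][uvox] + inc[[s]]
    }
  }
  sp <- species_params()
  cyt <- c("TNFA", "IL1B", "IL10")
  live <- cyt[vapply(cyt, function(s) any(f[[s]] > 0), TRUE)]
  if (length(live) > 0) {
    f[live] <- diffuse_tick_multi(f[live], state$lattice,
                                  sp$diffusivity[["TNFA"]])
  }
  if (!state$ldl_steady) {
    f$LDL <- apply_ldl_boundary(f$LDL, state$wss, cfg$c0_ldl)
    f$LDL <- diffuse_tick(f$LDL, state$lattice, sp$diffusivity[["LDL"]],
                          crop = TRUE)
  }
  cl <- il10_clearance(f$TNFA, f$IL1B, f$IL10)
  f$TNFA <- cl$TNFA; f$IL1B <- cl$IL1B
  ox <- oxidize_ldl(f$LDL, f$OXLDL)
  if (!state$ldl_steady) {
    f$LDL <- ox$LDL
    if (!is.null(state$ldl_prev)) {
      dmax <- max(abs(f$LDL - state$ldl_prev))
      ref <- max(f$LDL, 1e-12)
      if (dmax / ref < 1e-6) state$ldl_steady <- TRUE
    }
    state$ldl_prev <- f$LDL
  }
  f$OXLDL <- ox$OXLDL
  state$fields <- f
  state$attract <- f$TNFA + f$IL1B
  invisible(state)
}

# recruitment, transmigration and cohort placement
recruitment_tick <- function(state) {
  cfg <- state$config
  wss_in <- if (!is.null(state$wss_cycle)) state$wss_cycle else state$wss
  rec <- with_stream(state, "recruitment",
                     sample_recruitment(state$lattice, wss_in,
                                        state$fields, cfg$recruitment,
                                        occupied = state$occupied))
  hot <- which(rowSums(rec$tem) > 0)
  if (length(hot) > 0) {
    with_stream(state, "recruitment",
                place_cohorts(state, as.list(rec$ec_idx[hot]),
                              rec$tem[hot, , drop = FALSE]))
    state$tem_log[[length(state$tem_log) + 1]] <- data.frame(
      tick = state$tick, ec_vox = rec$ec_idx[hot],
      NEUTROPHIL = rec$tem[hot, 1], MONOCYTE = rec$tem[hot, 2],
      LYMPHOCYTE = rec$tem[hot, 3],
      wss = state$wss$tau[hot])
  }
  state$tem_this_tick <- sum(rec$tem)
  invisible(state)
}

#' Advance the simulation by one tick
#'
#' Applies the fixed within-tick order: transport, recruitment and
#' transmigration, chemotaxis, differentiation and death, remodeling, and
#' the conditional WSS handshake.
#'
#' @param state Simulation state environment.
#' @return The state, invisibly.
#' @export
step_tick <- function(state) {
  state$tick <- state$tick + 1L
  cfg <- state$config
  transport_tick(state)
  recruitment_tick(state)
  with_stream(state, "chemotaxis", chemotaxis_tick(state))
  differentiate_agents(state)
  age_and_die(state)
  ev <- with_stream(state, "remodeling",
                    glagov_tick(state, cfg$remodeling))
  if (!is.null(ev)) {
    state$remodel_log[[length(state$remodel_log) + 1]] <- ev
    if (any(ev$direction == "inward")) {
      state$grow_stale <- FALSE          # full invalidation already done
      remap_wss(state)
    }
  }
  if (isTRUE(state$grow_stale) && state$tick %% 12L == 0L) {
    state$lattice <- invalidate_cache(state$lattice)
    state$grow_stale <- FALSE
  }
  lum <- lumen_volume(state$lattice)
  state$cum_lumen_change <- abs(lum - state$lumen_initial)
  if (handshake_schedule(cfg$handshake, lum, state$lumen_at_update,
                         cfg$handshake_quota)) {
    update_wss(state)
  }
  cen <- agents_census(state$agents)
  state$census[[length(state$census) + 1]] <-
    c(tick = state$tick, cen, tem = state$tem_this_tick,
      lumen = lum, pending = sum(state$pending))
  if (cfg$audit_every > 0 && state$tick %% cfg$audit_every == 0) {
    audit_state(state)
  }
  invisible(state)
}

# conservation audit: occupancy bookkeeping must match a recount
audit_state <- function(state) {
  occ2 <- recount_occupied(state$lattice, state$agents)
  if (max(abs(occ2 - state$occupied)) > 1e-6) {
    stop("occupancy bookkeeping diverged from recount")
  }
  cap <- voxel_capacity(state$lattice)
  if (any(state$occupied > cap + 1e-6)) {
    stop("voxel capacity exceeded")
  }
  if (any(state$occupied > 0 &
          state$lattice$class != CLASS_WALL)) {
    stop("agents outside wall voxels")
  }
  invisible(TRUE)
}

#' Run a configured simulation
#'
#' @param config A [simulation_config()].
#' @param state Optional pre-initialized state (continues it).
#' @return The final state; per-tick census available via
#'   [census_table()].
#' @export
run_simulation <- function(config, state = NULL) {
  if (is.null(state)) state <- init_state(config)
  for (t in seq_len(config$duration_ticks)) step_tick(state)
  state
}

#' Per-tick census as a data frame
#' @param state Simulation state.
#' @return Data frame with tick, per-type counts, TEM events, lumen volume.
#' @export
census_table <- function(state) {
  as.data.frame(do.call(rbind, state$census))
}

#' Transmigration event log as a data frame
#' @param state Simulation state.
#' @return Data frame of TEM events (may have zero rows).
#' @export
tem_table <- function(state) {
  if (length(state$tem_log) == 0) {
    return(data.frame(tick = integer(0), ec_vox = integer(0),
                      NEUTROPHIL = integer(0), MONOCYTE = integer(0),
                      LYMPHOCYTE = integer(0), wss = numeric(0)))
  }
  do.call(rbind, state$tem_log)
}
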