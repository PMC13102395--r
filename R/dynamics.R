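# Langevin dynamics and the ATP-cycle scheduler.
#
# Integrator: BAOAB splitting (velocity Verlet with exact Ornstein-Uhlenbeck
# noise). Units: time in the intrinsic unit tau = sqrt(amu A^2 / kcal/mol);
# the step size is dimensionless and defaults to 0.2.

#' Langevin dynamics parameters
#'
#' @param dt Time step (tau, default 0.2).
#' @param temperature Temperature (K, default 300).
#' @param gamma Friction coefficient (1/tau per bead, default 0.02).
#' @param mass Bead mass (amu); scalar (uniform) or per-bead vector.
#' @param seed Integer seed for the counter-derived per-segment RNG streams.
#' @param stride Store a frame every `stride` steps (`NULL`: pick ~200 frames
#'   per segment).
#' @return An object of class `dynamics_params`.
#' @export
dynamics_params <- function(dt = 0.2, temperature = 300, gamma = 0.02,
                            mass = 50, seed = 1L, stride = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  structure(list(dt = dt, temperature = temperature, gamma = gamma,
                 mass = mass, seed = as.integer(seed), stride = stride),
            class = "dynamics_params")
}

#' ATP-cycle schedule
#'
#' The default cycle is disengaged -> engaged -> V-shape -> disengaged, each
#' state lasting 5e7 MD steps; `scale` shrinks every segment proportionally
#' for desk-scale runs (analysis windows scale with it automatically).
#'
#' @param scale Global multiplier on all segment lengths.
#' @param steps_per_state Steps per state before scaling.
#' @return A data frame of class `smc_schedule` with columns `state`,
#'   `n_steps`, `phase`.
#' @export
atp_cycle_schedule <- function(scale = 1, steps_per_state = 5e7) {
  sched <- data.frame(
    state = c("disengaged", "engaged", "vshape", "disengaged"),
    n_steps = round(scale * steps_per_state),
    phase = c("initial", "mid", "mid", "final"),
    stringsAsFactors = FALSE
  )
  class(sched) <- c("smc_schedule", "data.frame")
  attr(sched, "scale") <- scale
  sched
}

#' Arbitrary state schedule
#' @param states Character vector of state labels.
#' @param n_steps Steps per segment (recycled).
#' @param phases Translocation phases per segment (recycled;
#'   "initial"/"mid"/"final").
#' @return An `smc_schedule`.
#' @export
state_schedule <- function(states, n_steps, phases = "mid") {
  if (!length(states)) stop("schedule must contain at least one segment")
  if (any(n_steps <= 0)) stop("n_steps must be positive")
  sched <- data.frame(state = states,
                      n_steps = rep_len(round(n_steps), length(states)),
                      phase = rep_len(phases, length(states)),
                      stringsAsFactors = FALSE)
  class(sched) <- c("smc_schedule", "data.frame")
  sched
}

maxwell_velocities <- function(n, mass, temperature, seed) {
  m <- rep_len(mass, n)
  with_seed(seed, matrix(stats::rnorm(3 * n), n, 3) *
              sqrt(kBT(temperature) / m))
}

# Low-level segment runner on a resolved potential (internal format).
langevin_segment <- function(pot, coords, vel, n_steps, params, stride,
                             seed, store_initial = FALSE) {
  mass <- rep_len(params$mass, pot$n)
  cg_run_cpp(coords, vel, pot, as.integer(n_steps), params$dt, params$gamma,
             mass, kBT(params$temperature), as.double(seed),
             as.integer(stride), store_initial)
}

#' Advance a configuration by Langevin dynamics under a fixed potential
#'
#' One (or a few) underdamped BAOAB updates; deterministic given the seed.
#' This is the low-level single-state integrator; [run_schedule()] drives it
#' through the ATP cycle.
#'
#' @param system An `smc_system`.
#' @param coords,vel Current coordinates and velocities (n x 3).
#' @param state A [make_state_potential()] or state name.
#' @param params [dynamics_params()].
#' @param n_steps Number of steps (default 1).
#' @param ff,hb_model Force-field parameters and hydrogen-bond model.
#' @param seed RNG seed for the noise stream.
#' @return List with `coords`, `vel`, `mean_ke_per_dof`.
#' @export
step_langevin <- function(system, coords, vel, state = "disengaged",
                          params = dynamics_params(), n_steps = 1,
                          ff = ff_params(), hb_model = NULL,
                          seed = params$seed) {
  if (any(!is.finite(coords)) || any(!is.finite(vel))) {
    stop("coordinates and velocities must be finite")
  }
  if (is.character(state)) state <- make_state_potential(state)
  pot <- resolve_potential(system, state, ff, hb_model)
  res <- langevin_segment(pot, coords, vel, n_steps, params,
                          stride = max(n_steps, 1), seed = seed)
  if (res$blown) {
    stop(sprintf("dynamics blow-up at step %d (non-finite state)",
                 res$blow_step))
  }
  list(coords = res$coords, vel = res$vel,
       mean_ke_per_dof = res$mean_ke_per_dof)
}

#' Run an ATP-cycle schedule
#'
#' Integrates the system through the ordered state segments, switching the
#' potential instantaneously at segment boundaries (velocities untouched) and
#' storing frames and per-frame energy breakdowns.
#'
#' @param system An `smc_system`.
#' @param schedule An [atp_cycle_schedule()] or [state_schedule()].
#' @param params [dynamics_params()].
#' @param ff [ff_params()].
#' @param hb_model Optional [hbond_model()] used in hydrogen-bonding states.
#' @param coords,vel Optional initial conditions (default: system coordinates
#'   and Maxwell-Boltzmann velocities from the seed).
#' @param energies Compute per-frame energy breakdowns (default TRUE).
#' @return An object of class `smc_run`.
#' @export
run_schedule <- function(system, schedule, params = dynamics_params(),
                         ff = ff_params(), hb_model = NULL, coords = NULL,
                         vel = NULL, energies = TRUE) {
  if (!nrow(schedule)) stop("schedule must contain at least one segment")
  x <- coords %||% system$coords
  v <- vel %||% maxwell_velocities(nrow(x), params$mass, params$temperature,
                                   child_seed(params$seed, 0))
  frames <- list(); fsteps <- list(); fseg <- list(); ebd <- list()
  ke <- numeric(nrow(schedule))
  seg_start <- cumsum(c(0, schedule$n_steps))[seq_len(nrow(schedule))]
  blown <- FALSE; blow_info <- NULL
  for (s in seq_len(nrow(schedule))) {
    stride <- params$stride %||% max(1, floor(schedule$n_steps[s] / 50))
    sp <- make_state_potential(schedule$state[s], schedule$phase[s])
    pot <- resolve_potential(system, sp, ff, hb_model)
    res <- langevin_segment(pot, x, v, schedule$n_steps[s], params, stride,
                            seed = child_seed(params$seed, s),
                            store_initial = (s == 1))
    nf <- res$n_frames
    fr <- res$frames
    if (nf > 0) {
      fr <- fr[, , seq_len(nf), drop = FALSE]
      frames[[s]] <- fr
      fsteps[[s]] <- res$frame_steps + seg_start[s]
      fseg[[s]] <- rep(s, nf)
      if (energies) {
        ebd[[s]] <- do.call(rbind, lapply(seq_len(nf), function(k) {
          as.data.frame(cg_energy_cpp(fr[, , k], pot))
        }))
      }
    }
    ke[s] <- res$mean_ke_per_dof
    x <- res$coords; v <- res$vel
    if (res$blown) {
      blown <- TRUE
      blow_info <- list(segment = s, step = res$blow_step)
      warning(sprintf("blow-up in segment %d at step %d; returning partial run",
                      s, res$blow_step))
      break
    }
  }
  frames <- if (length(frames)) {
    arr <- array(NA_real_, c(nrow(x), 3, sum(vapply(frames, function(f)
      dim(f)[3], numeric(1)))))
    k <- 0
    for (f in frames) {
      arr[, , k + seq_len(dim(f)[3])] <- f
      k <- k + dim(f)[3]
    }
    arr
  } else NULL
  seg <- schedule
  seg$start_step <- seg_start
  seg$end_step <- seg_start + schedule$n_steps
  en <- if (energies && length(ebd)) do.call(rbind, ebd) else NULL
  structure(list(system = system, schedule = seg, params = params, ff = ff,
                 hb_model = hb_model,
                 frames = frames, frame_steps = unlist(fsteps),
                 frame_segment = unlist(fseg), energies = en,
                 mean_ke_per_dof = ke,
                 final = list(coords = x, vel = v),
                 seed = params$seed, blown = blown, blow_info = blow_info),
            class = "smc_run")
}

#' Number of stored frames
#' @param run An `smc_run`.
#' @return Integer frame count.
#' @export
n_frames <- function(run) if (is.null(run$frames)) 0L else dim(run$frames)[3]

#' Extract a stored frame
#' @param run An `smc_run`.
#' @param k Frame index.
#' @return n x 3 coordinate matrix.
#' @export
frame_coords <- function(run, k) run$frames[, , k]

#' Snapshot at the end of a segment
#' @param run An `smc_run`.
#' @param segment Segment index (default: last completed).
#' @return List with `coords`, `vel`, `system`, `segment`.
#' @export
snapshot <- function(run, segment = nrow(run$schedule)) {
  if (segment == nrow(run$schedule) || is.null(run$frames)) {
    return(list(coords = run$final$coords, vel = run$final$vel,
                system = run$system, segment = segment))
  }
  idx <- which(run$frame_segment == segment)
  if (!length(idx)) stop("no frames stored for segment ", segment)
  list(coords = run$frames[, , max(idx)], vel = run$final$vel,
       system = run$system, segment = segment)
}

#' Branch independent replica continuations from a snapshot
#'
#' Runs `length(seeds)` continuations of the given snapshot that differ only
#' in their random-noise stream, emulating the replication strategy in which
#' the trajectory tree widens at the V-shape and final disengaged states.
#'
#' @param snap A [snapshot()].
#' @param schedule Continuation schedule ([state_schedule()]).
#' @param seeds Integer vector of distinct seeds, one per replica.
#' @param params,ff,hb_model As in [run_schedule()].
#' @return List of `smc_run` objects; each carries `parent` metadata.
#' @export
branch_runs <- function(snap, schedule, seeds, params = dynamics_params(),
                        ff = ff_params(), hb_model = NULL) {
  if (anyDuplicated(seeds)) stop("duplicate seeds are not allowed")
  lapply(seeds, function(sd) {
    p <- params
    p$seed <- as.integer(sd)
    r <- run_schedule(snap$system, schedule, p, ff, hb_model,
                      coords = snap$coords, vel = snap$vel)
    r$parent <- list(segment = snap$segment, seed = params$seed)
    r
  })
}

#' @export
print.smc_run <- function(x, ...) {
  cat("smc_run:", nrow(x$schedule), "segment(s) [",
      paste(x$schedule$state, collapse = " -> "), "],",
      n_frames(x), "stored frames, seed", x$seed,
      if (x$blown) "(BLOWN UP)" else "", "\n")
  invisible(x)
}
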