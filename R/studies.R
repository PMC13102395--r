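# Desk-scale study drivers: the miniaturized translocation campaign and the
# property studies (structure-based stability, switching response, zipping
# order, kleisin-path asymmetry). These fix the study conditions -- system
# sizes, schedules, salt -- in one place so tests and the acceptance script
# run exactly the same computations.

#' Miniaturized DNA-translocation campaign
#'
#' Runs independent ATP-cycle trajectories of a small SMC-kleisin complex
#' (20-bead arms) threaded on 250-bp DNA at 300 mM salt with the schedule
#' scaled by 1e-3 (5e4 steps per state), then classifies each outcome.
#'
#' @param n_seeds Number of independent cycles.
#' @param seed Master seed; run seeds derive from it.
#' @param beads_per_arm Arm size of the toy complex.
#' @param n_bp DNA length (bp).
#' @param schedule_scale Schedule scale factor.
#' @param ionic_strength_mM Salt (mM).
#' @param dh_cutoff Electrostatics cutoff used for the campaign (A).
#' @param progress Print per-run outcomes.
#' @return List with `reports` (one `translocation_report` per run) and
#'   `summary` (counts, step/loop statistics, unidirectionality).
#' @export
mini_translocation_campaign <- function(n_seeds = 20, seed = 1,
                                        beads_per_arm = 20, n_bp = 250,
                                        schedule_scale = 1e-3,
                                        ionic_strength_mM = 300,
                                        dh_cutoff = 15, progress = FALSE) {
  cx <- build_toy_complex(complex_spec(beads_per_arm = beads_per_arm,
                                       seed = seed))
  dna <- build_dna(n_bp = n_bp, seed = child_seed(seed, 999))
  sys <- thread_dna(cx, dna, round(n_bp / 2))
  ff <- ff_params(ionic_strength_mM = ionic_strength_mM,
                  dh_cutoff = dh_cutoff)
  hb <- hbond_model()
  sched <- atp_cycle_schedule(schedule_scale)
  reports <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    run <- suppressWarnings(
      run_schedule(sys, sched, dynamics_params(seed = child_seed(seed, s)),
                   ff, hb, energies = FALSE))
    reports[[s]] <- classify_outcome(run)
    if (progress) print(reports[[s]])
  }
  outcomes <- vapply(reports, function(r) r$outcome, character(1))
  succ <- reports[outcomes == "translocation"]
  steps <- vapply(succ, function(r) r$step_size_bp, numeric(1))
  loops <- vapply(succ, function(r) r$loop_size_bp, numeric(1))
  summary <- list(
    n = n_seeds,
    outcomes = table(factor(outcomes, levels = c("translocation", "slippage",
                                                 "arm_trap", "no_capture",
                                                 "incomplete"))),
    n_translocation = length(succ),
    unidirectional = length(succ) == 0 ||
      length(unique(sign(steps))) == 1,
    mean_step_bp = if (length(succ)) mean(steps) else NA_real_,
    mean_loop_bp = if (length(succ)) mean(loops) else NA_real_,
    step_loop_reldev = if (length(succ)) {
      mean(abs(abs(steps) - loops) / loops)
    } else NA_real_
  )
  list(reports = reports, summary = summary)
}

#' Structure-based stability of the apo rod
#'
#' Runs the toy complex in the disengaged state and reports the Q-score
#' series of the disengaged head-dimer interface.
#'
#' @param n_steps Steps (default 1e6).
#' @param seed RNG seed.
#' @param beads_per_arm Arm size.
#' @return Data frame from [q_series()].
#' @export
stability_study <- function(n_steps = 1e6, seed = 1, beads_per_arm = 20) {
  cx <- build_toy_complex(complex_spec(beads_per_arm = beads_per_arm))
  sys <- as_system(cx)
  run <- run_schedule(sys, state_schedule("disengaged", n_steps, "initial"),
                      dynamics_params(seed = seed),
                      ff = ff_params(dh_cutoff = 20), energies = FALSE)
  q_series(run, "head_head_disengaged")
}

#' Switching response of the head dimer
#'
#' Disengaged segment followed by an engaged segment; reports both Q-score
#' series so the crossing after the landscape switch can be checked.
#'
#' @param seed RNG seed.
#' @param beads_per_arm Arm size.
#' @param n_steps Steps per segment.
#' @return Data frame with `segment`, `q_disengaged`, `q_engaged`.
#' @export
switching_study <- function(seed = 1, beads_per_arm = 20, n_steps = 3e4) {
  cx <- build_toy_complex(complex_spec(beads_per_arm = beads_per_arm))
  sys <- as_system(cx)
  run <- run_schedule(sys, state_schedule(c("disengaged", "engaged"),
                                          n_steps, c("initial", "mid")),
                      dynamics_params(seed = seed),
                      ff = ff_params(dh_cutoff = 20), energies = FALSE)
  qd <- q_series(run, "head_head_disengaged")
  qe <- q_series(run, "head_head_engaged")
  data.frame(segment = qd$segment, step = qd$step, q_disengaged = qd$q,
             q_engaged = qe$q)
}

#' Zipping order of the coiled-coil arms
#'
#' Relaxes the V-shape conformation under the final disengaged landscape
#' (inter-arm contacts active) and records, per seeded run, whether the
#' hinge-side arm third reaches Q = 0.5 before the head-side third.
#'
#' @param n_runs Number of seeded relaxations.
#' @param seed Master seed.
#' @param beads_per_arm Arm size.
#' @param n_steps Steps per relaxation.
#' @return List with `hinge_first` (logical per run) and `fraction`.
#' @export
zipping_study <- function(n_runs = 20, seed = 1, beads_per_arm = 20,
                          n_steps = 3e4) {
  cx <- build_toy_complex(complex_spec(beads_per_arm = beads_per_arm))
  sys <- as_system(cx)
  start <- reference_conformation(cx, "vshape")
  hinge_first <- vapply(seq_len(n_runs), function(s) {
    run <- run_schedule(sys, state_schedule("disengaged", n_steps, "final"),
                        dynamics_params(seed = child_seed(seed, s)),
                        ff = ff_params(dh_cutoff = 20),
                        coords = start, energies = FALSE)
    qh <- q_series(run, "arm_arm_inter", arm_third = "hinge")$q
    qd <- q_series(run, "arm_arm_inter", arm_third = "head")$q
    th <- which(qh >= 0.5)[1]
    td <- which(qd >= 0.5)[1]
    !is.na(th) && (is.na(td) || th < td)
  }, logical(1))
  list(hinge_first = hinge_first, fraction = mean(hinge_first))
}

#' Kleisin DNA-patch asymmetry study
#'
#' Samples DNA-free engaged-state ensembles of the complex with GGGGS linker
#' repeats `x` inserted around the DNA-binding patch, pools the aligned patch
#' positions over all seeds, and reports the side asymmetry.
#'
#' @param x GGGGS repeats per side (0-10).
#' @param n_seeds Independent runs pooled.
#' @param seed Master seed.
#' @param beads_per_arm Arm size.
#' @param n_steps Sampling steps per run (the first half is discarded as
#'   equilibration).
#' @return A `patch_distribution`.
#' @export
kleisin_asymmetry_study <- function(x = 0, n_seeds = 20, seed = 1,
                                    beads_per_arm = 20, n_steps = 7e4) {
  cx <- insert_linker(build_toy_complex(complex_spec(
    beads_per_arm = beads_per_arm)), x)
  sys <- as_system(cx, state = "engaged")
  frames <- list()
  for (s in seq_len(n_seeds)) {
    run <- run_schedule(sys, state_schedule("engaged", n_steps),
                        dynamics_params(seed = child_seed(seed, s),
                                        stride = max(1, n_steps %/% 40)),
                        ff = ff_params(dh_cutoff = 20), energies = FALSE)
    keep <- which(run$frame_steps > n_steps / 2)
    frames[[s]] <- run$frames[, , keep, drop = FALSE]
  }
  nf <- sum(vapply(frames, function(f) dim(f)[3], numeric(1)))
  all <- array(NA_real_, c(sys$topology$n, 3, nf))
  k <- 0
  for (f in frames) {
    all[, , k + seq_len(dim(f)[3])] <- f
    k <- k + dim(f)[3]
  }
  patch_distribution(all, sys)
}
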