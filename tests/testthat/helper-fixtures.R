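# Shared fixtures: all synthetic, built in code at test time.

mini_spec <- function(...) {
  complex_spec(beads_per_arm = 12, head_beads = 12, hinge_beads = 4,
               kleisin_n_beads = 4, kleisin_c_beads = 6, ...)
}

mini_complex <- function(...) build_toy_complex(mini_spec(...))

# a ~50-bead system for force-consistency property tests
fifty_bead_system <- function() {
  as_system(build_toy_complex(
    complex_spec(beads_per_arm = 6, head_beads = 9, hinge_beads = 2,
                 kleisin_n_beads = 2, kleisin_c_beads = 4,
                 kleisin_linker_residues = 8)))
}

# raw potential for an isolated harmonic dimer (bond only)
dimer_pot <- function(k = 5, r0 = 3.8) {
  list(n = 2L, bonds = matrix(c(1, 2, r0, k), 1),
       angles = NULL, dihedrals = NULL, contacts = NULL,
       sigma = c(0, 0), eps_ev = 0, ev_factor = 2,
       q = c(0, 0), qpd = c(0, 0), isdna = c(0L, 0L),
       lambda = 7.85, kpre = 4.26, dh_cut = 50, hb = NULL, excl = NULL,
       nl_skin = 2)
}

# synthetic contact series for the estimator rule-table tests: `spec` is a
# data.frame(frame, segment, kleisin, arms, hinge) of per-frame mean bp (NA =
# no contact); returns a contact_series-like data.frame
fake_contact_series <- function(spec) {
  rows <- list()
  doms <- c(kleisin = "kleisin", arms = "arm_mid", hinge = "hinge")
  for (r in seq_len(nrow(spec))) {
    for (v in names(doms)) {
      val <- spec[[v]][r]
      rows[[length(rows) + 1]] <- data.frame(
        frame = spec$frame[r], step = spec$frame[r] * 100,
        segment = spec$segment[r], domain = doms[[v]],
        n = if (is.na(val)) 0L else 5L,
        mean_bp = if (is.na(val)) NA_real_ else val)
    }
    for (d in c("heads", "arm_hinge", "arm_head")) {
      rows[[length(rows) + 1]] <- data.frame(
        frame = spec$frame[r], step = spec$frame[r] * 100,
        segment = spec$segment[r], domain = d, n = 0L, mean_bp = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("contact_series", "data.frame")
  out
}

# minimal run skeleton for rule-table classification tests
fake_run <- function(states = c("disengaged", "engaged", "vshape",
                                "disengaged"), blown = FALSE) {
  sched <- data.frame(state = states, n_steps = 100,
                      phase = c("initial", rep("mid", length(states) - 2),
                                "final"))
  structure(list(schedule = sched, blown = blown, frames = NULL),
            class = "smc_run")
}

expect_close <- function(x, y, tol = 1e-9) expect_lt(max(abs(x - y)), tol)
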