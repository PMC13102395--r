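# Potential-energy terms and the per-nucleotide-state activation rules (the
# switching energy landscapes).
#
# Functional forms: harmonic bonds/angles, cosine dihedrals, 12-10 native
# contacts, purely repulsive (sigma/r)^12 excluded volume (shifted to zero at
# ev_factor*sigma), Debye-Huckel electrostatics (truncated and shifted), and
# a directional protein-DNA hydrogen-bond term with Gaussian radial/angular
# modulation inside hard filter windows.

#' Global force-field and environment parameters
#'
#' @param ionic_strength_mM Monovalent salt concentration (mM); presets used
#'   in the study conditions are 150 (DNA-binding-site mapping) and 300
#'   (translocation runs).
#' @param temperature Temperature (K).
#' @param eps_r Relative dielectric constant.
#' @param dh_cutoff Electrostatics cutoff (Angstrom); the energy is shifted to
#'   zero there.
#' @param eps_ev Excluded-volume energy scale (kcal/mol).
#' @param ev_factor Excluded-volume range in units of the pair sigma.
#' @param flex_scale Stiffness reduction factor applied to hinge-arm junction
#'   angles in the engaged and V-shape states (flexible local potential).
#' @param nl_skin Neighbor-list skin (Angstrom).
#' @return An object of class `ff_params`.
#' @export
ff_params <- function(ionic_strength_mM = 150, temperature = 300, eps_r = 78,
                      dh_cutoff = 50, eps_ev = 0.2, ev_factor = 2,
                      flex_scale = 0.05, nl_skin = 4) {
  if (ionic_strength_mM <= 0) stop("ionic strength must be positive")
  structure(list(ionic_strength_mM = ionic_strength_mM,
                 temperature = temperature, eps_r = eps_r,
                 dh_cutoff = dh_cutoff, eps_ev = eps_ev,
                 ev_factor = ev_factor, flex_scale = flex_scale,
                 nl_skin = nl_skin),
            class = "ff_params")
}

#' Debye screening length
#'
#' @param ionic_strength_mM 1:1 salt concentration in mM.
#' @param temperature Temperature (K).
#' @param eps_r Relative dielectric constant.
#' @return Screening length in Angstrom.
#' @export
debye_length <- function(ionic_strength_mM, temperature = 300, eps_r = 78) {
  if (any(ionic_strength_mM <= 0)) stop("ionic strength must be positive")
  lB <- .COULOMB / (eps_r * .kB * temperature)    # Bjerrum length, A
  n <- ionic_strength_mM / 1000 * .AVOGADRO_A3    # number density, A^-3
  1 / sqrt(8 * pi * lB * n)
}

#' 12-10 native-contact pair energy
#'
#' `U = eps * (5 (r0/r)^12 - 6 (r0/r)^10)`, minimum `-eps` at `r = r0`.
#'
#' @param r Pair distance (A), positive.
#' @param r0 Native distance (A).
#' @param eps Well depth (kcal/mol).
#' @return Energy (kcal/mol).
#' @export
native_contact_energy <- function(r, r0, eps = 1) {
  if (any(r <= 0)) stop("domain error: r must be positive")
  s <- r0 / r
  eps * (5 * s^12 - 6 * s^10)
}

#' Debye-Huckel pair energy (truncated and shifted)
#'
#' @param qi,qj Charges (e).
#' @param r Distance (A).
#' @param ff [ff_params()] supplying salt, temperature, dielectric, cutoff.
#' @return Energy (kcal/mol); exactly 0 at and beyond the cutoff.
#' @export
debye_huckel_energy <- function(qi, qj, r, ff = ff_params()) {
  if (any(r <= 0)) stop("domain error: r must be positive")
  lam <- debye_length(ff$ionic_strength_mM, ff$temperature, ff$eps_r)
  kpre <- .COULOMB / ff$eps_r
  shift <- exp(-ff$dh_cutoff / lam) / ff$dh_cutoff
  u <- kpre * qi * qj * (exp(-r / lam) / r - shift)
  ifelse(r >= ff$dh_cutoff, 0, u)
}

#' Coarse-grained hydrogen-bond model
#'
#' Directional short-range potential between protein C-alpha donor beads and
#' DNA phosphate beads:
#' `U = -eps * G(r; r0, sr) * G(theta; th0, st) * G(phi; ph0, sp)`, where each
#' `G` is a Gaussian multiplied by a smooth filter that reaches exactly zero
#' at `filter` standard deviations, so forces act only in a short range and
#' specific orientation. theta is the angle at the donor bead between its
#' orientation-reference neighbour and the phosphate (the angular modulation
#' acts on cos(theta), with the width mapped so that it matches a
#' theta-Gaussian of width `sigma_theta` near the peak -- this keeps forces
#' finite at collinear geometries); phi is the dihedral (neighbour, donor,
#' phosphate, sugar). An infinite `sigma_phi` (the toy-model default) drops
#' the dihedral modulation entirely.
#'
#' @param r0,sigma_r Radial peak and width (A).
#' @param theta0,sigma_theta Angular peak and width (degrees).
#' @param phi0,sigma_phi Dihedral peak and width (degrees).
#' @param epsilon Well depth (kcal/mol); default 4.0 kBT at 300 K.
#' @param filter Hard-zero half-width in standard deviations.
#' @param donors Optional data frame (`prev`, `donor`) overriding the
#'   system's donor table.
#' @return An object of class `hbond_model`.
#' @export
hbond_model <- function(r0 = 9, sigma_r = 1.5, theta0 = 135, sigma_theta = 25,
                        phi0 = 0, sigma_phi = Inf,
                        epsilon = 4 * kBT(300), filter = 3, donors = NULL) {
  if (sigma_r <= 0 || sigma_theta <= 0 || sigma_phi <= 0) {
    stop("configuration error: hydrogen-bond widths must be positive")
  }
  if (!is.finite(sigma_phi)) sigma_phi <- 1e6
  if (epsilon <= 0) stop("configuration error: epsilon must be positive")
  structure(list(r0 = r0, sigma_r = sigma_r, theta0 = theta0,
                 sigma_theta = sigma_theta, phi0 = phi0,
                 sigma_phi = sigma_phi, epsilon = epsilon, filter = filter,
                 donors = donors),
            class = "hbond_model")
}

# Gaussian with C1 smooth cutoff at `filter` sigmas (matches the compiled
# kernel): 1 at d = 0, exp(-1/2) at |d| = sigma, exactly 0 for |d| >= filter.
hb_gauss_r <- function(d, s, filter = 3) {
  u <- abs(d) / s
  g <- exp(-0.5 * (d / s)^2)
  t1 <- pmin(pmax(u - (filter - 1), 0), 1)
  sw <- 1 - (3 * t1^2 - 2 * t1^3)
  ifelse(u >= filter, 0, g * sw)
}

#' Hydrogen-bond energy at a given geometry
#'
#' @param r Donor-phosphate distance (A).
#' @param theta Angle at the donor (degrees).
#' @param phi Dihedral (degrees).
#' @param model An [hbond_model()].
#' @return Energy (kcal/mol); exactly 0 outside the filter windows, minimum
#'   `-epsilon` at `(r0, theta0, phi0)`.
#' @export
hbond_energy <- function(r, theta, phi, model = hbond_model()) {
  th0 <- model$theta0 * pi / 180
  sc <- max(abs(sin(th0)) * model$sigma_theta * pi / 180, 1e-6)
  gt <- hb_gauss_r(cos(theta * pi / 180) - cos(th0), sc, model$filter)
  sph <- model$sigma_phi * pi / 180
  gp <- if (sph >= 10) 1 else {
    dphi <- (phi - model$phi0 + 180) %% 360 - 180
    hb_gauss_r(dphi * pi / 180, sph, model$filter)
  }
  -model$epsilon * hb_gauss_r(r - model$r0, model$sigma_r, model$filter) *
    gt * gp
}

#' Per-nucleotide-state activation table
#'
#' Encodes which native-contact groups, scalings and interaction switches are
#' active in each nucleotide state of the ATP cycle:
#' disengaged = intra + disengaged head dimer + hinge dimer + kleisin-head
#' (+ inter-arm contacts only in the final disengaged segment of a
#' translocation run); engaged = intra + engaged head dimer (x2 strength) +
#' hinge dimer + kleisin-head, hydrogen bonds on, flexible hinge-arm junction
#' on; vshape = engaged set minus all head-head contacts minus hydrogen
#' bonds, flexible junction on.
#'
#' @param state `"disengaged"`, `"engaged"` or `"vshape"`.
#' @param translocation_phase `"initial"`, `"mid"` or `"final"`.
#' @return An object of class `state_potential`.
#' @export
make_state_potential <- function(state = c("disengaged", "engaged", "vshape"),
                                 translocation_phase = c("initial", "mid",
                                                         "final")) {
  state <- match.arg(state)
  phase <- match.arg(translocation_phase)
  base <- c("intra_domain", "hinge_dimer", "kleisin_head")
  out <- switch(state,
    disengaged = list(
      active_groups = c(base, "head_head_disengaged",
                        if (phase == "final") "arm_arm_inter"),
      head_scale = 1, hbond_active = FALSE, flex_active = FALSE),
    engaged = list(
      active_groups = c(base, "head_head_engaged"),
      head_scale = 2, hbond_active = TRUE, flex_active = TRUE),
    vshape = list(
      active_groups = base,
      head_scale = 1, hbond_active = FALSE, flex_active = TRUE)
  )
  structure(c(list(state = state, translocation_phase = phase), out),
            class = "state_potential")
}

#' Assign coarse-grained charges
#'
#' Protein beads get integer charges from a residue table (default: K/R = +1,
#' D/E = -1, others 0). DNA phosphate beads carry the dual-valued charge of
#' the model: -0.6 e for DNA-DNA pairs (counter-ion condensation) and -1.0 e
#' for protein-DNA pairs; the two values are applied strictly by pair class.
#'
#' @param system An `smc_system` (or `smc_complex` topology).
#' @param table Named numeric vector of per-residue charges overriding the
#'   default; or a two-column data frame (`bead`, `charge`) giving explicit
#'   per-bead protein charges.
#' @return An object of class `charge_model` with vectors `q` (same-class
#'   pairs), `q_pd` (protein-DNA pairs) and `is_dna`.
#' @export
assign_charges <- function(system, table = NULL) {
  topo <- if (inherits(system, "smc_complex")) system$topology else system$topology
  isdna <- topo$isdna %||% rep(0L, topo$n)
  q <- numeric(topo$n)
  qpd <- numeric(topo$n)
  prot <- which(isdna == 0)
  if (is.data.frame(table)) {
    q[table$bead] <- table$charge
  } else {
    q[prot] <- default_charges(topo$residue[prot], topo$kind[prot],
                               table = table)
  }
  qpd[prot] <- q[prot]
  dna <- which(isdna == 1)
  q[dna] <- ifelse(topo$kind[dna] == "phosphate", -0.6, 0)
  qpd[dna] <- ifelse(topo$kind[dna] == "phosphate", -1.0, 0)
  structure(list(q = q, q_pd = qpd, is_dna = isdna), class = "charge_model")
}

default_charges <- function(residue, kind, table = NULL) {
  tab <- c(K = 1, R = 1, D = -1, E = -1, H = 0)
  if (!is.null(table)) tab[names(table)] <- table
  out <- numeric(length(residue))
  ca <- kind == "ca"
  known <- residue %in% c(names(tab), "A", "C", "F", "G", "I", "L", "M", "N",
                          "P", "Q", "S", "T", "V", "W", "Y")
  if (any(ca & !known)) {
    stop("unknown residue code(s): ",
         paste(unique(residue[ca & !known]), collapse = ", "))
  }
  hit <- ca & residue %in% names(tab)
  out[hit] <- tab[residue[hit]]
  out
}

# Default hydrogen-bond pair table for a system: every donor bead paired with
# every DNA phosphate bead (plus that nucleotide's sugar bead as the dihedral
# reference).
hb_pairs <- function(system) {
  topo <- system$topology
  don <- topo$hb_donors
  ph <- which(topo$kind == "phosphate")
  if (is.null(don) || nrow(don) == 0 || length(ph) == 0) return(NULL)
  # same-nucleotide sugar for each phosphate
  sug <- which(topo$kind == "sugar")
  key <- paste(topo$strand[sug], topo$base_index[sug])
  ph_sug <- sug[match(paste(topo$strand[ph], topo$base_index[ph]), key)]
  g <- expand.grid(d = seq_len(nrow(don)), p = seq_along(ph))
  cbind(don$prev[g$d], don$donor[g$d], ph[g$p], ph_sug[g$p])
}

# Resolve a system + state potential + parameters into the flat term tables
# consumed by the compiled kernels.
resolve_potential <- function(system, state_pot, ff = ff_params(),
                              hb_model = NULL, charges = NULL) {
  topo <- system$topology
  stopifnot(inherits(state_pot, "state_potential"))
  ct <- topo$contacts
  act <- ct[ct$group %in% state_pot$active_groups, , drop = FALSE]
  eps <- act$eps
  eps[act$group == "head_head_engaged"] <- eps[act$group == "head_head_engaged"] *
    state_pot$head_scale
  contacts <- if (nrow(act)) cbind(act$i, act$j, act$r0, eps) else NULL

  ang <- topo$angles
  kth <- ang$kth
  if (state_pot$flex_active && any(ang$flex)) {
    kth[ang$flex] <- kth[ang$flex] * ff$flex_scale
  }
  angles <- if (nrow(ang)) cbind(ang$i, ang$j, ang$k, ang$th0, kth) else NULL
  dih <- topo$dihedrals
  dihedrals <- if (!is.null(dih) && nrow(dih)) {
    ph0 <- if (state_pot$state == "engaged" && !is.null(dih$ph0_eng)) {
      dih$ph0_eng
    } else dih$ph0
    cbind(dih$i, dih$j, dih$k, dih$l, ph0, dih$kph,
          dih$mult %||% rep(1, nrow(dih)))
  } else NULL
  bonds <- cbind(topo$bonds$i, topo$bonds$j, topo$bonds$r0, topo$bonds$k)

  cm <- charges %||% list(q = topo$charge,
                          q_pd = topo$charge_pd %||% topo$charge,
                          is_dna = topo$isdna %||% rep(0L, topo$n))

  hb <- NULL
  if (state_pot$hbond_active) {
    hm <- hb_model %||% hbond_model()
    pairs <- if (!is.null(hm$donors)) {
      # explicit donor table: pair with all phosphates
      sys2 <- system
      sys2$topology$hb_donors <- hm$donors
      hb_pairs(sys2)
    } else hb_pairs(system)
    if (!is.null(pairs)) {
      hb <- list(pairs = pairs, r0 = hm$r0, sr = hm$sigma_r,
                 th0 = hm$theta0 * pi / 180, sth = hm$sigma_theta * pi / 180,
                 ph0 = hm$phi0 * pi / 180, sph = hm$sigma_phi * pi / 180,
                 eps = hm$epsilon, filt = hm$filter)
    }
  }

  excl <- rbind(cbind(topo$bonds$i, topo$bonds$j),
                if (nrow(ang)) cbind(ang$i, ang$k),
                if (!is.null(dih) && nrow(dih)) cbind(dih$i, dih$l),
                if (nrow(act)) cbind(act$i, act$j),
                if (!is.null(topo$excl_extra) && nrow(topo$excl_extra))
                  cbind(topo$excl_extra$i, topo$excl_extra$j))

  list(n = topo$n, bonds = bonds, angles = angles, dihedrals = dihedrals,
       contacts = contacts, sigma = topo$sigma, eps_ev = ff$eps_ev,
       ev_factor = ff$ev_factor, q = cm$q, qpd = cm$q_pd,
       isdna = as.integer(cm$is_dna),
       lambda = debye_length(ff$ionic_strength_mM, ff$temperature, ff$eps_r),
       kpre = .COULOMB / ff$eps_r, dh_cut = ff$dh_cutoff,
       hb = hb, excl = if (is.null(excl)) NULL else
         matrix(as.integer(excl), ncol = 2),
       nl_skin = ff$nl_skin)
}

#' Total potential energy with component breakdown
#'
#' @param system An `smc_system`.
#' @param coords Coordinates (defaults to the system's).
#' @param state A [make_state_potential()] result or state name.
#' @param ff [ff_params()].
#' @param hb_model Optional [hbond_model()].
#' @param charges Optional [assign_charges()] result.
#' @return An `energy_breakdown` list: bond, angle, dihedral, native_contact
#'   (with per-group attribution in `native_contact_by_group`),
#'   excluded_volume, electrostatic, hbond, total (kcal/mol).
#' @export
total_energy <- function(system, coords = system$coords,
                         state = make_state_potential("disengaged"),
                         ff = ff_params(), hb_model = NULL, charges = NULL) {
  if (is.character(state)) state <- make_state_potential(state)
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  pot <- resolve_potential(system, state, ff, hb_model, charges)
  mind <- min_bonded_distance(coords, pot)
  if (mind < 1e-9) stop("singular geometry: coincident beads")
  e <- cg_energy_cpp(coords, pot)
  # per-group native-contact attribution
  ct <- system$topology$contacts
  act <- ct[ct$group %in% state$active_groups, , drop = FALSE]
  by_group <- if (nrow(act)) {
    d <- sqrt(rowSums((coords[act$i, , drop = FALSE] -
                       coords[act$j, , drop = FALSE])^2))
    eps <- act$eps
    eps[act$group == "head_head_engaged"] <-
      eps[act$group == "head_head_engaged"] * state$head_scale
    tapply(native_contact_energy(d, act$r0, eps), act$group, sum)
  } else numeric(0)
  structure(c(e, list(native_contact_by_group = by_group, state = state$state)),
            class = "energy_breakdown")
}

min_bonded_distance <- function(coords, pot) {
  if (is.null(pot$bonds) || nrow(pot$bonds) == 0) return(Inf)
  min(sqrt(rowSums((coords[pot$bonds[, 1], , drop = FALSE] -
                    coords[pot$bonds[, 2], , drop = FALSE])^2)))
}

#' Analytic forces
#'
#' Gradient of [total_energy()] with respect to all bead coordinates.
#'
#' @inheritParams total_energy
#' @return An `n x 3` force matrix (kcal/mol/A).
#' @export
forces <- function(system, coords = system$coords,
                   state = make_state_potential("disengaged"),
                   ff = ff_params(), hb_model = NULL, charges = NULL) {
  if (is.character(state)) state <- make_state_potential(state)
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  pot <- resolve_potential(system, state, ff, hb_model, charges)
  cg_forces_cpp(coords, pot)
}

#' @export
print.energy_breakdown <- function(x, ...) {
  comps <- c("bond", "angle", "dihedral", "native_contact", "excluded_volume",
             "electrostatic", "hbond", "total")
  for (cp in comps) cat(sprintf("  %-16s %12.4f kcal/mol\n", cp, x[[cp]]))
  invisible(x)
}
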