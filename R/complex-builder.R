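# Synthetic SMC-kleisin complex builder.
#
# The toy geometry replaces a homology model: arms are straight bead chains,
# the hinge is a dimerized bead cluster joining them, the heads are compact
# "super-bead" blocks with a large excluded-volume radius, and the kleisin is
# an asymmetric chain (structured NTD bound to one arm, structured CTD bound
# under the other head, disordered linker carrying the DNA-binding patch)
# drawn on the front (+y) side of the head plane.

# -- internal geometry constants ----------------------------------------------
.ARM_X <- 2.5          # half-separation of the juxtaposed arms (A)
.HEAD_SPACING <- 7.5   # head block lattice spacing (A)
.HEAD_SIGMA <- 8       # head bead excluded-volume diameter parameter (A)
.HINGE_SIGMA <- 8
.CHAIN_SIGMA <- 4
.JOINT_BEADS <- 3      # flexible beads linking each arm bottom to its head
.ENGAGED_ETA <- 0.88   # hinge height fraction in the engaged O-shape drawing
.ENGAGED_ROT <- 85 * pi / 180  # head rearrangement rotation
.ENGAGED_SLIDE <- c(0, 0, 0)   # pure rotation: necks stay on the axis
.VSHAPE_ROT <- 12 * pi / 180   # arm splay in the V-shape reference

#' Specification of a toy SMC-kleisin complex
#'
#' Defines the bead counts and dimensions of the synthetic complex. Defaults
#' emulate a prokaryotic SMC-ScpA ring: ~50 nm coiled-coil arms (130 beads at
#' 3.8 A), a dimerized hinge, two compact ATPase head blocks, and a kleisin
#' whose 63-residue disordered linker carries a 5-lysine DNA-binding patch at
#' the position corresponding to ScpA K126-K130.
#'
#' @param beads_per_arm Beads per SMC coiled-coil arm.
#' @param bead_spacing Bond length between consecutive chain beads (Angstrom).
#' @param arm_contour_length Nominal arm contour length (Angstrom); must agree
#'   with `beads_per_arm * bead_spacing` within one bead spacing.
#' @param hinge_beads Total hinge beads (split evenly between the subunits;
#'   must be even and >= 2).
#' @param head_beads Beads per ATPase head block (>= 4).
#' @param kleisin_n_beads,kleisin_c_beads Structured kleisin terminus bead
#'   counts.
#' @param kleisin_linker_residues Disordered linker length in residues
#'   (default 63).
#' @param linker_repeats_x Number of GGGGS repeats inserted on each side of
#'   the DNA-binding patch (0-10).
#' @param mirror_kleisin Build the mirror-image kleisin path (back side) --
#'   used to test the asymmetry analysis.
#' @param seed Integer seed recorded for provenance (the builder itself is
#'   deterministic).
#' @return An object of class `complex_spec`.
#' @export
complex_spec <- function(beads_per_arm = 130, bead_spacing = 3.8,
                         arm_contour_length = beads_per_arm * bead_spacing,
                         hinge_beads = 8, head_beads = 18,
                         kleisin_n_beads = 15, kleisin_c_beads = 15,
                         kleisin_linker_residues = 63, linker_repeats_x = 0,
                         mirror_kleisin = FALSE, seed = 1L) {
  counts <- c(beads_per_arm = beads_per_arm, hinge_beads = hinge_beads,
              head_beads = head_beads, kleisin_n_beads = kleisin_n_beads,
              kleisin_c_beads = kleisin_c_beads,
              kleisin_linker_residues = kleisin_linker_residues)
  bad <- names(counts)[counts < 1]
  if (length(bad)) {
    stop("all bead counts must be >= 1; offending field(s): ",
         paste(bad, collapse = ", "))
  }
  if (beads_per_arm < 6) {
    stop("counts too small to form a closed ring: beads_per_arm must be >= 6")
  }
  if (hinge_beads < 2 || hinge_beads %% 2 != 0) {
    stop("counts too small to form a closed ring: hinge_beads must be an even",
         " number >= 2")
  }
  if (head_beads < 9) {
    stop("counts too small to form a closed ring: head_beads must be >= 9")
  }
  if (kleisin_n_beads < 2 || kleisin_c_beads < 2) {
    stop("counts too small to form a closed ring: kleisin terminus bead",
         " counts must be >= 2")
  }
  if (kleisin_linker_residues < 7) {
    stop("counts too small to form a closed ring: kleisin_linker_residues",
         " must be >= 7")
  }
  if (linker_repeats_x < 0 || linker_repeats_x > 10 ||
      linker_repeats_x != round(linker_repeats_x)) {
    stop("linker_repeats_x must be an integer in [0, 10]")
  }
  if (abs(arm_contour_length - beads_per_arm * bead_spacing) > bead_spacing) {
    stop("arm_contour_length must equal beads_per_arm * bead_spacing within",
         " one bead spacing")
  }
  structure(list(beads_per_arm = as.integer(beads_per_arm),
                 bead_spacing = bead_spacing,
                 arm_contour_length = arm_contour_length,
                 hinge_beads = as.integer(hinge_beads),
                 head_beads = as.integer(head_beads),
                 kleisin_n_beads = as.integer(kleisin_n_beads),
                 kleisin_c_beads = as.integer(kleisin_c_beads),
                 kleisin_linker_residues = as.integer(kleisin_linker_residues),
                 linker_repeats_x = as.integer(linker_repeats_x),
                 mirror_kleisin = isTRUE(mirror_kleisin),
                 seed = as.integer(seed)),
            class = "complex_spec")
}

# lattice positions for a head block of `count` beads on the given subunit
# side (two z-layers, three y-rows), plus the neck bead (on the vertical axis
# through the block center, which is the engaged-rearrangement rotation axis).
head_block <- function(count, side) {
  hs <- .HEAD_SPACING
  nx <- ceiling(count / 6)
  pos <- expand.grid(x = seq_len(nx), y = -1:1, z = 0:1)
  pos <- pos[seq_len(count), , drop = FALSE]
  x <- side * (4 + (pos$x - 1) * hs)   # innermost lattice plane at |x| = 4
  y <- pos$y * hs
  z <- -37.5 + pos$z * hs
  grid <- cbind(x, y, z)
  centre_x <- side * (4 + (nx - 1) * hs / 2)
  # the neck sits on the rotation axis well above the top face, clear of the
  # DNA-binding track
  neck <- c(centre_x, 0, -10)
  list(grid = grid, neck = neck, centre_x = centre_x)
}

# Linker residue sequence: a GGGGS-like background with the 5-lysine patch at
# the position corresponding to ScpA K126-K130 (fractionally ~0.75 along the
# 63-residue linker), plus optional GGGGS inserts flanking the patch.
linker_residues <- function(n_base, x) {
  centre <- max(3, min(n_base - 2, round(n_base * 47 / 63)))
  base <- rep("G", n_base)
  base[seq(5, n_base, by = 5)] <- "S"
  base[(centre - 2):(centre + 2)] <- "K"
  if (x == 0) return(base)
  ins <- rep(c("G", "G", "G", "G", "S"), x)
  c(base[1:(centre - 3)], ins, base[(centre - 2):(centre + 2)], ins,
    base[(centre + 3):n_base])
}

#' Build a toy SMC-kleisin complex
#'
#' Constructs the bead topology (bonds, angles, dihedrals, native-contact
#' groups, hydrogen-bond donor table) and three reference conformations:
#' `disengaged` (I-shape, apo), `engaged` (O-shape, ATP-bound, heads
#' rearranged), `vshape` (ADP-bound, heads apart). All bonded rest values are
#' defined from the disengaged reference; the engaged head-head contact group
#' takes its rest distances from the engaged reference.
#'
#' @param spec A [complex_spec()].
#' @return An object of class `smc_complex` with elements `spec`, `topology`,
#'   `conformations` (named list of coordinate matrices) and `groups` (named
#'   bead index sets).
#' @export
build_toy_complex <- function(spec = complex_spec()) {
  stopifnot(inherits(spec, "complex_spec"))
  a <- spec$bead_spacing
  n_arm <- spec$beads_per_arm
  L <- (n_arm - 1) * a
  mir <- if (spec$mirror_kleisin) -1 else 1

  dom <- character(0); chain <- character(0); res <- character(0)
  sig <- numeric(0)
  coords <- matrix(numeric(0), 0, 3)
  add <- function(xyz, domain, ch, residue, sigma) {
    xyz <- matrix(xyz, ncol = 3)
    k <- nrow(xyz)
    coords <<- rbind(coords, xyz)
    dom <<- c(dom, rep_len(domain, k))
    chain <<- c(chain, rep(ch, k))
    res <<- c(res, rep_len(residue, k))
    sig <<- c(sig, rep_len(sigma, k))
    seq_len(k) + (length(dom) - k)
  }

  third <- function(i) {
    b <- ceiling(3 * i / n_arm)
    c("head", "mid", "hinge")[pmin(pmax(b, 1), 3)]
  }
  arm_res <- rep("A", n_arm)
  mid <- round(n_arm / 2)
  arm_res[max(1, mid - 2):min(mid + 2, n_arm)] <- "K"   # mid-arm DNA patch

  # arms (bead 1 = head end, bead n = hinge end)
  arm_z <- (seq_len(n_arm) - 1) * a
  i_arm_b <- add(cbind(-.ARM_X, 0, arm_z),
                 paste0("arm_blue_", third(seq_len(n_arm))), "A", arm_res, .CHAIN_SIGMA)
  i_arm_r <- add(cbind(+.ARM_X, 0, arm_z),
                 paste0("arm_red_", third(seq_len(n_arm))), "B", arm_res, .CHAIN_SIGMA)

  # heads (neck bead + block); top-layer beads are arginine HB donors
  hb_blue <- head_block(spec$head_beads, -1)
  hb_red <- head_block(spec$head_beads, +1)
  # basic surface: top-layer central-row arginines are the hydrogen-bond
  # donors; the rest of the top layer and the outer-face column are
  # charge-only lysines (the side patch that guides DNA around the rim)
  head_res <- function(grid) {
    top <- grid[, 3] > -33
    outer <- abs(grid[, 1]) > max(abs(grid[, 1])) - 1
    ifelse(top & abs(grid[, 2]) < 1, "R", ifelse(top | outer, "K", "A"))
  }
  i_neck_b <- add(hb_blue$neck, "head_blue", "A", "A", .HEAD_SIGMA)
  i_grid_b <- add(hb_blue$grid, "head_blue", "A", head_res(hb_blue$grid), .HEAD_SIGMA)
  i_neck_r <- add(hb_red$neck, "head_red", "B", "A", .HEAD_SIGMA)
  i_grid_r <- add(hb_red$grid, "head_red", "B", head_res(hb_red$grid), .HEAD_SIGMA)
  # arm-head joints, arced toward the back so the front ring entrance above
  # the heads stays clear for DNA insertion
  joint_xyz <- function(arm_bottom, neck) {
    place_linker(arm_bottom, neck,
                 rbind((arm_bottom + neck) / 2 + c(0, -4 * mir, 0)),
                 .JOINT_BEADS, 5.0, lobes = 2)
  }
  i_joint_b <- add(joint_xyz(c(-.ARM_X, 0, 0), hb_blue$neck), "head_blue",
                   "A", "G", .CHAIN_SIGMA)
  i_joint_r <- add(joint_xyz(c(+.ARM_X, 0, 0), hb_red$neck), "head_red",
                   "B", "G", .CHAIN_SIGMA)

  # hinge halves
  m_half <- spec$hinge_beads / 2
  hinge_half <- function(side) {
    j <- seq_len(m_half)
    cbind(side * 4, 4 * (-1)^(j + 1), L + 6 + 8 * floor((j - 1) / 2))
  }
  hres <- rep("K", m_half)   # inner hinge surface is a DNA-binding patch
  i_hinge_b <- add(hinge_half(-1), "hinge", "A", hres, .HINGE_SIGMA)
  i_hinge_r <- add(hinge_half(+1), "hinge", "B", hres, .HINGE_SIGMA)

  # kleisin: NTD down the front of the blue arm, disordered linker, zig-zag
  # CTD bound under the red head (front side)
  kn <- spec$kleisin_n_beads; kc <- spec$kleisin_c_beads
  ntd_xyz <- cbind(-.ARM_X, mir * 6.5, a * (kn + 1 - seq_len(kn)))
  i_ntd <- add(ntd_xyz, "kleisin_ntd", "C", "A", .CHAIN_SIGMA)
  lres <- linker_residues(spec$kleisin_linker_residues, spec$linker_repeats_x)
  nl <- length(lres)
  ctd_xyz <- cbind(20 + (seq_len(kc) - 1) * 2.33,
                   mir * (12 + 1.5 * (-1)^seq_len(kc)), -45)
  # route the disordered linker down the FRONT face of the blue head (the
  # head blocks leave no central channel), across below the heads, up to the
  # CTD; the +y meander that absorbs the contour slack stays on the front
  # side. The depth of the below-heads leg adapts to the linker contour so
  # short linkers still close the ring.
  link_wp <- function(A, B) {
    function(z) rbind(c(A[1] - 6, mir * 16, -40), c(A[1] - 6, mir * 12, z),
                      c(B[1], mir * 12, z))
  }
  choose_zlow <- function(A, B, contour) {
    wp <- link_wp(A, B)
    L <- function(z) curve_length(meander_curve(rbind(A, wp(z), B), 0))
    if (L(-46) > 0.8 * contour) return(NA_real_)  # too short for the route
    z <- tryCatch(stats::uniroot(function(z) L(z) - 0.7 * contour,
                                 c(-150, -46), tol = 1e-6)$root,
                  error = function(e) -150)
    min(max(z, -68), -46)
  }
  A0 <- ntd_xyz[kn, ]; B0 <- ctd_xyz[1, ]
  contour <- (nl + 1) * a
  # wild-type-length linkers are drawn entirely on the front side (the
  # asymmetric emanation); linkers elongated well beyond the wild type are
  # drawn as a compact alternating-side coil
  link_lobes <- if (nl > 90) -8 else 4
  draw_linker <- function(A, B) {
    z <- choose_zlow(A, B, contour)
    wps <- if (is.na(z)) {
      rbind((A + B) / 2 + c(0, mir * 10, -8))
    } else {
      link_wp(A, B)(z)
    }
    place_linker(A, B, wps, nl, a, lobes = link_lobes, ydir = mir)
  }
  link_xyz <- draw_linker(A0, B0)
  i_link <- add(link_xyz, ifelse(lres == "K", "kleisin_patch", "kleisin_linker"),
                "C", lres, .CHAIN_SIGMA)
  i_ctd <- add(ctd_xyz, "kleisin_ctd", "C", "A", .CHAIN_SIGMA)

  n <- nrow(coords)

  # ------------------------------------------------------------- bonded terms
  dist_ij <- function(i, j, xyz = coords) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  bonds <- list(); angles <- list(); dihedrals <- list()
  bond <- function(i, j, k = 50) {
    bonds[[length(bonds) + 1]] <<- c(i, j, dist_ij(i, j), k)
  }
  angle3 <- function(i, j, k, kth = 30, flex = FALSE) {
    v1 <- coords[i, ] - coords[j, ]; v2 <- coords[k, ] - coords[j, ]
    th <- acos(max(-1, min(1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2)))))
    angles[[length(angles) + 1]] <<- c(i, j, k, th, kth, as.numeric(flex))
  }
  dihed4 <- function(i, j, k, l, kph = 1, mult = 1) {
    ph <- dihedral_angle(coords[i, ], coords[j, ], coords[k, ], coords[l, ])
    dihedrals[[length(dihedrals) + 1]] <<- c(i, j, k, l, ph, kph, mult)
  }

  chain_terms <- function(idx, with_angles = TRUE, with_dihedrals = FALSE) {
    for (t in seq_len(length(idx) - 1)) bond(idx[t], idx[t + 1])
    if (with_angles && length(idx) >= 3) {
      for (t in 2:(length(idx) - 1)) angle3(idx[t - 1], idx[t], idx[t + 1])
    }
    if (with_dihedrals && length(idx) >= 4) {
      for (t in seq_len(length(idx) - 3)) {
        dihed4(idx[t], idx[t + 1], idx[t + 2], idx[t + 3])
      }
    }
  }

  chain_terms(i_arm_b); chain_terms(i_arm_r)
  # arm -> joint -> neck: bonds plus stiff angles, so each head is rigidly
  # positioned under its arm; the engaged head rearrangement spins the head
  # block about the vertical axis through the neck, which no bonded term
  # restrains
  joint_terms <- function(arm, joint, neck) {
    idx <- c(arm[2], arm[1], joint, neck)
    for (t in 3:length(idx)) bond(idx[t - 1], idx[t], 50)
    for (t in 2:(length(idx) - 1)) angle3(idx[t - 1], idx[t], idx[t + 1],
                                          kth = 20)
    for (t in seq_len(length(idx) - 3)) {
      dihed4(idx[t], idx[t + 1], idx[t + 2], idx[t + 3], kph = 10)
    }
  }
  joint_terms(i_arm_b, i_joint_b, i_neck_b)
  joint_terms(i_arm_r, i_joint_r, i_neck_r)
  # arm -> hinge (flexible junction triples)
  for (hb in i_hinge_b[seq_len(min(2, m_half))]) {
    bond(i_arm_b[n_arm], hb)
    angle3(i_arm_b[n_arm - 1], i_arm_b[n_arm], hb, kth = 50, flex = TRUE)
  }
  for (hb in i_hinge_r[seq_len(min(2, m_half))]) {
    bond(i_arm_r[n_arm], hb)
    angle3(i_arm_r[n_arm - 1], i_arm_r[n_arm], hb, kth = 50, flex = TRUE)
  }
  # cross-subunit junction angles: pin the two arm directions to the dimerized
  # hinge so the apo rod (I-shape) is maintained by hinge + head interactions
  # alone; these belong to the flexible-junction set softened in the engaged
  # and V-shape states, which lets the ring open
  angle3(i_arm_b[n_arm - 1], i_arm_b[n_arm], i_arm_r[n_arm], kth = 50,
         flex = TRUE)
  angle3(i_arm_r[n_arm - 1], i_arm_r[n_arm], i_arm_b[n_arm], kth = 50,
         flex = TRUE)
  # rigid units: elastic-network bonds
  en_bonds <- function(idx, cutoff, k) {
    if (length(idx) < 2) return(invisible())
    for (u in seq_along(idx)) {
      for (v in seq_along(idx)) {
        if (v <= u) next
        if (dist_ij(idx[u], idx[v]) < cutoff) bond(idx[u], idx[v], k)
      }
    }
  }
  en_bonds(i_grid_b, 11, 5)
  en_bonds(i_grid_r, 11, 5)
  # strut each neck to the two lattice beads nearest its rotation axis (both
  # on the axis for the default head size, so the engaged spin leaves all
  # neck bonds unchanged)
  neck_struts <- function(jref, neck, grid_idx) {
    ax <- coords[neck, 1:2]
    d2 <- (coords[grid_idx, 1] - ax[1])^2 + (coords[grid_idx, 2] - ax[2])^2
    on_axis <- grid_idx[order(d2)][1:2]
    for (g in on_axis) bond(neck, g, 30)
    # spin restraint about the neck axis; its rest angle switches with the
    # nucleotide state (recomputed from the engaged reference below), so the
    # head is pinned to the apo interface pose in the apo/ADP landscapes and
    # actively driven to the rotated pose when the engaged landscape is
    # switched on
    off_axis <- grid_idx[d2 > 1]
    corner <- off_axis[which.max(d2[match(off_axis, grid_idx)])]
    axis_low <- on_axis[which.min(coords[on_axis, 3])]
    dihed4(jref, neck, axis_low, corner, kph = 3, mult = 1)
  }
  # the spin reference is the middle joint bead: rigidly held off the neck
  # axis, so the dihedral never approaches a collinear geometry
  neck_struts(i_joint_b[2], i_neck_b, i_grid_b)
  neck_struts(i_joint_r[2], i_neck_r, i_grid_r)
  en_bonds(i_hinge_b, 12, 20)
  en_bonds(i_hinge_r, 12, 20)
  # kleisin chain: NTD straight (angles), linker fully flexible (bonds only),
  # CTD zig-zag (angles + dihedrals)
  chain_terms(i_ntd)
  bond(i_ntd[kn], i_link[1])
  chain_terms(i_link, with_angles = FALSE)
  bond(i_link[nl], i_ctd[1])
  chain_terms(i_ctd, with_dihedrals = TRUE)

  # -------------------------------------------------- engaged conformation
  eng <- coords
  etaL <- .ENGAGED_ETA * L
  arm_arc <- function(side) {
    # circular arc with exactly equal chords `a` between the arm endpoints,
    # bulging outward (away from the complex axis)
    p0 <- c(side * .ARM_X, 0, 0); p1 <- c(side * .ARM_X, 0, etaL)
    d <- etaL
    f <- function(R) 2 * R * sin((n_arm - 1) * asin(a / (2 * R))) - d
    R <- stats::uniroot(f, c(max(d / 2, a / 2) + 1e-9, 1e7), tol = 1e-12)$root
    h <- sqrt(max(R^2 - (d / 2)^2, 0))
    centre <- c(side * .ARM_X - side * h, 0, etaL / 2)  # inward of the chord
    ang0 <- atan2(p0[3] - centre[3], p0[1] - centre[1])
    ang1 <- atan2(p1[3] - centre[3], p1[1] - centre[1])
    dang <- ang1 - ang0
    while (dang > pi) dang <- dang - 2 * pi
    while (dang < -pi) dang <- dang + 2 * pi
    th <- ang0 + dang * (seq_len(n_arm) - 1) / (n_arm - 1)
    cbind(centre[1] + R * cos(th), 0, centre[3] + R * sin(th))
  }
  eng[i_arm_b, ] <- arm_arc(-1)
  eng[i_arm_r, ] <- arm_arc(+1)
  eng[c(i_hinge_b, i_hinge_r), 3] <- eng[c(i_hinge_b, i_hinge_r), 3] - (L - etaL)
  rot_red <- c(i_neck_r, i_grid_r, i_ctd)
  eng <- rotate_about(eng, rot_red, origin = coords[i_neck_r, ],
                      axis = c(0, 0, 1), angle = mir * .ENGAGED_ROT)
  eng[rot_red, ] <- sweep(eng[rot_red, , drop = FALSE], 2, .ENGAGED_SLIDE, `+`)
  A1 <- eng[i_ntd[kn], ]; B1 <- eng[i_ctd[1], ]
  eng[i_link, ] <- draw_linker(A1, B1)

  # -------------------------------------------------- vshape conformation
  vsh <- coords
  blue_unit <- c(i_arm_b[-n_arm], i_joint_b, i_neck_b, i_grid_b, i_ntd)
  red_unit <- c(i_arm_r[-n_arm], i_joint_r, i_neck_r, i_grid_r, i_ctd)
  vsh <- rotate_about(vsh, blue_unit, origin = coords[i_arm_b[n_arm], ],
                      axis = c(0, 1, 0), angle = +.VSHAPE_ROT)
  vsh <- rotate_about(vsh, red_unit, origin = coords[i_arm_r[n_arm], ],
                      axis = c(0, 1, 0), angle = -.VSHAPE_ROT)
  A2 <- vsh[i_ntd[kn], ]; B2 <- vsh[i_ctd[1], ]
  vsh[i_link, ] <- draw_linker(A2, B2)

  # --------------------------------------------------------- contact groups
  contacts <- list()
  add_contacts <- function(set1, set2, cutoff, group, xyz = coords,
                           eps = 0.6, same = FALSE) {
    for (u in set1) {
      for (v in set2) {
        if (same && v <= u) next
        r0 <- dist_ij(u, v, xyz)
        if (r0 < cutoff && r0 > 1e-6) {
          contacts[[length(contacts) + 1]] <<- c(u, v, r0, eps,
                                                 group = NA)
          names(contacts)[length(contacts)] <<- group
        }
      }
    }
  }
  # intra-domain contacts (hinge halves and kleisin termini i,i+3)
  add_contacts(i_hinge_b, i_hinge_b, 12, "intra_domain", same = TRUE)
  add_contacts(i_hinge_r, i_hinge_r, 12, "intra_domain", same = TRUE)
  for (idx in list(i_ntd, i_ctd)) {
    for (t in seq_len(max(length(idx) - 3, 0))) {
      contacts[[length(contacts) + 1]] <- c(idx[t], idx[t + 3],
                                            dist_ij(idx[t], idx[t + 3]), 0.6, NA)
      names(contacts)[length(contacts)] <- "intra_domain"
    }
  }
  blue_head <- c(i_neck_b, i_grid_b, i_joint_b)
  red_head <- c(i_neck_r, i_grid_r, i_joint_r)
  add_contacts(i_grid_b, i_grid_r, 12.5, "head_head_disengaged", eps = 1.5)
  add_contacts(i_grid_b, i_grid_r, 16, "head_head_engaged", xyz = eng, eps = 1)
  # drop engaged-interface pairs that are compressed in the disengaged pose:
  # switching the landscape on such a pair would place it deep inside the
  # repulsive 12-10 core
  keep <- vapply(seq_along(contacts), function(t) {
    if (names(contacts)[t] != "head_head_engaged") return(TRUE)
    ct <- contacts[[t]]
    dist_ij(ct[1], ct[2]) >= 0.9 * ct[3]
  }, logical(1))
  contacts <- contacts[keep]
  add_contacts(i_arm_b, i_arm_r, 6.6, "arm_arm_inter")
  add_contacts(i_hinge_b, i_hinge_r, 18, "hinge_dimer", eps = 3)
  add_contacts(i_ntd, i_arm_b, 12, "kleisin_head")
  add_contacts(i_ctd, i_grid_r, 13, "kleisin_head")

  to_df <- function(lst, nm) {
    if (!length(lst)) {
      return(stats::setNames(as.data.frame(matrix(numeric(0), 0, length(nm))), nm))
    }
    df <- as.data.frame(do.call(rbind, lst))
    names(df) <- nm
    df
  }
  bonds_df <- to_df(bonds, c("i", "j", "r0", "k"))
  angles_df <- to_df(angles, c("i", "j", "k", "th0", "kth", "flex"))
  angles_df$flex <- angles_df$flex > 0
  dihedrals_df <- to_df(dihedrals, c("i", "j", "k", "l", "ph0", "kph", "mult"))
  # dihedral rest angles in the engaged landscape, from the engaged reference
  # (identical for rigidly carried groups; differs only for the head-spin
  # coordinate, which is part of the switched head interface)
  dihedrals_df$ph0_eng <- vapply(seq_len(nrow(dihedrals_df)), function(r) {
    dihedral_angle(eng[dihedrals_df$i[r], ], eng[dihedrals_df$j[r], ],
                   eng[dihedrals_df$k[r], ], eng[dihedrals_df$l[r], ])
  }, numeric(1))
  contacts_df <- to_df(contacts, c("i", "j", "r0", "eps", "dummy"))
  contacts_df$dummy <- NULL
  contacts_df$group <- if (length(contacts)) names(contacts) else character(0)

  # hydrogen-bond donors: head top-layer arginines; the orientation reference
  # ("previous" bead) is the lattice bead directly below the donor, which
  # makes the bond top-face selective (theta0 ~ 150 degrees)
  donors <- which(res == "R" & dom %in% c("head_blue", "head_red"))
  prev <- vapply(donors, function(d) {
    cand <- setdiff(which(dom == dom[d]), d)
    below <- cand[abs(coords[cand, 1] - coords[d, 1]) < 0.1 &
                    abs(coords[cand, 2] - coords[d, 2]) < 0.1 &
                    coords[cand, 3] < coords[d, 3]]
    if (!length(below)) below <- cand
    below[which.min(coords[d, 3] - coords[below, 3])]
  }, integer(1))
  hb_donors <- data.frame(prev = prev, donor = donors)

  # the disordered kleisin chain carries no angle/dihedral terms, so its
  # 1-3 and 1-4 pairs must be excluded from the nonbonded terms explicitly
  kle_chain <- c(i_ntd, i_link, i_ctd)
  excl_extra <- rbind(
    data.frame(i = kle_chain[seq_len(length(kle_chain) - 2)],
               j = kle_chain[-(1:2)]),
    data.frame(i = kle_chain[seq_len(length(kle_chain) - 3)],
               j = kle_chain[-(1:3)]),
    data.frame(i = c(i_arm_b[1], i_joint_b[seq_len(.JOINT_BEADS - 1)],
                     i_arm_r[1], i_joint_r[seq_len(.JOINT_BEADS - 1)]),
               j = c(i_joint_b[-1], i_neck_b, i_joint_r[-1], i_neck_r))
  )

  topology <- list(
    n = n, kind = rep("ca", n), residue = res, chain = chain, domain = dom,
    base_index = rep(NA_integer_, n), strand = rep(NA_integer_, n),
    sigma = sig, bonds = bonds_df, angles = angles_df,
    dihedrals = dihedrals_df, contacts = contacts_df, hb_donors = hb_donors,
    excl_extra = excl_extra
  )
  topology$charge <- default_charges(res, kind = topology$kind)

  groups <- list(
    arm_blue = i_arm_b, arm_red = i_arm_r,
    head_blue = blue_head, head_red = red_head,
    hinge_blue = i_hinge_b, hinge_red = i_hinge_r,
    kleisin_ntd = i_ntd, kleisin_linker = i_link, kleisin_ctd = i_ctd,
    kleisin_patch = which(dom == "kleisin_patch")
  )

  structure(list(spec = spec, topology = topology,
                 conformations = list(disengaged = coords, engaged = eng,
                                      vshape = vsh),
                 groups = groups),
            class = "smc_complex")
}

# dihedral angle (radians) between planes (p1,p2,p3) and (p2,p3,p4)
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  atan2(vnorm(b2) * sum(b1 * n2), sum(n1 * n2))
}

#' Insert GGGGS linker repeats flanking the kleisin DNA patch
#'
#' Rebuilds the complex with `5*x` glycine/serine beads inserted on each side
#' of the 5-lysine patch (10*x beads in total), redrawing the disordered
#' linker and rebuilding its local bonds. Inserted beads are charge-neutral.
#'
#' @param complex An [build_toy_complex()] result.
#' @param x Integer number of GGGGS repeats per side, in `[0, 10]`.
#' @return A new `smc_complex` (identical to the input when `x = 0` and the
#'   input was built with `x = 0`).
#' @export
insert_linker <- function(complex, x) {
  stopifnot(inherits(complex, "smc_complex"))
  if (length(x) != 1 || x < 0 || x > 10 || x != round(x)) {
    stop("x must be an integer in [0, 10]")
  }
  if (x == complex$spec$linker_repeats_x) return(complex)
  spec <- complex$spec
  spec$linker_repeats_x <- as.integer(x)
  build_toy_complex(spec)
}

#' Extract a reference conformation
#' @param complex An `smc_complex`.
#' @param state One of "disengaged", "engaged", "vshape".
#' @return Coordinate matrix (n x 3, Angstrom).
#' @export
reference_conformation <- function(complex,
                                   state = c("disengaged", "engaged", "vshape")) {
  state <- match.arg(state)
  complex$conformations[[state]]
}

#' @export
print.smc_complex <- function(x, ...) {
  cat("Toy SMC-kleisin complex:", x$topology$n, "beads\n")
  cat("  arms:", x$spec$beads_per_arm, "beads each (",
      round(x$spec$beads_per_arm * x$spec$bead_spacing), "A contour )\n")
  cat("  kleisin linker:", sum(x$topology$domain %in%
                               c("kleisin_linker", "kleisin_patch")),
      "beads (GGGGS repeats x =", x$spec$linker_repeats_x, ")\n")
  cat("  contacts:", nrow(x$topology$contacts), "in groups:",
      paste(unique(x$topology$contacts$group), collapse = ", "), "\n")
  invisible(x)
}
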