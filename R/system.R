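# System assembly: merging a toy complex with a DNA duplex and threading the
# duplex through the kleisin ring of the disengaged conformation.

#' Wrap a complex (optionally with DNA) as a simulation system
#'
#' @param complex An `smc_complex`.
#' @param state Reference conformation supplying the initial coordinates.
#' @return An object of class `smc_system` (protein-only).
#' @export
as_system <- function(complex, state = "disengaged") {
  coords <- reference_conformation(complex, state)
  topo <- complex$topology
  topo$charge_pd <- topo$charge
  topo$isdna <- rep(0L, topo$n)
  structure(list(complex = complex, topology = topo, coords = coords,
                 dna = NULL, n_bp = 0L,
                 groups = complex$groups,
                 threading = list(kleisin = FALSE, smc = FALSE),
                 offset_bp = NA_integer_),
            class = "smc_system")
}

merge_complex_dna <- function(complex, dna, dna_coords) {
  pt <- complex$topology
  dt <- dna$topology
  np <- pt$n
  dna_bonds <- dt$bonds
  dna_bonds$i <- dna_bonds$i + np
  dna_bonds$j <- dna_bonds$j + np
  dna_excl <- dt$excl_extra
  dna_excl$i <- dna_excl$i + np
  dna_excl$j <- dna_excl$j + np
  topo <- list(
    n = np + dt$n,
    kind = c(pt$kind, dt$kind),
    residue = c(pt$residue, dt$residue),
    chain = c(pt$chain, dt$chain),
    domain = c(pt$domain, rep("dna", dt$n)),
    base_index = c(pt$base_index, dt$base_index),
    strand = c(pt$strand, dt$strand),
    sigma = c(pt$sigma, dt$sigma),
    charge = c(pt$charge, dt$charge),
    charge_pd = c(pt$charge, dt$charge_pd),
    isdna = c(rep(0L, np), rep(1L, dt$n)),
    bonds = rbind(pt$bonds, dna_bonds),
    angles = pt$angles,
    dihedrals = pt$dihedrals,
    contacts = pt$contacts,
    hb_donors = pt$hb_donors,
    excl_extra = rbind(pt$excl_extra, dna_excl)
  )
  coords <- rbind(reference_conformation(complex, "disengaged"), dna_coords)
  groups <- complex$groups
  groups$dna <- np + seq_len(dt$n)
  list(topology = topo, coords = coords, groups = groups)
}

#' Thread a DNA duplex through the kleisin ring
#'
#' Places the duplex axis along the y direction through the kleisin-ring
#' opening of the disengaged conformation, with base pair `offset_bp` nearest
#' the kleisin DNA-binding patch, and verifies sterics and threading parity.
#'
#' @param complex An `smc_complex`.
#' @param dna A [build_dna()] result.
#' @param offset_bp 1-based base-pair index initially facing the patch.
#' @return An `smc_system` with DNA, threading status, and the initial
#'   patch-proximal base pair recorded.
#' @export
thread_dna <- function(complex, dna, offset_bp) {
  stopifnot(inherits(complex, "smc_complex"), inherits(dna, "dna_duplex"))
  if (length(offset_bp) != 1 || offset_bp < 1 || offset_bp > dna$n_bp ||
      offset_bp != round(offset_bp)) {
    stop("offset_bp must be an integer in [1, n_bp]")
  }
  span_needed <- 40  # A of duplex required on each side of the ring
  min_bp <- 2 * ceiling(span_needed / dna$rise) + 1
  if ((offset_bp - 1) * dna$rise < span_needed ||
      (dna$n_bp - offset_bp) * dna$rise < span_needed) {
    stop(sprintf(paste0("DNA too short to thread without overlap: need >= %d",
                        " bp with >= %.0f A on each side of the offset"),
                 min_bp, span_needed))
  }
  ref <- reference_conformation(complex, "disengaged")
  patch <- complex$groups$kleisin_patch
  pc <- colMeans(ref[patch, , drop = FALSE])

  # orient the duplex axis along +y at candidate (x, z) offsets from the patch
  prot_sig <- complex$topology$sigma
  dna_local <- dna$coords
  # built helix axis is +z; rotate so it runs along +y
  R <- rot_axis(c(1, 0, 0), -pi / 2)
  dna_local <- dna_local %*% t(R)
  axis_y <- dna_local[, 2]
  best <- NULL
  for (dz in 11:17) {
    for (dx in c(0, 2, -2, 4, -4)) {
      cand <- dna_local
      cand[, 1] <- cand[, 1] + pc[1] + dx
      cand[, 3] <- cand[, 3] + pc[3] + dz
      cand[, 2] <- cand[, 2] + pc[2] -
        (axis_y[match(TRUE, dna$topology$base_index == offset_bp &
                        dna$topology$kind == "sugar")])
      near <- cand[, 1] > min(ref[, 1]) - 25 & cand[, 1] < max(ref[, 1]) + 25 &
        cand[, 2] > min(ref[, 2]) - 25 & cand[, 2] < max(ref[, 2]) + 25 &
        cand[, 3] > min(ref[, 3]) - 25 & cand[, 3] < max(ref[, 3]) + 25
      clear <- if (!any(near)) Inf else {
        steric_clearance(ref, prot_sig, cand[near, , drop = FALSE],
                         dna$topology$sigma[near])
      }
      pd <- min(proxy_dist(ref[patch, , drop = FALSE], cand))
      if (clear >= 0.9 && pd < 9) {
        # prefer the highest admissible placement (closest under the heads),
        # then the largest clearance
        score <- c(dz, clear)
        if (is.null(best) || score[1] > best$score[1] ||
            (score[1] == best$score[1] && score[2] > best$score[2])) {
          best <- list(coords = cand, clear = clear, patch_dist = pd,
                       score = score)
        }
      }
    }
  }
  if (is.null(best)) {
    stop("DNA too short to thread without overlap: no sterically admissible",
         " placement found near the kleisin patch")
  }
  merged <- merge_complex_dna(complex, dna, best$coords)
  sys <- structure(c(merged, list(complex = complex, dna = dna,
                                  n_bp = dna$n_bp,
                                  offset_bp = as.integer(offset_bp))),
                   class = "smc_system")
  sys$threading <- list(
    kleisin = threading_check(sys, sys$coords, "kleisin")$threaded,
    smc = threading_check(sys, sys$coords, "smc")$threaded
  )
  sys
}

# minimum pairwise distance / pair sigma ratio between two bead sets
steric_clearance <- function(xa, sa, xb, sb) {
  m <- proxy_dist(xa, xb)
  sij <- outer(sa, sb, function(a, b) (a + b) / 2)
  min(m / sij)
}

proxy_dist <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, `+`) - 2 * (a %*% t(b))
  sqrt(pmax(d2, 0))
}

#' Ordered bead cycle of a protein ring
#'
#' The kleisin ring runs NTD -> linker -> CTD and closes through the two head
#' necks; the SMC ring runs up the blue arm, across the hinge, down the red
#' arm and closes through the necks.
#'
#' @param system An `smc_system` (or `smc_complex`).
#' @param ring `"kleisin"` or `"smc"`.
#' @return Integer vector of bead indices forming the closed cycle.
#' @export
ring_path <- function(system, ring = c("kleisin", "smc")) {
  ring <- match.arg(ring)
  g <- if (inherits(system, "smc_complex")) system$groups else system$groups
  if (is.null(g$kleisin_ntd)) stop("ring not closable: no kleisin in topology")
  neck_b <- g$head_blue[1]; neck_r <- g$head_red[1]
  if (ring == "kleisin") {
    c(g$kleisin_ntd, sort(c(g$kleisin_linker, g$kleisin_patch)),
      g$kleisin_ctd, neck_r, neck_b)
  } else {
    c(g$arm_blue, g$hinge_blue[1], g$hinge_red[1], rev(g$arm_red),
      neck_r, neck_b)
  }
}

#' @export
print.smc_system <- function(x, ...) {
  cat("SMC-kleisin system:", x$topology$n, "beads")
  if (x$n_bp > 0) {
    cat(",", x$n_bp, "bp DNA threaded at bp", x$offset_bp,
        "(kleisin ring threaded:", x$threading$kleisin, ")")
  }
  cat("\n")
  invisible(x)
}
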