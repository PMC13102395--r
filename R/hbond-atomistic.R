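# Generic atomistic hydrogen-bond analysis: Baker-Hubbard detection,
# per-residue bond fractions, donor-residue selection, and derivation of
# coarse-grained hydrogen-bond parameters from geometry histograms.

#' Hydrogen-bond donor/hydrogen/acceptor triples
#'
#' @param donor,hydrogen,acceptor Atom indices.
#' @param residue Donor-side residue identifier per triple.
#' @return A validated data frame of class `hb_triples`.
#' @export
hb_triples <- function(donor, hydrogen, acceptor, residue) {
  df <- data.frame(donor = donor, hydrogen = hydrogen, acceptor = acceptor,
                   residue = residue, stringsAsFactors = FALSE)
  bad <- with(df, donor == hydrogen | donor == acceptor | hydrogen == acceptor)
  if (any(bad)) {
    stop("triples must have three distinct atom ids (rows ",
         paste(which(bad), collapse = ", "), ")")
  }
  class(df) <- c("hb_triples", "data.frame")
  df
}

#' Baker-Hubbard hydrogen-bond detection in one frame
#'
#' A bond is present iff the hydrogen-acceptor distance is strictly below
#' `r_cut` (2.5 A) and the donor-hydrogen-acceptor angle is strictly above
#' `theta_cut` (120 degrees).
#'
#' @param coords Atom coordinate matrix.
#' @param triples An [hb_triples()] table.
#' @param r_cut Distance criterion (A).
#' @param theta_cut Angle criterion (degrees).
#' @return Logical vector, one element per triple.
#' @export
detect_hbonds <- function(coords, triples, r_cut = 2.5, theta_cut = 120) {
  idx <- c(triples$donor, triples$hydrogen, triples$acceptor)
  if (any(idx < 1 | idx > nrow(coords))) {
    bad <- which(triples$donor > nrow(coords) | triples$hydrogen > nrow(coords) |
                   triples$acceptor > nrow(coords))[1]
    stop("missing atom in triple ", bad %||% "?")
  }
  H <- coords[triples$hydrogen, , drop = FALSE]
  D <- coords[triples$donor, , drop = FALSE]
  A <- coords[triples$acceptor, , drop = FALSE]
  ha <- A - H
  hd <- D - H
  r <- sqrt(rowSums(ha^2))
  cosang <- rowSums(ha * hd) / (r * sqrt(rowSums(hd^2)))
  ang <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
  r < r_cut & ang > theta_cut
}

#' Per-residue hydrogen-bond fractions over a trajectory
#'
#' Discards the first `cut` frames as equilibration, then reports per residue
#' the fraction of remaining frames with at least one hydrogen bond, plus the
#' per-frame total bond count series.
#'
#' @param traj A 3D coordinate array (atoms x 3 x frames) or list of frames.
#' @param triples An [hb_triples()] table.
#' @param cut Number of initial frames to discard.
#' @param r_cut,theta_cut Baker-Hubbard criteria.
#' @return List with `fractions` (named by residue), `counts` (per analyzed
#'   frame) and `n_frames`.
#' @export
bond_fractions <- function(traj, triples, cut = 0, r_cut = 2.5,
                           theta_cut = 120) {
  get_frame <- if (is.list(traj)) function(k) traj[[k]] else
    function(k) traj[, , k]
  nf <- if (is.list(traj)) length(traj) else dim(traj)[3]
  if (cut >= nf) stop("equilibration cut removes the whole trajectory")
  use <- seq.int(cut + 1, nf)
  resids <- unique(triples$residue)
  hit <- matrix(0, length(use), length(resids),
                dimnames = list(NULL, as.character(resids)))
  counts <- integer(length(use))
  for (t in seq_along(use)) {
    b <- detect_hbonds(get_frame(use[t]), triples, r_cut, theta_cut)
    counts[t] <- sum(b)
    if (any(b)) {
      got <- unique(as.character(triples$residue[b]))
      hit[t, got] <- 1
    }
  }
  fractions <- colMeans(hit)
  list(fractions = fractions, counts = counts, n_frames = length(use))
}

#' Select hydrogen-bonding residues for the coarse-grained model
#'
#' Residues with bond fraction strictly above the threshold, in descending
#' order, truncated to the top `top_n` (default: top 15 with fraction >
#' 0.05).
#'
#' @param fractions Named fractions from [bond_fractions()].
#' @param threshold Strict lower bound on the fraction.
#' @param top_n Maximum number of residues returned.
#' @return Character vector of residue identifiers (possibly empty).
#' @export
select_hb_residues <- function(fractions, threshold = 0.05, top_n = 15) {
  f <- fractions[fractions > threshold]
  f <- f[order(-f)]
  utils::head(names(f), top_n)
}

hist_mode <- function(x, bw) {
  rng <- range(x)
  breaks <- seq(rng[1] - bw / 2, rng[2] + bw, by = bw)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  nz <- h$counts[h$counts > 0]
  peakless <- length(nz) > 6 && max(nz) < 2.5 * stats::median(nz)
  # ties broken toward the smaller bin center
  mode <- h$mids[which.max(h$counts)]
  list(mode = mode, counts = h$counts, mids = h$mids, peakless = peakless)
}

#' Derive coarse-grained hydrogen-bond parameters from geometry samples
#'
#' Histograms the (r, theta, phi) samples of each selected residue and takes
#' the peak positions (center of the maximal bin; ties toward the smaller
#' value) as the coarse-grained parameters.
#'
#' @param samples Named list (per residue) of lists with numeric vectors `r`
#'   (A), `theta`, `phi` (degrees); at least `min_samples` each.
#' @param bin_r,bin_theta,bin_phi Histogram bin widths.
#' @param min_samples Minimum samples per residue.
#' @return An object of class `cg_param_estimate`: per-residue `r0`,
#'   `theta0`, `phi0`, the histograms, and `peakless` flags.
#' @export
derive_cg_params <- function(samples, bin_r = 0.1, bin_theta = 5, bin_phi = 5,
                             min_samples = 100) {
  short <- names(samples)[vapply(samples, function(s) {
    min(length(s$r), length(s$theta), length(s$phi)) < min_samples
  }, logical(1))]
  if (length(short)) {
    stop("too few geometry samples for residue(s): ",
         paste(short, collapse = ", "))
  }
  per <- lapply(samples, function(s) {
    hr <- hist_mode(s$r, bin_r)
    ht <- hist_mode(s$theta, bin_theta)
    hp <- hist_mode(s$phi, bin_phi)
    if (hr$peakless || ht$peakless || hp$peakless) {
      warning("peakless geometry distribution; using the maximal-bin mode")
    }
    list(r0 = hr$mode, theta0 = ht$mode, phi0 = hp$mode,
         histograms = list(r = hr, theta = ht, phi = hp),
         peakless = hr$peakless || ht$peakless || hp$peakless)
  })
  structure(list(residues = names(samples), params = per,
                 bins = c(r = bin_r, theta = bin_theta, phi = bin_phi)),
            class = "cg_param_estimate")
}

#' Convert a parameter estimate into a coarse-grained hydrogen-bond model
#'
#' Pools the per-residue peak positions (median across residues) into one
#' [hbond_model()] parameter block, with the well depth defaulting to
#' 4.0 kBT.
#'
#' @param estimate A [derive_cg_params()] result.
#' @param epsilon Well depth (kcal/mol).
#' @param ... Width/filter overrides passed to [hbond_model()].
#' @return An [hbond_model()].
#' @export
as_hbond_model <- function(estimate, epsilon = 4 * kBT(300), ...) {
  stopifnot(inherits(estimate, "cg_param_estimate"))
  r0 <- stats::median(vapply(estimate$params, `[[`, numeric(1), "r0"))
  th0 <- stats::median(vapply(estimate$params, `[[`, numeric(1), "theta0"))
  ph0 <- stats::median(vapply(estimate$params, `[[`, numeric(1), "phi0"))
  hbond_model(r0 = r0, theta0 = th0, phi0 = ph0, epsilon = epsilon, ...)
}

#' Standard donor/acceptor table
#'
#' Ships the default atomistic donor and acceptor atom-name table (standard
#' protein side-chain/backbone donors; DNA backbone O1P/O2P/O3'/O5'
#' acceptors).
#'
#' @return Data frame with columns `kind`, `residue`, `atom`.
#' @export
hb_donor_acceptor_table <- function() {
  fn <- system.file("extdata", "hb_donors_acceptors.tsv", package = "smcgo")
  utils::read.delim(fn, stringsAsFactors = FALSE)
}
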