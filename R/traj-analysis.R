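# Trajectory statistics: domain-DNA contact series, Q-scores, geometry
# observables, captured-loop and translocation step size, outcome
# classification, kleisin-path asymmetry, and ring-threading parity.

.DOMAIN_MAP <- list(
  kleisin = c("kleisin_ntd", "kleisin_linker", "kleisin_patch", "kleisin_ctd"),
  heads = c("head_blue", "head_red"),
  arm_hinge = c("arm_blue_hinge", "arm_red_hinge"),
  arm_mid = c("arm_blue_mid", "arm_red_mid"),
  arm_head = c("arm_blue_head", "arm_red_head"),
  hinge = "hinge"
)
.ARM_DOMAINS <- c("arm_hinge", "arm_mid", "arm_head")

#' Domain-DNA contacts in one frame
#'
#' Base pair `b` contacts protein domain `D` iff any bead of `b` is strictly
#' within `cutoff` of any bead of `D`.
#'
#' @param system An `smc_system` with DNA.
#' @param coords Frame coordinates.
#' @param cutoff Contact cutoff (A, default 10; strict `<`).
#' @return Named list per analysis domain (kleisin, heads, arm_hinge,
#'   arm_mid, arm_head, hinge) with elements `bp` (contacted base pairs) and
#'   `mean_bp` (NA when the set is empty).
#' @export
domain_dna_contacts <- function(system, coords = system$coords, cutoff = 10) {
  topo <- system$topology
  if (is.null(topo$domain)) stop("frame carries no domain labels")
  if (system$n_bp == 0) stop("system has no DNA")
  dom_id <- match(topo$domain, names(.DOMAIN_MAP))
  for (d in seq_along(.DOMAIN_MAP)) {
    dom_id[topo$domain %in% .DOMAIN_MAP[[d]]] <- d
  }
  prot <- which(topo$isdna == 0)
  dna <- which(topo$isdna == 1)
  m <- cg_contacts_frame(coords, prot, dom_id[prot], dna,
                         topo$base_index[dna], length(.DOMAIN_MAP),
                         system$n_bp, cutoff)
  out <- lapply(seq_along(.DOMAIN_MAP), function(d) {
    bp <- which(m[d, ])
    list(bp = bp, mean_bp = if (length(bp)) mean(bp) else NA_real_)
  })
  names(out) <- names(.DOMAIN_MAP)
  out
}

#' Per-frame domain-DNA contact series
#'
#' @param run An `smc_run` on a DNA-containing system.
#' @param cutoff Contact cutoff (A).
#' @return A data frame of class `contact_series` with columns `frame`,
#'   `step`, `segment`, `domain`, `n`, `mean_bp`.
#' @export
contact_series <- function(run, cutoff = 10) {
  nf <- n_frames(run)
  if (nf == 0) stop("run has no stored frames")
  rows <- vector("list", nf)
  for (k in seq_len(nf)) {
    cc <- domain_dna_contacts(run$system, frame_coords(run, k), cutoff)
    rows[[k]] <- data.frame(
      frame = k, step = run$frame_steps[k], segment = run$frame_segment[k],
      domain = names(cc),
      n = vapply(cc, function(z) length(z$bp), numeric(1)),
      mean_bp = vapply(cc, function(z) z$mean_bp, numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_series", "data.frame")
  out
}

cs_domain <- function(cs, dom, segment = NULL) {
  z <- cs[cs$domain %in% dom, , drop = FALSE]
  if (!is.null(segment)) z <- z[z$segment %in% segment, , drop = FALSE]
  z
}

# pooled per-frame mean bp of a domain set (frames where any member contacts)
pooled_mean_bp <- function(cs, dom, segment, frames = NULL) {
  z <- cs_domain(cs, dom, segment)
  if (!is.null(frames)) z <- z[z$frame %in% frames, , drop = FALSE]
  z <- z[z$n > 0, , drop = FALSE]
  if (!nrow(z)) return(list(frames = integer(0), mean = NA_real_,
                            per_frame = numeric(0)))
  agg <- tapply(z$mean_bp * z$n, z$frame, sum) / tapply(z$n, z$frame, sum)
  list(frames = as.integer(names(agg)), mean = mean(agg),
       per_frame = as.numeric(agg))
}

#' Captured DNA-loop size
#'
#' Absolute difference between the average base positions of DNA in contact
#' with the kleisin and with the coiled-coil arms over the final fraction of
#' the engaged segment (the averaging window scales with the schedule).
#'
#' @param run An `smc_run` containing an engaged segment.
#' @param cs Optional precomputed [contact_series()].
#' @param window Final fraction of the engaged segment to average (default
#'   0.2, i.e. the last 1e7 steps of a full 5e7-step segment).
#' @param cutoff Contact cutoff (A).
#' @return Loop size in base pairs (>= 0).
#' @export
loop_size <- function(run, cs = NULL, window = 0.2, cutoff = 10) {
  cs <- cs %||% contact_series(run, cutoff)
  seg <- which(run$schedule$state == "engaged")
  if (!length(seg)) stop_no_capture("run has no engaged segment")
  seg <- seg[length(seg)]
  frames_in <- unique(cs$frame[cs$segment == seg])
  if (!length(frames_in)) stop_no_capture("no frames in the engaged segment")
  win <- frames_in[frames_in >= stats::quantile(frames_in, 1 - window)]
  kle <- pooled_mean_bp(cs, "kleisin", seg, win)
  arm <- pooled_mean_bp(cs, .ARM_DOMAINS, seg, win)
  both <- intersect(kle$frames, arm$frames)
  if (!length(both)) {
    stop_no_capture("no engaged-window frame with both kleisin and arm contacts")
  }
  abs(mean(arm$per_frame[match(both, arm$frames)]) -
      mean(kle$per_frame[match(both, kle$frames)]))
}

stop_no_capture <- function(msg) {
  stop(structure(class = c("smcgo_no_capture", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Translocation step size
#'
#' Signed difference between the average kleisin-contacted base position in
#' the final disengaged segment (after pumping; final fraction `window`) and
#' in the first disengaged segment. Positive values point toward increasing
#' bp index.
#'
#' @inheritParams loop_size
#' @return Step size in base pairs (signed).
#' @export
step_size <- function(run, cs = NULL, window = 0.2, cutoff = 10) {
  cs <- cs %||% contact_series(run, cutoff)
  dis <- which(run$schedule$state == "disengaged")
  if (length(dis) < 2) {
    stop("run lacks initial and final disengaged segments")
  }
  first <- pooled_mean_bp(cs, "kleisin", dis[1])
  frames_in <- unique(cs$frame[cs$segment == dis[length(dis)]])
  win <- frames_in[frames_in >= stats::quantile(frames_in, 1 - window)]
  last <- pooled_mean_bp(cs, "kleisin", dis[length(dis)], win)
  if (!length(first$frames) || !length(last$frames)) {
    stop(structure(class = c("smcgo_undefined_step", "error", "condition"),
                   list(message = paste("kleisin contacts missing in a",
                                        "disengaged segment"),
                        call = sys.call())))
  }
  last$mean - first$mean
}

#' Classify the outcome of an ATP-cycle run
#'
#' Rule table over the contact series of a complete
#' disengaged-engaged-vshape-disengaged cycle:
#' `translocation` iff the DNA loop is maintained through the V-shape segment
#' and the kleisin-contact mean jumps by more than
#' `max(jump_min, jump_sd_mult * sd)` between the two disengaged segments;
#' `slippage` iff kleisin contact is continuous but the loop is lost;
#' `arm_trap` iff the final frames retain DNA-arm(mid) contacts without a
#' kleisin jump; `no_capture` iff no loop formed in the engaged state;
#' otherwise `incomplete`.
#'
#' @param run An `smc_run`.
#' @param cs Optional precomputed [contact_series()].
#' @param cutoff Contact cutoff (A).
#' @param jump_min Minimum discontinuous jump (bp, default 25).
#' @param jump_sd_mult Multiple of the within-first-segment standard
#'   deviation of the kleisin-contact mean (default 3).
#' @param loop_frac Minimum fraction of V-shape frames retaining the loop.
#' @return An object of class `translocation_report`.
#' @export
classify_outcome <- function(run, cs = NULL, cutoff = 10, jump_min = 25,
                             jump_sd_mult = 3, loop_frac = 0.5) {
  report <- function(outcome, loop = NA_real_, stp = NA_real_,
                     hinge = NA, reason = NULL, kmeans = NULL) {
    structure(list(outcome = outcome, loop_size_bp = loop, step_size_bp = stp,
                   hinge_reached = hinge, reason = reason,
                   segment_kleisin_bp = kmeans),
              class = "translocation_report")
  }
  states <- run$schedule$state
  complete <- length(states) >= 4 && states[1] == "disengaged" &&
    "engaged" %in% states && "vshape" %in% states &&
    states[length(states)] == "disengaged" && !run$blown
  if (!complete) {
    return(report("incomplete",
                  reason = if (run$blown) "dynamics blow-up"
                           else "truncated or non-cyclic schedule"))
  }
  cs <- cs %||% contact_series(run, cutoff)
  segs <- seq_len(nrow(run$schedule))
  kmeans <- vapply(segs, function(s) pooled_mean_bp(cs, "kleisin", s)$mean,
                   numeric(1))
  eng <- max(which(states == "engaged"))
  vsh <- max(which(states == "vshape"))
  hinge_reached <- any(cs$n[cs$segment == eng & cs$domain == "hinge"] > 0)

  loop <- tryCatch(loop_size(run, cs, cutoff = cutoff),
                   smcgo_no_capture = function(e) NA_real_)
  stp <- tryCatch(step_size(run, cs, cutoff = cutoff),
                  error = function(e) NA_real_)

  # loop maintained through vshape: frames with both kleisin and arm/hinge
  # contacts
  vframes <- unique(cs$frame[cs$segment == vsh])
  loop_frames <- vapply(vframes, function(f) {
    k <- any(cs$n[cs$frame == f & cs$domain == "kleisin"] > 0)
    a <- any(cs$n[cs$frame == f &
                    cs$domain %in% c(.ARM_DOMAINS, "hinge")] > 0)
    k && a
  }, logical(1))
  loop_maintained <- length(loop_frames) > 0 && mean(loop_frames) >= loop_frac

  k1 <- cs_domain(cs, "kleisin", segs[1])
  sd1 <- stats::sd(k1$mean_bp[k1$n > 0])
  thresh <- max(jump_min, jump_sd_mult * (if (is.finite(sd1)) sd1 else 0))
  jump <- is.finite(stp) && abs(stp) > thresh

  kle_frac <- mean(vapply(unique(cs$frame), function(f) {
    any(cs$n[cs$frame == f & cs$domain == "kleisin"] > 0)
  }, logical(1)))

  last_frames <- utils::tail(unique(cs$frame[cs$segment == max(segs)]), 3)
  arm_mid_end <- any(cs$n[cs$frame %in% last_frames &
                            cs$domain == "arm_mid"] > 0)

  outcome <- if (!is.na(loop) && loop_maintained && jump) {
    "translocation"
  } else if (!is.na(loop) && kle_frac >= 0.9 && !loop_maintained && !jump) {
    "slippage"
  } else if (!is.na(loop) && arm_mid_end && !jump) {
    "arm_trap"
  } else if (is.na(loop)) {
    "no_capture"
  } else {
    "incomplete"
  }
  report(outcome, loop = loop, stp = stp, hinge = hinge_reached,
         kmeans = kmeans,
         reason = if (outcome == "incomplete") "ambiguous contact pattern")
}

#' @export
print.translocation_report <- function(x, ...) {
  cat("outcome:", x$outcome)
  if (is.finite(x$loop_size_bp)) cat(sprintf(" | loop %.1f bp", x$loop_size_bp))
  if (is.finite(x$step_size_bp)) cat(sprintf(" | step %+.1f bp", x$step_size_bp))
  if (isTRUE(x$hinge_reached)) cat(" | hinge reached")
  cat("\n")
  invisible(x)
}

#' Q-score (fraction of native contacts formed)
#'
#' @param coords Frame coordinates.
#' @param contacts Data frame with columns `i`, `j`, `r0` (a subset of the
#'   topology's native-contact list).
#' @param factor Formation tolerance: a contact is formed when
#'   `r < factor * r0` (default 1.2).
#' @return Fraction in `[0, 1]`.
#' @export
q_score <- function(coords, contacts, factor = 1.2) {
  if (is.null(contacts) || nrow(contacts) == 0) {
    stop("empty contact group")
  }
  d <- sqrt(rowSums((coords[contacts$i, , drop = FALSE] -
                     coords[contacts$j, , drop = FALSE])^2))
  mean(d < factor * contacts$r0)
}

#' Native-contact subset of a system by group (optionally by arm third)
#'
#' @param system An `smc_system` or `smc_complex`.
#' @param group Contact group tag.
#' @param arm_third For `arm_arm_inter`: restrict to contacts whose beads lie
#'   in the given arm third ("hinge", "mid", "head").
#' @return Contact data frame.
#' @export
contact_group <- function(system, group, arm_third = NULL) {
  topo <- system$topology
  ct <- topo$contacts[topo$contacts$group == group, , drop = FALSE]
  if (!is.null(arm_third)) {
    keep <- topo$domain[ct$i] %in% paste0(c("arm_blue_", "arm_red_"), arm_third)
    ct <- ct[keep, , drop = FALSE]
  }
  ct
}

#' Q-score time series over a run
#'
#' @param run An `smc_run`.
#' @param group Contact group tag.
#' @param arm_third Optional arm third for `arm_arm_inter`.
#' @param factor Formation tolerance.
#' @return Data frame `frame`, `step`, `segment`, `q`.
#' @export
q_series <- function(run, group, arm_third = NULL, factor = 1.2) {
  ct <- contact_group(run$system, group, arm_third)
  nf <- n_frames(run)
  q <- vapply(seq_len(nf), function(k) q_score(frame_coords(run, k), ct,
                                               factor), numeric(1))
  data.frame(frame = seq_len(nf), step = run$frame_steps,
             segment = run$frame_segment, q = q)
}

#' Hinge opening angle
#'
#' Planar angle at the hinge centroid between the centroids of the 10-bead
#' middle windows of the two coiled-coil arms.
#'
#' @param system An `smc_system` or `smc_complex`.
#' @param coords Frame coordinates.
#' @return Angle in degrees.
#' @export
hinge_angle <- function(system, coords) {
  g <- system$groups
  p0 <- colMeans(coords[c(g$hinge_blue, g$hinge_red), , drop = FALSE])
  midwin <- function(arm) {
    mid <- round(length(arm) / 2)
    w <- arm[max(1, mid - 4):min(length(arm), mid + 5)]
    colMeans(coords[w, , drop = FALSE])
  }
  v1 <- midwin(g$arm_blue) - p0
  v2 <- midwin(g$arm_red) - p0
  if (vnorm(v1) < 1e-9 || vnorm(v2) < 1e-9) {
    stop("degenerate geometry: coincident points")
  }
  acos(max(-1, min(1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))) * 180 / pi
}

#' Head-to-head distance
#' @param system An `smc_system` or `smc_complex`.
#' @param coords Frame coordinates.
#' @return Distance between the two head-domain centroids (A).
#' @export
head_to_head <- function(system, coords) {
  g <- system$groups
  vnorm(colMeans(coords[g$head_blue, , drop = FALSE]) -
        colMeans(coords[g$head_red, , drop = FALSE]))
}

#' Spatial distribution of the kleisin DNA patch
#'
#' Aligns every frame's ATPase head dimer onto the engaged reference by
#' least-squares superposition and records the patch centroid. The front side
#' (positive y) is defined by the kleisin CTD attachment. The asymmetry score
#' is the fraction of frames on the majority side of the head plane.
#'
#' @param frames A 3D coordinate array (n x 3 x F), or an `smc_run`.
#' @param system An `smc_system` or `smc_complex` (taken from the run if
#'   omitted).
#' @param reference Reference conformation used for the alignment.
#' @return An object of class `patch_distribution` with fields `y`,
#'   `centroids`, `asymmetry` (in `[0.5, 1]`).
#' @export
patch_distribution <- function(frames, system = NULL, reference = "engaged") {
  if (inherits(frames, "smc_run")) {
    system <- system %||% frames$system
    frames <- frames$frames
  }
  cx <- if (inherits(system, "smc_system")) system$complex else system
  ref <- reference_conformation(cx, reference)
  g <- system$groups
  heads <- c(g$head_blue, g$head_red)
  patch <- g$kleisin_patch
  nf <- dim(frames)[3]
  cent <- matrix(NA_real_, nf, 3)
  for (k in seq_len(nf)) {
    xyz <- frames[, , k]
    if (max(apply(xyz[heads, , drop = FALSE], 2, stats::sd)) < 1e-9) {
      stop("alignment failure: degenerate head coordinates")
    }
    fit <- kabsch_fit(xyz, ref, heads)
    cent[k, ] <- colMeans(fit(xyz[patch, , drop = FALSE]))
  }
  y <- cent[, 2]
  structure(list(y = y, centroids = cent,
                 asymmetry = max(mean(y > 0), mean(y <= 0))),
            class = "patch_distribution")
}

#' @export
print.patch_distribution <- function(x, ...) {
  cat(sprintf("patch distribution: %d frames, asymmetry %.3f (front fraction %.3f)\n",
              length(x$y), x$asymmetry, mean(x$y > 0)))
  invisible(x)
}

#' Ring-threading parity test
#'
#' Counts crossings of the DNA centerline through a triangulated surface
#' spanning the closed protein ring polygon; odd parity means the DNA is
#' topologically threaded.
#'
#' @param system An `smc_system` with DNA.
#' @param coords Frame coordinates.
#' @param ring `"kleisin"` or `"smc"`.
#' @return List with `crossings` and `threaded`.
#' @export
threading_check <- function(system, coords = system$coords,
                            ring = c("kleisin", "smc")) {
  ring <- match.arg(ring)
  if (system$n_bp == 0) stop("system has no DNA")
  idx <- ring_path(system, ring)
  poly <- coords[idx, , drop = FALSE]
  centroid <- colMeans(poly)
  np <- nrow(poly)
  tri <- matrix(NA_real_, np, 9)
  for (t in seq_len(np)) {
    p1 <- poly[t, ]; p2 <- poly[if (t == np) 1 else t + 1, ]
    tri[t, ] <- c(centroid, p1, p2)
  }
  dna_idx <- which(system$topology$isdna == 1)
  topo <- list(kind = system$topology$kind[dna_idx],
               base_index = system$topology$base_index[dna_idx])
  line <- dna_centerline(topo, coords[dna_idx, , drop = FALSE])
  cr <- cg_polyline_crossings(line, tri)
  list(crossings = cr, threaded = cr %% 2 == 1)
}

#' Moving average of a per-residue charge profile
#'
#' Centered moving average with an odd window; window ends are truncated to
#' the available residues.
#'
#' @param charges Numeric per-residue charges.
#' @param window Odd window size (default 5).
#' @return Smoothed profile of the same length.
#' @export
moving_average_charge <- function(charges, window = 5) {
  if (window %% 2 == 0) stop("window must be odd")
  if (window > length(charges)) stop("window exceeds profile length")
  h <- (window - 1) / 2
  n <- length(charges)
  vapply(seq_len(n), function(i) {
    mean(charges[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}
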