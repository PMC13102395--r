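# Three-site-per-nucleotide duplex DNA builder (base, sugar, phosphate beads
# on an idealized B-form helix; the 5'-terminal phosphate is omitted on each
# strand). The duplex is held together by an elastic network fitted to the
# built geometry -- a declared simplification with no sequence-dependent
# stacking or base-pairing energetics.

.DNA_SIGMA <- 4
.DNA_EN_CUTOFF <- 8    # elastic-network pair cutoff (A)
.DNA_EN_K <- 2         # elastic-network spring constant (kcal/mol/A^2)

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' The 47-bp duplex used for the head-DNA hydrogen-bond study
#'
#' @return The 47-nucleotide sequence string (strand 1, 5'->3').
#' @export
dna_47bp_sequence <- function() {
  fn <- system.file("extdata", "dna_47bp.fasta", package = "smcgo")
  read_fasta_sequence(fn)
}

#' Build an idealized B-form DNA duplex
#'
#' @param sequence Strand-1 sequence (5'->3', ACGT; whitespace tolerated), or
#'   `NULL` to generate a random sequence of `n_bp` base pairs from `seed`.
#' @param n_bp Number of base pairs when `sequence` is `NULL`.
#' @param rise Helical rise per base pair (Angstrom, default 3.4).
#' @param twist Helical twist per base pair (degrees, default 34.3).
#' @param seed Seed for the random sequence.
#' @return An object of class `dna_duplex`.
#' @export
build_dna <- function(sequence = NULL, n_bp = NULL, rise = 3.4, twist = 34.3,
                      seed = 1L) {
  if (is.null(sequence)) {
    if (is.null(n_bp) || n_bp < 2) stop("n_bp must be >= 2")
    sequence <- with_seed(seed, paste(sample(names(.COMPLEMENT), n_bp,
                                             replace = TRUE), collapse = ""))
  }
  sequence <- toupper(gsub("\\s", "", sequence))
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% names(.COMPLEMENT))
  if (length(bad)) {
    stop(sprintf("non-ACGT character '%s' at position %d", chars[bad[1]],
                 bad[1]))
  }
  n <- length(chars)
  if (n < 2) stop("n_bp must be >= 2")
  comp <- unname(.COMPLEMENT[chars])

  tw <- twist * pi / 180
  helix_bead <- function(i, ang_off, radius, strand) {
    chi <- (i - 1) * tw + if (strand == 1) ang_off else pi - ang_off
    c(radius * cos(chi), radius * sin(chi), (i - 1) * rise)
  }
  coords <- list(); kind <- character(0); residue <- character(0)
  bidx <- integer(0); strand <- integer(0)
  emit <- function(i, s) {
    if ((s == 1 && i > 1) || (s == 2 && i < n)) {
      coords[[length(coords) + 1]] <<- helix_bead(i, 0.00, 8.9, s)
      kind <<- c(kind, "phosphate")
      residue <<- c(residue, if (s == 1) chars[i] else comp[i])
      bidx <<- c(bidx, i); strand <<- c(strand, s)
    }
    coords[[length(coords) + 1]] <<- helix_bead(i, 30 * pi / 180, 6.9, s)
    coords[[length(coords) + 1]] <<- helix_bead(i, 55 * pi / 180, 2.5, s)
    kind <<- c(kind, "sugar", "base")
    residue <<- c(residue, rep(if (s == 1) chars[i] else comp[i], 2))
    bidx <<- c(bidx, i, i); strand <<- c(strand, s, s)
  }
  for (i in seq_len(n)) emit(i, 1)       # strand 1, 5'->3' (bp 1..n)
  for (i in rev(seq_len(n))) emit(i, 2)  # strand 2, 5'->3'  (bp n..1)
  coords <- do.call(rbind, coords)
  nb <- nrow(coords)
  stopifnot(nb == 2 * (3 * n - 1))

  # elastic network: all bead pairs within cutoff and at most 2 bp apart
  bonds <- dna_network(coords, bidx)
  # near-diagonal duplex pairs (|d bp| <= 4) are governed by the elastic
  # network; exclude them from excluded-volume/electrostatic terms
  excl <- dna_near_pairs(bidx, 4)

  topo <- list(n = nb, kind = kind, residue = residue,
               chain = ifelse(strand == 1, "D", "E"),
               base_index = bidx, strand = strand,
               sigma = rep(.DNA_SIGMA, nb),
               charge = ifelse(kind == "phosphate", -0.6, 0),
               charge_pd = ifelse(kind == "phosphate", -1.0, 0),
               bonds = bonds, excl_extra = excl)
  structure(list(sequence = sequence, sequence_strand2 = paste(rev(comp),
                                                               collapse = ""),
                 n_bp = n, rise = rise, twist = twist,
                 topology = topo, coords = coords),
            class = "dna_duplex")
}

dna_near_pairs <- function(bidx, window) {
  acc <- vector("list", max(bidx))
  for (b in sort(unique(bidx))) {
    cand <- which(bidx >= b & bidx <= b + window)
    own <- cand[bidx[cand] == b]
    g <- expand.grid(i = own, j = cand)
    ij <- cbind(pmin(g$i, g$j), pmax(g$i, g$j))
    acc[[b]] <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
  }
  ij <- unique(do.call(rbind, acc))
  data.frame(i = ij[, 1], j = ij[, 2])
}

dna_network <- function(coords, bidx) {
  acc <- vector("list", max(bidx))
  for (b in sort(unique(bidx))) {
    cand <- which(bidx >= b & bidx <= b + 2)
    own <- cand[bidx[cand] == b]
    g <- expand.grid(i = own, j = cand)
    ij <- cbind(pmin(g$i, g$j), pmax(g$i, g$j))
    ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
    acc[[b]] <- ij
  }
  ij <- unique(do.call(rbind, acc))
  g <- data.frame(i = ij[, 1], j = ij[, 2])
  d <- sqrt(rowSums((coords[g$i, , drop = FALSE] -
                     coords[g$j, , drop = FALSE])^2))
  keep <- d < .DNA_EN_CUTOFF
  data.frame(i = g$i[keep], j = g$j[keep], r0 = d[keep], k = .DNA_EN_K)
}

#' Per-base-pair centerline of a duplex
#'
#' Midpoints of the two base beads of each pair, ordered by bp index; used as
#' the DNA axis polyline for ring-threading tests.
#'
#' @param topology A topology list carrying `kind`, `base_index`.
#' @param coords Coordinates matching the topology.
#' @return An `n_bp x 3` matrix.
#' @export
dna_centerline <- function(topology, coords) {
  base <- which(topology$kind == "base")
  bp <- topology$base_index[base]
  ubp <- sort(unique(bp))
  t(vapply(ubp, function(b) colMeans(coords[base[bp == b], , drop = FALSE]),
           numeric(3)))
}

#' @export
print.dna_duplex <- function(x, ...) {
  cat("B-form DNA duplex:", x$n_bp, "bp,", x$topology$n, "beads",
      sprintf("(rise %.2f A/bp, twist %.1f deg/bp)\n", x$rise, x$twist))
  invisible(x)
}
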