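# File formats: coarse-grained PDB (one ATOM record per bead, charge in the
# occupancy column), DCD trajectories, FASTA sequences, JSON run configs.

.AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
          H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
          P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
          W = "TRP", Y = "TYR")

#' Write a coarse-grained structure as PDB
#'
#' One ATOM record per bead. Chains: A/B = SMC subunits, C = kleisin, D/E =
#' DNA strands. The occupancy column carries the bead charge; the B-factor
#' column carries the DNA base-pair index (0 for protein beads).
#'
#' @param system An `smc_system`, `smc_complex` or bare topology list.
#' @param file Output path.
#' @param coords Coordinates (defaults to the system's / the disengaged
#'   reference).
#' @return The file path, invisibly.
#' @export
write_cg_pdb <- function(system, file, coords = NULL) {
  if (inherits(system, "smc_complex")) {
    topo <- system$topology
    coords <- coords %||% reference_conformation(system, "disengaged")
  } else {
    topo <- system$topology
    coords <- coords %||% system$coords
  }
  kind <- topo$kind
  atom <- c(ca = "CA", base = "B", sugar = "S", phosphate = "P")[kind]
  res3 <- ifelse(kind == "ca", .AA3[topo$residue],
                 paste0("D", topo$residue))
  charge <- topo$charge %||% rep(0, topo$n)
  bidx <- topo$base_index
  bidx[is.na(bidx)] <- 0
  resseq <- resseq_by_chain(topo)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.1f",
    seq_len(topo$n) %% 100000, atom, res3, topo$chain,
    resseq %% 10000, coords[, 1], coords[, 2], coords[, 3],
    charge, bidx %% 1000)
  writeLines(c(lines, "END"), file)
  invisible(file)
}

resseq_by_chain <- function(topo) {
  out <- integer(topo$n)
  for (ch in unique(topo$chain)) {
    idx <- which(topo$chain == ch)
    if (topo$kind[idx[1]] == "ca") {
      out[idx] <- seq_along(idx)
    } else {
      # DNA: residue number = nucleotide ordinal along the strand
      out[idx] <- cumsum(c(1, diff(match(topo$base_index[idx],
                                         unique(topo$base_index[idx]))) != 0))
    }
  }
  out
}

#' Read a coarse-grained PDB written by [write_cg_pdb()]
#'
#' @param file Path.
#' @return List with `coords`, `chain`, `atom`, `residue3`, `charge`,
#'   `base_index`.
#' @export
read_cg_pdb <- function(file) {
  ln <- readLines(file)
  ln <- ln[startsWith(ln, "ATOM")]
  list(
    coords = cbind(as.numeric(substr(ln, 31, 38)),
                   as.numeric(substr(ln, 39, 46)),
                   as.numeric(substr(ln, 47, 54))),
    chain = substr(ln, 22, 22),
    atom = trimws(substr(ln, 13, 16)),
    residue3 = trimws(substr(ln, 18, 20)),
    charge = as.numeric(substr(ln, 55, 60)),
    base_index = as.numeric(substr(ln, 61, 66))
  )
}

#' Write a trajectory as (CHARMM-style) DCD
#'
#' @param frames 3D coordinate array (n x 3 x F) or an `smc_run`.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_dcd <- function(frames, file) {
  if (inherits(frames, "smc_run")) frames <- frames$frames
  n <- dim(frames)[1]; nf <- dim(frames)[3]
  con <- file(file, "wb")
  on.exit(close(con))
  wblock <- function(writer) {
    # Fortran unformatted record: length prefix/suffix
    raw <- writer()
    writeBin(as.integer(length(raw)), con, size = 4, endian = "little")
    writeBin(raw, con)
    writeBin(as.integer(length(raw)), con, size = 4, endian = "little")
  }
  hdr <- raw(84)
  hdr[1:4] <- charToRaw("CORD")
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1; icntrl[3] <- 1; icntrl[4] <- nf
  icntrl[20] <- 24
  hdr[5:84] <- writeBin(as.integer(icntrl), raw(), size = 4,
                        endian = "little")
  wblock(function() hdr)
  title <- sprintf("%-80s", "smcgo coarse-grained trajectory")
  wblock(function() c(writeBin(1L, raw(), size = 4, endian = "little"),
                      charToRaw(title)))
  wblock(function() writeBin(as.integer(n), raw(), size = 4,
                             endian = "little"))
  for (k in seq_len(nf)) {
    for (d in 1:3) {
      wblock(function() writeBin(as.numeric(frames[, d, k]), raw(), size = 4,
                                 endian = "little"))
    }
  }
  invisible(file)
}

#' Read a DCD trajectory written by [write_dcd()]
#'
#' @param file Path.
#' @return 3D coordinate array (n x 3 x F).
#' @export
read_dcd <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  rblock <- function() {
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    raw <- readBin(con, "raw", len)
    readBin(con, "integer", 1, size = 4, endian = "little")
    raw
  }
  hdr <- rblock()
  nf <- readBin(hdr[5:8], "integer", 1, size = 4, endian = "little")
  rblock()  # title
  n <- readBin(rblock(), "integer", 1, size = 4, endian = "little")
  out <- array(NA_real_, c(n, 3, nf))
  for (k in seq_len(nf)) {
    for (d in 1:3) {
      out[, d, k] <- readBin(rblock(), "numeric", n, size = 4,
                             endian = "little")
    }
  }
  out
}

#' Read the first sequence from a FASTA file
#'
#' @param file Path to a FASTA file.
#' @return Upper-case sequence string.
#' @export
read_fasta_sequence <- function(file) {
  ln <- readLines(file)
  ln <- ln[!grepl("^[>;]", ln)]
  toupper(gsub("\\s", "", paste(ln, collapse = "")))
}

#' Assemble a run configuration
#'
#' @param complex [complex_spec()] fields (list).
#' @param dna List with `n_bp` or `sequence`, and optional `seed`.
#' @param offset_bp Threading offset (bp); `NULL` for a protein-only run.
#' @param schedule_scale Global schedule scale factor.
#' @param ionic_strength_mM 150 or 300 mM presets (any positive value
#'   accepted).
#' @param seed Master seed.
#' @param stride Frame stride (`NULL`: automatic).
#' @param dh_cutoff Electrostatics cutoff (A).
#' @return A `run_config` list.
#' @export
run_config <- function(complex = list(), dna = list(n_bp = 250),
                       offset_bp = 125, schedule_scale = 1e-3,
                       ionic_strength_mM = 300, seed = 1L, stride = NULL,
                       dh_cutoff = 25) {
  cfg <- list(complex = complex, dna = dna, offset_bp = offset_bp,
              schedule_scale = schedule_scale,
              ionic_strength_mM = ionic_strength_mM, seed = seed,
              stride = stride, dh_cutoff = dh_cutoff)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as JSON
#' @param cfg A [run_config()].
#' @param file Path.
#' @return `write_config`: the path; `read_config`: the configuration.
#' @export
write_config <- function(cfg, file) {
  jsonlite::write_json(unclass(cfg), file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  cfg$stride <- cfg$stride %||% NULL
  class(cfg) <- "run_config"
  cfg
}

#' Stable hash of a configuration
#' @param cfg A [run_config()].
#' @return MD5 hex string.
#' @export
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]  # canonical: drop NULL fields
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}
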