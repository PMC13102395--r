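# Internal helpers shared across modules.

# Boltzmann constant in kcal/mol/K and Coulomb constant in kcal*A/mol/e^2.
.kB <- 0.0019872041
.COULOMB <- 332.0637
.AVOGADRO_A3 <- 6.02214076e-4  # particles per A^3 for a 1 mol/L solution

#' Thermal energy at a given temperature
#'
#' @param temperature Temperature in Kelvin.
#' @return kB*T in kcal/mol.
#' @export
kBT <- function(temperature = 300) .kB * temperature

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) v / vnorm(v)

# Rotation matrix for angle (radians) about an arbitrary unit axis.
rot_axis <- function(axis, angle) {
  u <- unitv(axis)
  c1 <- cos(angle); s1 <- sin(angle); t1 <- 1 - c1
  matrix(c(
    c1 + u[1]^2 * t1, u[1] * u[2] * t1 - u[3] * s1, u[1] * u[3] * t1 + u[2] * s1,
    u[2] * u[1] * t1 + u[3] * s1, c1 + u[2]^2 * t1, u[2] * u[3] * t1 - u[1] * s1,
    u[3] * u[1] * t1 - u[2] * s1, u[3] * u[2] * t1 + u[1] * s1, c1 + u[3]^2 * t1
  ), nrow = 3, byrow = TRUE)
}

# Rotate rows of `coords` (subset `idx`) about `axis` through `origin`.
rotate_about <- function(coords, idx, origin, axis, angle) {
  R <- rot_axis(axis, angle)
  sub <- coords[idx, , drop = FALSE]
  sub <- sweep(sub, 2, origin)
  sub <- sub %*% t(R)
  coords[idx, ] <- sweep(sub, 2, origin, `+`)
  coords
}

# Least-squares superposition (Kabsch). Returns function mapping coords onto ref
# frame, fitted on the rows `idx`.
kabsch_fit <- function(coords, ref, idx) {
  X <- coords[idx, , drop = FALSE]
  Y <- ref[idx, , drop = FALSE]
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- t(sweep(X, 2, cx)) %*% sweep(Y, 2, cy)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  function(m) sweep(sweep(m, 2, cx) %*% t(R), 2, cy, `+`)
}

# Evaluate with a temporary R RNG state so package simulations do not disturb
# the caller's random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a bounded child seed from a parent seed and a stream index.
child_seed <- function(seed, k) {
  ((as.numeric(seed) %% 2147483647) * 48271 + 7919 * k) %% 2147483629 + 1
}

# Walk a finely sampled 3D curve (m x 3 matrix) placing `n` beads at equal
# chord length `a`, starting from the first row. Returns the bead coordinates.
walk_chords <- function(curve, n, a) {
  pts <- matrix(NA_real_, n, 3)
  cur <- curve[1, ]
  seg <- 1
  m <- nrow(curve)
  for (b in seq_len(n)) {
    # advance along the polyline until a point at distance a from `cur`
    found <- FALSE
    while (seg < m) {
      p0 <- curve[seg, ]; p1 <- curve[seg + 1, ]
      # solve |p0 + t(p1-p0) - cur| = a for t in (t_lo, 1]
      d <- p1 - p0
      f <- p0 - cur
      A <- sum(d^2); B <- 2 * sum(f * d); C <- sum(f^2) - a^2
      disc <- B^2 - 4 * A * C
      if (A > 0 && disc >= 0) {
        t1 <- (-B + sqrt(disc)) / (2 * A)
        if (t1 >= 0 && t1 <= 1 && sum((p0 + t1 * d - cur)^2) > 0) {
          cur <- p0 + t1 * d
          pts[b, ] <- cur
          found <- TRUE
          break
        }
      }
      seg <- seg + 1
    }
    if (!found) {
      # ran off the end of the curve: continue along last direction
      dirv <- unitv(curve[m, ] - curve[m - 1, ])
      cur <- cur + a * dirv
      pts[b, ] <- cur
    }
  }
  pts
}

# Densely resample a piecewise-linear path given waypoints, with an added
# y-meander (sign of `amp` picks the side) so the total contour can be tuned.
# Returns an m x 3 matrix.
meander_curve <- function(waypoints, amp, lobes = 4, m = 2000) {
  segs <- diff(waypoints)
  lens <- sqrt(rowSums(segs^2))
  total <- sum(lens)
  s <- seq(0, total, length.out = m)
  cum <- c(0, cumsum(lens))
  base <- matrix(NA_real_, m, 3)
  for (i in seq_len(m)) {
    k <- findInterval(s[i], cum, rightmost.closed = TRUE)
    k <- min(k, nrow(segs))
    t1 <- (s[i] - cum[k]) / lens[k]
    base[i, ] <- waypoints[k, ] + t1 * segs[k, ]
  }
  tt <- s / total
  # one-sided lobes (sin^2) by default; a negative `lobes` requests
  # alternating sides (plain sin), used for very long chains whose drawn
  # conformation should resemble a compact coil rather than one giant lobe
  if (lobes > 0) {
    base[, 2] <- base[, 2] + amp * sin(lobes * pi * tt)^2
  } else {
    base[, 2] <- base[, 2] + amp * sin(-lobes * pi * tt)
  }
  base
}

curve_length <- function(curve) sum(sqrt(rowSums(diff(curve)^2)))

# Place an n-bead chain of spacing ~a between fixed endpoints A and B along a
# waypoint path, tuning the meander amplitude so that the chain contour fits.
# `ydir` picks the meander side (+1 front, -1 mirrored). Used for the
# disordered kleisin linker in every reference conformation.
place_linker <- function(A, B, waypoints, n, a, lobes = 4, ydir = 1) {
  wp <- rbind(A, waypoints, B)
  target <- (n + 1) * a
  base_len <- curve_length(meander_curve(wp, 0, lobes))
  if (base_len >= target) {
    # path already long enough: no meander, just walk it
    curve <- meander_curve(wp, 0, lobes)
    return(walk_chords(curve, n, a))
  }
  f <- function(amp) curve_length(meander_curve(wp, ydir * amp, lobes)) - target
  amp0 <- stats::uniroot(f, c(0, 4 * target / lobes), tol = 1e-8)$root
  # refine the amplitude so that walking chords of exactly `a` closes the
  # chain onto B (all bond rest lengths then equal the bead spacing in every
  # conformation)
  g <- function(amp) {
    pts <- walk_chords(meander_curve(wp, ydir * amp, lobes), n, a)
    vnorm(pts[n, ] - B) - a
  }
  amp <- tryCatch(
    stats::uniroot(g, c(0.6 * amp0, 1.5 * amp0), tol = 1e-10)$root,
    error = function(e) amp0)
  pts <- walk_chords(meander_curve(wp, ydir * amp, lobes), n, a)
  # spread any residual closure error smoothly along the chain (each bond
  # changes by at most |delta|/n)
  pstar <- B + a * unitv(pts[n, ] - B)
  delta <- pstar - pts[n, ]
  pts + outer(seq_len(n) / n, delta)
}
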