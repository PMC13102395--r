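test_that("domain-DNA contacts: empty far away, exact sets nearby, strict
           cutoff", {
  cx <- mini_complex()
  dna <- build_dna(n_bp = 120, seed = 2)
  sys <- thread_dna(cx, dna, 60)
  # DNA displaced 300 A away: all sets empty
  far <- sys$coords
  far[sys$topology$isdna == 1, 1] <- far[sys$topology$isdna == 1, 1] + 300
  cc <- domain_dna_contacts(sys, far)
  expect_true(all(vapply(cc, function(z) length(z$bp) == 0, logical(1))))
  expect_true(all(is.na(vapply(cc, function(z) z$mean_bp, numeric(1)))))

  # constructed frame: bp 50-60 placed within cutoff of the kleisin patch only
  x <- far
  patch <- sys$groups$kleisin_patch
  pc <- colMeans(x[patch, , drop = FALSE])
  dn <- which(sys$topology$isdna == 1)
  for (b in 50:60) {
    sel <- dn[sys$topology$base_index[dn] == b]
    x[sel, ] <- matrix(pc + c(3 * (b - 55), 5, 0), length(sel), 3,
                       byrow = TRUE) +
      matrix(rnorm(3 * length(sel), sd = 0.1), ncol = 3)
  }
  cc2 <- domain_dna_contacts(sys, x)
  expect_equal(cc2$kleisin$mean_bp, 55)
  expect_setequal(cc2$kleisin$bp, 50:60)

  # brute-force pair-scan oracle for the full contact map
  cutoff <- 10
  prot <- which(sys$topology$isdna == 0)
  oracle <- lapply(smcgo:::.DOMAIN_MAP, function(doms) {
    pb <- prot[sys$topology$domain[prot] %in% doms]
    d <- smcgo:::proxy_dist(x[pb, , drop = FALSE], x[dn, , drop = FALSE])
    sort(unique(sys$topology$base_index[dn][colSums(d < cutoff) > 0]))
  })
  got <- lapply(cc2, `[[`, "bp")
  expect_identical(got, oracle)

  # a bead at exactly the cutoff distance does not count (strict <):
  # approach the outermost blue-head corner from outside the complex
  x3 <- far
  hb <- sys$groups$head_blue
  don <- hb[which.min(x3[hb, 1])]
  sel <- dn[sys$topology$base_index[dn] == 1][1]
  x3[sel, ] <- x3[don, ] + c(-10, 0, 0)
  expect_false(1 %in% domain_dna_contacts(sys, x3)$heads$bp)
  x3[sel, ] <- x3[don, ] + c(-(10 - 1e-9), 0, 0)
  expect_true(1 %in% domain_dna_contacts(sys, x3)$heads$bp)
})

test_that("q_score: reference 1, far 0, half-formed 0.5, empty errors", {
  cx <- mini_complex()
  x <- reference_conformation(cx, "disengaged")
  ct <- contact_group(cx, "head_head_disengaged")
  expect_equal(q_score(x, ct), 1)
  expect_equal(q_score(x * 10, ct), 0)
  # constructed frame with exactly half the contacts formed (synthetic pairs)
  ct2 <- data.frame(i = 1:4, j = 5:8, r0 = 5)
  xs <- matrix(0, 8, 3)
  xs[5:8, 1] <- c(5, 5, 50, 50)
  xs[1:4, 2] <- (1:4) * 1e-9
  expect_equal(q_score(xs, ct2), 0.5)
  expect_error(q_score(x, ct[0, ]), "empty")
})

test_that("hinge angle: collinear 180, perpendicular 90, matches the
           vector-math oracle", {
  cx <- mini_complex()
  g <- cx$groups
  x <- reference_conformation(cx, "disengaged")
  # construct collinear arm-middle centroids around the hinge centroid
  p0 <- colMeans(x[c(g$hinge_blue, g$hinge_red), , drop = FALSE])
  place_arm <- function(x, arm, target) {
    mid <- round(length(arm) / 2)
    w <- arm[max(1, mid - 4):min(length(arm), mid + 5)]
    x[w, ] <- sweep(x[w, , drop = FALSE], 2,
                    colMeans(x[w, , drop = FALSE]) - target, `-`)
    x
  }
  xc <- place_arm(x, g$arm_blue, p0 + c(10, 0, 0))
  xc <- place_arm(xc, g$arm_red, p0 - c(7, 0, 0))
  expect_equal(hinge_angle(cx, xc), 180)
  xp <- place_arm(x, g$arm_blue, p0 + c(10, 0, 0))
  xp <- place_arm(xp, g$arm_red, p0 + c(0, 8, 0))
  expect_equal(hinge_angle(cx, xp), 90)
  set.seed(5)
  v1 <- rnorm(3); v2 <- rnorm(3)
  xr <- place_arm(x, g$arm_blue, p0 + v1)
  xr <- place_arm(xr, g$arm_red, p0 + v2)
  oracle <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(hinge_angle(cx, xr), oracle, tolerance = 1e-9)
  xd <- place_arm(x, g$arm_blue, p0)
  expect_error(hinge_angle(cx, xd), "degenerate")
})

test_that("loop size estimator matches the arithmetic oracle", {
  run <- fake_run()
  frames <- data.frame(frame = 1:40, segment = rep(1:4, each = 10))
  frames$kleisin <- 100
  frames$arms <- NA
  frames$arms[frames$segment == 2] <- 300
  frames$hinge <- NA
  cs <- fake_contact_series(frames)
  expect_equal(loop_size(run, cs), 200)
  frames$arms[frames$segment == 2] <- 100
  expect_equal(loop_size(run, fake_contact_series(frames)), 0)
  frames$arms <- NA
  expect_error(loop_size(run, fake_contact_series(frames)),
               class = "smcgo_no_capture")
})

test_that("step size estimator is the signed difference of kleisin means", {
  run <- fake_run()
  frames <- data.frame(frame = 1:40, segment = rep(1:4, each = 10),
                       kleisin = c(rep(350, 10), rep(400, 20), rep(520, 10)),
                       arms = NA, hinge = NA)
  expect_equal(step_size(run, fake_contact_series(frames)), 170)
  frames$kleisin <- 400
  expect_equal(step_size(run, fake_contact_series(frames)), 0)
  frames$kleisin[frames$segment == 4] <- NA
  expect_error(step_size(run, fake_contact_series(frames)), "kleisin")
})

test_that("outcome rule table: translocation, slippage, no_capture,
           incomplete", {
  run <- fake_run()
  base <- data.frame(frame = 1:40, segment = rep(1:4, each = 10))
  # translocation: loop held through vshape + 200-bp kleisin jump
  tr <- base
  tr$kleisin <- c(rep(400, 30), rep(600, 10))
  tr$arms <- c(rep(NA, 10), rep(600, 20), rep(NA, 10))
  tr$hinge <- NA
  rep1 <- classify_outcome(run, fake_contact_series(tr))
  expect_equal(rep1$outcome, "translocation")
  expect_equal(rep1$loop_size_bp, 200)
  expect_equal(rep1$step_size_bp, 200)
  # brute-force oracle for the same numbers
  expect_equal(rep1$step_size_bp, mean(tr$kleisin[31:40]) -
                 mean(tr$kleisin[1:10]))
  expect_equal(rep1$loop_size_bp, abs(600 - 400))

  # slippage: kleisin drifts continuously, loop vanishes in vshape
  sl <- base
  sl$kleisin <- seq(400, 420, length.out = 40)
  sl$arms <- c(rep(NA, 10), rep(500, 10), rep(NA, 20))
  sl$hinge <- NA
  expect_equal(classify_outcome(run, fake_contact_series(sl))$outcome,
               "slippage")

  # no engaged-state arm contacts at all -> no_capture
  nc <- base
  nc$kleisin <- 400
  nc$arms <- NA
  nc$hinge <- NA
  expect_equal(classify_outcome(run, fake_contact_series(nc))$outcome,
               "no_capture")

  # truncated run
  expect_equal(classify_outcome(fake_run(states = c("disengaged", "engaged")),
                                fake_contact_series(nc[1:20, ]))$outcome,
               "incomplete")
  expect_equal(classify_outcome(fake_run(blown = TRUE),
                                fake_contact_series(nc))$outcome,
               "incomplete")
})

test_that("patch distribution: one-sided 1.0, mirrored ensemble 0.5", {
  cx <- mini_complex()
  sys <- as_system(cx)
  ref <- reference_conformation(cx, "engaged")
  patch <- cx$groups$kleisin_patch
  nf <- 12
  frames <- array(rep(ref, nf), c(nrow(ref), 3, nf))
  set.seed(1)
  for (k in seq_len(nf)) {
    frames[patch, 2, k] <- abs(frames[patch, 2, k]) + runif(1, 0, 5)
  }
  pd <- patch_distribution(frames, sys)
  expect_equal(pd$asymmetry, 1)
  # ensemble plus its mirror image
  mirror <- frames
  mirror[, 2, ] <- -mirror[, 2, ]
  both <- array(c(frames, mirror), c(nrow(ref), 3, 2 * nf))
  pdm <- patch_distribution(both, sys)
  expect_equal(pdm$asymmetry, 0.5)
  expect_true(pd$asymmetry >= 0.5 && pd$asymmetry <= 1)
  # degenerate heads
  bad <- frames
  bad[c(cx$groups$head_blue, cx$groups$head_red), , ] <- 0
  expect_error(patch_distribution(bad, sys), "degenerate")
})

test_that("threading parity: threaded by construction, not threaded outside,
           hairpin touching is not threaded", {
  cx <- mini_complex()
  dna <- build_dna(n_bp = 120, seed = 2)
  sys <- thread_dna(cx, dna, 60)
  expect_true(threading_check(sys, sys$coords, "kleisin")$threaded)
  out <- sys$coords
  dn <- which(sys$topology$isdna == 1)
  out[dn, 1] <- out[dn, 1] + 500
  expect_false(threading_check(sys, out, "kleisin")$threaded)
  # hairpin: fold the DNA so it enters and exits through the same face
  hp <- sys$coords
  yy <- hp[dn, 2]
  hp[dn, 2] <- pmin(yy, 60 - (yy - 60))  # reflect beyond y = 60
  ck <- threading_check(sys, hp, "kleisin")
  expect_false(ck$threaded)
  # brute-force segment-triangle oracle on the same hairpin
  idx <- ring_path(sys, "kleisin")
  poly <- hp[idx, , drop = FALSE]
  centroid <- colMeans(poly)
  line <- dna_centerline(list(kind = sys$topology$kind[dn],
                              base_index = sys$topology$base_index[dn]),
                         hp[dn, , drop = FALSE])
  brute <- 0
  seg_tri <- function(p, q, a, b, c) {
    d <- q - p; e1 <- b - a; e2 <- c - a
    pv <- c(d[2] * e2[3] - d[3] * e2[2], d[3] * e2[1] - d[1] * e2[3],
            d[1] * e2[2] - d[2] * e2[1])
    det <- sum(e1 * pv)
    if (abs(det) < 1e-12) return(FALSE)
    tv <- p - a
    u <- sum(tv * pv) / det
    if (u < 0 || u > 1) return(FALSE)
    qv <- c(tv[2] * e1[3] - tv[3] * e1[2], tv[3] * e1[1] - tv[1] * e1[3],
            tv[1] * e1[2] - tv[2] * e1[1])
    v <- sum(d * qv) / det
    if (v < 0 || u + v > 1) return(FALSE)
    tt <- sum(e2 * qv) / det
    tt >= 0 && tt < 1
  }
  for (s in seq_len(nrow(line) - 1)) {
    for (t in seq_len(nrow(poly))) {
      a <- centroid; b <- poly[t, ]; cc <- poly[if (t == nrow(poly)) 1 else t + 1, ]
      if (seg_tri(line[s, ], line[s + 1, ], a, b, cc)) brute <- brute + 1
    }
  }
  expect_equal(ck$crossings, brute)
  expect_equal(ck$threaded, brute %% 2 == 1)
})

test_that("moving-average charge profile", {
  expect_equal(moving_average_charge(rep(1, 5), 5)[3], 1)
  expect_equal(moving_average_charge(rep(0, 7), 5), rep(0, 7))
  expect_equal(moving_average_charge(c(0, 0, 1, 0, 0), 5)[3], 0.2)
  # ends truncated to the available residues
  expect_equal(moving_average_charge(c(1, 0, 0, 0, 0), 5)[1], 1 / 3)
  expect_error(moving_average_charge(1:10, 4), "odd")
  expect_error(moving_average_charge(1:3, 5), "length")
})
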