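test_that("native-contact closed form: minimum, decay, spot value", {
  expect_equal(native_contact_energy(2, 2, eps = 3), -3)
  expect_lt(abs(native_contact_energy(20, 2, eps = 1)), 1e-9)
  # independent arithmetic oracle at r = 1.2 r0
  s <- 1 / 1.2
  expect_equal(native_contact_energy(1.2, 1, 1), 5 * s^12 - 6 * s^10)
  expect_equal(round(native_contact_energy(1.2, 1, 1), 4), -0.4083)
  expect_error(native_contact_energy(-1, 2), "domain")
})

test_that("Debye length matches the standard closed form", {
  # oracle: lambda = sqrt(eps0 epsr kB T / (2 e^2 NA I)) evaluated via the
  # Bjerrum-length route with independent constants
  lB <- 1.671e-5 / (78 * 1.380649e-23 * 300) * 1e10 * (1.602177e-19)^2 / 1e10
  lB <- (1.602177e-19)^2 / (4 * pi * 8.854188e-12 * 78 * 1.380649e-23 * 300) * 1e10
  n150 <- 0.15 * 6.02214076e23 / 1e27  # per A^3
  lam_oracle <- 1 / sqrt(8 * pi * lB * n150)
  expect_lt(abs(debye_length(150) - lam_oracle), 0.02)
  expect_equal(round(debye_length(150), 1), 7.9)
  # doubling the ionic strength scales lambda by 1/sqrt(2)
  expect_equal(debye_length(300), debye_length(150) / sqrt(2), tolerance = 1e-12)
  expect_error(debye_length(0), "positive")
})

test_that("Debye-Huckel energy: closed form below cutoff, exactly 0 beyond", {
  ff <- ff_params(ionic_strength_mM = 150, dh_cutoff = 30)
  expect_equal(debye_huckel_energy(0, 1, 5, ff), 0)
  lam <- debye_length(150)
  r <- 6.5
  u_oracle <- 332.0637 / 78 * (exp(-r / lam) / r - exp(-30 / lam) / 30)
  expect_equal(debye_huckel_energy(1, 1, r, ff), u_oracle, tolerance = 1e-12)
  expect_identical(debye_huckel_energy(1, 1, 30, ff), 0)
  expect_identical(debye_huckel_energy(1, -1, 45, ff), 0)
  expect_error(ff_params(ionic_strength_mM = -10), "positive")
})

test_that("hydrogen-bond term: depth, radial factor, hard zero, grid minimum", {
  m <- hbond_model()
  expect_equal(hbond_energy(m$r0, m$theta0, m$phi0, m), -4 * kBT(300))
  expect_equal(round(hbond_energy(m$r0, m$theta0, m$phi0, m), 3), -2.385)
  expect_equal(hbond_energy(m$r0 + m$sigma_r, m$theta0, m$phi0, m),
               -m$epsilon * exp(-0.5), tolerance = 1e-12)
  expect_identical(hbond_energy(m$r0 + 3 * m$sigma_r + 1e-9, m$theta0, 0, m), 0)
  expect_identical(hbond_energy(m$r0 - 3 * m$sigma_r - 1e-9, m$theta0, 0, m), 0)
  # grid search confirms the global minimum sits at (r0, theta0)
  gr <- expand.grid(r = seq(3, 15, by = 0.1), th = seq(0, 180, by = 1))
  u <- hbond_energy(gr$r, gr$th, 0, m)
  expect_equal(min(u), -m$epsilon, tolerance = 1e-6)
  best <- gr[which.min(u), ]
  expect_lt(abs(best$r - m$r0), 0.11)
  expect_lt(abs(best$th - m$theta0), 2.1)
  # finite-width dihedral factor peaks at phi0
  mf <- hbond_model(sigma_phi = 60)
  expect_equal(hbond_energy(mf$r0, mf$theta0, mf$phi0, mf), -mf$epsilon)
  expect_lt(abs(hbond_energy(mf$r0, mf$theta0, mf$phi0 + 60, mf)),
            abs(hbond_energy(mf$r0, mf$theta0, mf$phi0, mf)))
  expect_error(hbond_model(sigma_r = -1), "widths")
})

test_that("state activation tables follow the nucleotide-state rules", {
  eng <- make_state_potential("engaged")
  expect_equal(eng$head_scale, 2)
  expect_true(eng$hbond_active)
  expect_true(eng$flex_active)
  expect_true("head_head_engaged" %in% eng$active_groups)
  expect_false("head_head_disengaged" %in% eng$active_groups)

  vsh <- make_state_potential("vshape")
  expect_false(any(grepl("head_head", vsh$active_groups)))
  expect_false(vsh$hbond_active)
  expect_true(vsh$flex_active)

  di <- make_state_potential("disengaged", "initial")
  expect_false("arm_arm_inter" %in% di$active_groups)
  df <- make_state_potential("disengaged", "final")
  expect_true("arm_arm_inter" %in% df$active_groups)
  expect_true("head_head_disengaged" %in% df$active_groups)
  expect_error(make_state_potential("open"), "arg")
})

test_that("charge assignment follows the dual phosphate convention", {
  cx <- mini_complex()
  dna <- build_dna(n_bp = 30, seed = 3)
  # lysine +1, glycine 0
  expect_equal(unname(smcgo:::default_charges("K", "ca")), 1)
  expect_equal(unname(smcgo:::default_charges("G", "ca")), 0)
  expect_error(smcgo:::default_charges("Z", "ca"), "unknown residue")
  # phosphate pair products by class
  ph <- which(dna$topology$kind == "phosphate")
  expect_equal(unique(dna$topology$charge[ph]), -0.6)
  expect_equal(unique(dna$topology$charge_pd[ph]), -1.0)
  expect_equal(dna$topology$charge[ph][1] * dna$topology$charge[ph][2], 0.36)
  # custom table override
  sys <- as_system(cx)
  cm <- assign_charges(sys, table = c(K = 2))
  expect_equal(max(cm$q), 2)
})

test_that("reference energies: bonded terms zero, contacts at minima,
           components sum to the total", {
  cx <- mini_complex()
  sys <- as_system(cx)
  e <- total_energy(sys, state = "disengaged")
  expect_lt(abs(e$bond), 1e-14)
  expect_lt(abs(e$angle), 1e-14)
  expect_lt(abs(e$dihedral), 1e-14)
  # native contacts all at their minima: energy = -sum(eps) over active groups
  ct <- cx$topology$contacts
  act <- ct[ct$group %in% make_state_potential("disengaged")$active_groups, ]
  expect_equal(e$native_contact, -sum(act$eps), tolerance = 1e-9)
  # with all eps = 1, native_contact = -N
  sys1 <- sys
  sys1$topology$contacts$eps <- 1
  e1 <- total_energy(sys1, state = "disengaged")
  expect_equal(e1$native_contact, -nrow(act), tolerance = 1e-9)
  # bookkeeping invariant
  comp_sum <- e$bond + e$angle + e$dihedral + e$native_contact +
    e$excluded_volume + e$electrostatic + e$hbond
  expect_lt(abs(e$total - comp_sum), 1e-9 * max(1, abs(e$total)))
  expect_error(total_energy(sys, sys$coords * NA), "finite")
})

test_that("forces match central finite differences in all states", {
  sys <- fifty_bead_system()
  ref <- sys$coords
  set.seed(42)
  h <- 1e-5
  for (st in c("disengaged", "engaged", "vshape")) {
    x <- ref + matrix(rnorm(length(ref), sd = 0.3), ncol = 3)
    f <- forces(sys, x, state = st)
    for (t in 1:12) {
      i <- sample(nrow(x), 1); d <- sample(3, 1)
      xp <- x; xp[i, d] <- xp[i, d] + h
      xm <- x; xm[i, d] <- xm[i, d] - h
      num <- -(total_energy(sys, xp, st)$total -
                 total_energy(sys, xm, st)$total) / (2 * h)
      expect_lt(abs(num - f[i, d]) / max(1, abs(num)), 1e-4)
    }
    # Newton's third law: zero net force
    expect_lt(max(abs(colSums(f))), 1e-8)
  }
})

test_that("energy is invariant under rigid-body motion", {
  sys <- fifty_bead_system()
  set.seed(7)
  x <- sys$coords + matrix(rnorm(length(sys$coords), sd = 0.2), ncol = 3)
  e0 <- total_energy(sys, x, "engaged")$total
  xt <- sweep(x, 2, c(13.2, -7.1, 4.4), `+`)
  expect_lt(abs(total_energy(sys, xt, "engaged")$total - e0), 1e-9)
  R <- smcgo:::rot_axis(c(1, 2, 3), 0.83)
  xr <- sweep(x, 2, colMeans(x)) %*% t(R)
  xr <- sweep(xr, 2, colMeans(x), `+`)
  expect_lt(abs(total_energy(sys, xr, "engaged")$total - e0), 1e-8)
})

test_that("switching to the engaged landscape lowers the engaged-group
           contact energy after relaxation", {
  cx <- mini_complex()
  sys <- as_system(cx)
  e0 <- total_energy(sys, state = "engaged")$native_contact_by_group
  run <- run_schedule(sys, state_schedule("engaged", 8000),
                      dynamics_params(seed = 4, stride = 8000),
                      energies = FALSE)
  e1 <- total_energy(sys, run$final$coords,
                     state = "engaged")$native_contact_by_group
  expect_lt(e1[["head_head_engaged"]], e0[["head_head_engaged"]])
})
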