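test_that("Baker-Hubbard criteria with strict boundaries", {
  # donor D, hydrogen H, acceptor A placed at controlled geometry
  mk <- function(r, theta_deg) {
    th <- theta_deg * pi / 180
    rbind(D = c(-1, 0, 0), H = c(0, 0, 0),
          A = r * c(cos(pi - th), sin(pi - th), 0))
  }
  tri <- hb_triples(1, 2, 3, residue = "R62")
  expect_true(detect_hbonds(mk(2.4, 150), tri))
  expect_false(detect_hbonds(mk(2.5, 150), tri))   # strict distance
  expect_false(detect_hbonds(mk(2.0, 110), tri))   # angle criterion
  expect_false(detect_hbonds(mk(2.0, 120), tri))   # strict angle
  expect_true(detect_hbonds(mk(2.0, 121), tri))
  expect_error(hb_triples(1, 1, 3, "x"), "distinct")
  expect_error(detect_hbonds(mk(2, 150), hb_triples(1, 2, 9, "x")),
               "missing atom")
})

test_that("detect_hbonds agrees exactly with a brute-force geometric oracle", {
  set.seed(99)
  n <- 60
  coords <- matrix(rnorm(3 * n, sd = 2), n, 3)
  raw <- data.frame(d = sample(n, 1400, TRUE), h = sample(n, 1400, TRUE),
                    a = sample(n, 1400, TRUE))
  raw <- raw[raw$d != raw$h & raw$d != raw$a & raw$h != raw$a, ][1:1000, ]
  tri <- hb_triples(raw$d, raw$h, raw$a,
                    residue = sample(letters, 1000, TRUE))
  got <- detect_hbonds(coords, tri)
  brute <- vapply(seq_len(nrow(tri)), function(t) {
    H <- coords[tri$hydrogen[t], ]; D <- coords[tri$donor[t], ]
    A <- coords[tri$acceptor[t], ]
    r <- sqrt(sum((A - H)^2))
    ang <- acos(sum((D - H) * (A - H)) /
                  (sqrt(sum((D - H)^2)) * r)) * 180 / pi
    r < 2.5 && ang > 120
  }, logical(1))
  expect_identical(got, brute)
})

test_that("bond fractions recover planted occupancy and count series", {
  set.seed(11)
  nf <- 400
  # two residues: one bonds in every frame, one with planted 50% occupancy
  traj <- lapply(seq_len(nf), function(k) {
    on2 <- runif(1) < 0.5
    rbind(c(-1, 0, 0), c(0, 0, 0), c(2.0, 0.5, 0),          # res A: always
          c(10, 0, 0), c(11, 0, 0),
          if (on2) c(13, 0.3, 0) else c(16, 0, 0))          # res B: 50%
  })
  tri <- hb_triples(c(1, 4), c(2, 5), c(3, 6), residue = c("A", "B"))
  bf <- bond_fractions(traj, tri, cut = 0)
  expect_equal(unname(bf$fractions["A"]), 1)
  expect_lt(abs(bf$fractions["B"] - 0.5), 3 * sqrt(0.25 / nf))
  expect_equal(length(bf$counts), nf)
  expect_true(all(bf$counts %in% 1:2))
  # the equilibration cut can remove all bonding frames
  off <- traj[[1]]
  off[c(3, 6), 1] <- off[c(3, 6), 1] + 100  # move the acceptors away
  traj0 <- c(traj[1:10], lapply(1:10, function(k) off))
  bf0 <- bond_fractions(traj0, tri, cut = 10)
  expect_equal(unname(bf0$fractions["A"]), 0)
  expect_error(bond_fractions(traj, tri, cut = nf), "cut")
})

test_that("residue selection: fraction > 0.05, descending, top 15", {
  fr <- setNames(seq(0.9, 0.06, length.out = 18), paste0("r", 1:18))
  sel <- select_hb_residues(fr)
  expect_length(sel, 15)
  expect_equal(sel[1], "r1")
  expect_identical(select_hb_residues(setNames(rep(0.05, 8), letters[1:8])),
                   character(0))
  expect_identical(select_hb_residues(setNames(c(0.05, 0.051), c("a", "b"))),
                   "b")
})

test_that("coarse-grained parameters recover planted histogram peaks", {
  set.seed(21)
  mk_samples <- function() list(r = rnorm(1500, 6.0, 0.12),
                                theta = rnorm(1500, 100, 4),
                                phi = rnorm(1500, 40, 5))
  est <- derive_cg_params(list(R62 = mk_samples(), K56 = mk_samples()),
                          bin_r = 0.1, bin_theta = 5, bin_phi = 5)
  for (p in est$params) {
    expect_lte(abs(p$r0 - 6.0), 0.1)
    expect_lte(abs(p$theta0 - 100), 5)
    expect_lte(abs(p$phi0 - 40), 5)
    expect_false(p$peakless)
  }
  # degenerate inputs
  expect_warning(
    derive_cg_params(list(u = list(r = runif(500, 4, 8),
                                   theta = runif(500, 0, 180),
                                   phi = runif(500, -180, 180)))),
    "peakless")
  one <- suppressWarnings(derive_cg_params(list(s = list(
    r = rep(6.2, 150), theta = rep(90, 150), phi = rep(10, 150)))))
  expect_equal(one$params$s$r0, 6.2, tolerance = 0.051)
  expect_error(derive_cg_params(list(few = list(r = 1:5, theta = 1:5,
                                                phi = 1:5))),
               "too few")
})

test_that("pipeline closure: derived parameters place the CG minimum at the
           planted geometry", {
  set.seed(31)
  samples <- list(R1 = list(r = rnorm(1500, 7.5, 0.12),
                            theta = rnorm(1500, 120, 4),
                            phi = rnorm(1500, 0, 5)))
  est <- derive_cg_params(samples, bin_r = 0.1, bin_theta = 5, bin_phi = 5)
  hm <- as_hbond_model(est)
  gr <- expand.grid(r = seq(4, 12, by = 0.05), th = seq(60, 180, by = 1))
  u <- hbond_energy(gr$r, gr$th, 0, hm)
  best <- gr[which.min(u), ]
  expect_lt(abs(best$r - 7.5), 0.1)    # within one r bin
  expect_lt(abs(best$th - 120), 5)     # within one theta bin
  expect_equal(min(u), -4 * kBT(300), tolerance = 1e-3)
})

test_that("the shipped donor/acceptor table loads", {
  tab <- hb_donor_acceptor_table()
  expect_true(all(c("kind", "residue", "atom") %in% names(tab)))
  expect_true("NZ" %in% tab$atom[tab$residue == "LYS"])
  expect_true(all(c("O1P", "O2P") %in% tab$atom[tab$kind == "acceptor"]))
})
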