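test_that("kleisin linker carries 63 disordered residues at x = 0", {
  cx <- build_toy_complex(complex_spec(beads_per_arm = 12))
  linker <- sum(cx$topology$domain %in% c("kleisin_linker", "kleisin_patch"))
  expect_equal(linker, 63)
  expect_equal(sum(cx$topology$domain == "kleisin_patch"), 5)
})

test_that("disengaged reference is an I-shape with juxtaposed arms", {
  cx <- mini_complex()
  x <- reference_conformation(cx, "disengaged")
  g <- cx$groups
  d <- sqrt(rowSums((x[g$arm_blue, ] - x[g$arm_red, ])^2))
  expect_lt(mean(d), 2 * cx$spec$bead_spacing)
})

test_that("arm contour length is beads_per_arm x bead_spacing", {
  cx <- build_toy_complex(complex_spec(beads_per_arm = 130, bead_spacing = 3.8))
  x <- reference_conformation(cx, "disengaged")
  arm <- cx$groups$arm_blue
  # oracle: direct summation of inter-bead distances along the arm
  contour <- sum(sqrt(rowSums(diff(x[arm, ])^2)))
  expect_lte(abs(contour - 494), cx$spec$bead_spacing + 1e-9)
  expect_equal(cx$spec$arm_contour_length, 494)
})

test_that("reference conformations share one topology and satisfy the state
           invariants", {
  cx <- mini_complex()
  xd <- reference_conformation(cx, "disengaged")
  xe <- reference_conformation(cx, "engaged")
  xv <- reference_conformation(cx, "vshape")
  expect_equal(dim(xd), dim(xe))
  expect_equal(dim(xd), dim(xv))
  # engaged: arms separated (O-shape drawing)
  g <- cx$groups
  sep_d <- mean(sqrt(rowSums((xd[g$arm_blue, ] - xd[g$arm_red, ])^2)))
  sep_e <- mean(sqrt(rowSums((xe[g$arm_blue, ] - xe[g$arm_red, ])^2)))
  expect_gt(sep_e, 3 * sep_d)
  # vshape: head-to-head distance larger than disengaged
  expect_gt(head_to_head(cx, xv), head_to_head(cx, xd))
  # every bead has exactly one domain label from the closed set
  labels <- c("head_blue", "head_red", "hinge", "kleisin_ntd", "kleisin_ctd",
              "kleisin_linker", "kleisin_patch",
              paste0("arm_blue_", c("hinge", "mid", "head")),
              paste0("arm_red_", c("hinge", "mid", "head")))
  expect_true(all(cx$topology$domain %in% labels))
})

test_that("bonded rest values are geometry-consistent", {
  cx <- mini_complex()
  tb <- cx$topology
  kle <- sort(unlist(cx$groups[c("kleisin_ntd", "kleisin_linker",
                                 "kleisin_patch", "kleisin_ctd")]))
  ang_val <- function(x, a) {
    v1 <- x[a$i, ] - x[a$j, ]; v2 <- x[a$k, ] - x[a$j, ]
    acos(pmin(pmax(rowSums(v1 * v2) /
                     (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2))), -1), 1))
  }
  for (st in c("disengaged", "engaged", "vshape")) {
    x <- reference_conformation(cx, st)
    d <- sqrt(rowSums((x[tb$bonds$i, ] - x[tb$bonds$j, ])^2))
    lk <- tb$bonds$i %in% kle | tb$bonds$j %in% kle
    # bonds: exact everywhere except the redrawn disordered linker (within
    # the redraw tolerance)
    expect_lt(max(abs(d - tb$bonds$r0)[!lk]), 1e-9)
    expect_lt(max(abs(d - tb$bonds$r0)[lk]), 0.15)
  }
  # angles and dihedrals are defined from (and exact in) the disengaged
  # reference
  xd <- reference_conformation(cx, "disengaged")
  expect_lt(max(abs(ang_val(xd, tb$angles) - tb$angles$th0)), 1e-9)
  dih <- tb$dihedrals
  phv <- vapply(seq_len(nrow(dih)), function(r) {
    smcgo:::dihedral_angle(xd[dih$i[r], ], xd[dih$j[r], ], xd[dih$k[r], ],
                           xd[dih$l[r], ])
  }, numeric(1))
  expect_lt(max(abs(phv - dih$ph0)), 1e-9)
  # in engaged/vshape the only angle terms that differ are the flexible
  # hinge-arm junction triples (plus redrawn-linker-adjacent terms, of which
  # the kleisin has none since the linker carries no angles)
  for (st in c("engaged", "vshape")) {
    x <- reference_conformation(cx, st)
    dev <- abs(ang_val(x, tb$angles) - tb$angles$th0)
    arm_any <- grepl("^arm", cx$topology$domain[tb$angles$i]) |
      grepl("^arm", cx$topology$domain[tb$angles$j]) |
      grepl("^arm", cx$topology$domain[tb$angles$k])
    # acos conditioning amplifies rotation roundoff near 180 deg
    ok <- dev < 1e-5 | tb$angles$flex |
      (st == "engaged" & arm_any)  # engaged arm arcs are a drawing choice
    expect_true(all(ok))
  }
})

test_that("builder is deterministic and rejects degenerate counts", {
  a <- build_toy_complex(mini_spec(seed = 5))
  b <- build_toy_complex(mini_spec(seed = 5))
  expect_identical(a$conformations, b$conformations)
  expect_error(complex_spec(beads_per_arm = 2), "closed ring")
  expect_error(complex_spec(hinge_beads = 3), "hinge_beads")
  expect_error(complex_spec(kleisin_linker_residues = 3), "closed ring")
  expect_error(complex_spec(linker_repeats_x = 11), "0, 10")
  expect_error(complex_spec(beads_per_arm = 10, arm_contour_length = 60),
               "within")
})

test_that("insert_linker adds 5x GGGGS beads per side and preserves the patch", {
  cx0 <- build_toy_complex(complex_spec(beads_per_arm = 12))
  expect_identical(insert_linker(cx0, 0), cx0)
  cx8 <- insert_linker(cx0, 8)
  expect_equal(cx8$topology$n - cx0$topology$n, 80)
  cx4 <- insert_linker(cx0, 4)
  expect_equal(sum(cx4$topology$domain == "kleisin_patch"),
               sum(cx0$topology$domain == "kleisin_patch"))
  expect_equal(sum(cx4$topology$domain == "kleisin_linker") -
                 sum(cx0$topology$domain == "kleisin_linker"), 40)
  ins <- setdiff(seq_len(cx4$topology$n), 0)
  expect_true(all(cx4$topology$charge[cx4$topology$domain ==
                                        "kleisin_linker"] == 0))
  expect_error(insert_linker(cx0, -1), "0, 10")
})

test_that("mirrored kleisin attachment mirrors the patch distribution", {
  cx <- mini_complex()
  cm <- mini_complex(mirror_kleisin = TRUE)
  for (st in c("disengaged", "engaged", "vshape")) {
    y <- mean(reference_conformation(cx, st)[cx$groups$kleisin_patch, 2])
    ym <- mean(reference_conformation(cm, st)[cm$groups$kleisin_patch, 2])
    expect_lt(abs(y + ym), 1e-6)
    expect_gt(abs(y), 1)
  }
})
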