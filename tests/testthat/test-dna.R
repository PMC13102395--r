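test_that("the packaged 47-bp sequence builds the expected duplex", {
  seqn <- dna_47bp_sequence()
  d <- build_dna(seqn)
  expect_equal(d$n_bp, 47)
  expect_equal(d$topology$n, 280)  # 2 * (3*47 - 1)
  expect_equal(sum(d$topology$strand == 1), 3 * 47 - 1)
  expect_equal(sum(d$topology$kind == "phosphate"), 2 * 46)
})

test_that("strand 2 is the reverse complement; AT is self-complementary", {
  d <- build_dna("AT")
  expect_equal(d$sequence_strand2, "AT")
  d2 <- build_dna("GGCA")
  expect_equal(d2$sequence_strand2, "TGCC")
  expect_equal(unique(d2$topology$base_index[d2$topology$strand == 2]),
               4:1)
})

test_that("consecutive-bp rise matches the configured value exactly", {
  d <- build_dna(n_bp = 20, rise = 3.4, seed = 2)
  s1 <- which(d$topology$strand == 1 & d$topology$kind == "sugar")
  z <- d$coords[s1, 3]
  expect_lt(max(abs(diff(z) - 3.4)), 1e-6)
  d2 <- build_dna(n_bp = 10, rise = 3.2, seed = 2)
  z2 <- d2$coords[which(d2$topology$strand == 1 &
                          d2$topology$kind == "sugar"), 3]
  expect_lt(max(abs(diff(z2) - 3.2)), 1e-6)
})

test_that("invalid sequences are rejected with the offending position", {
  expect_error(build_dna("ACGX"), "position 4")
  expect_error(build_dna("ACGU"), "'U'")
  expect_error(build_dna(n_bp = 1), ">= 2")
  # whitespace tolerated
  expect_equal(build_dna("AC GT\nAC")$n_bp, 6)
})

test_that("random sequences are reproducible from the seed", {
  expect_identical(build_dna(n_bp = 30, seed = 9)$sequence,
                   build_dna(n_bp = 30, seed = 9)$sequence)
  expect_false(identical(build_dna(n_bp = 30, seed = 9)$sequence,
                         build_dna(n_bp = 30, seed = 10)$sequence))
})

test_that("elastic network respects the bp window and rest lengths", {
  d <- build_dna(n_bp = 12, seed = 1)
  b <- d$topology$bonds
  dbp <- abs(d$topology$base_index[b$i] - d$topology$base_index[b$j])
  expect_true(all(dbp <= 2))
  dist <- sqrt(rowSums((d$coords[b$i, ] - d$coords[b$j, ])^2))
  expect_lt(max(abs(dist - b$r0)), 1e-9)
})
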