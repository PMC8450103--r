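test_that("DP equals exhaustive enumeration on random tiny models", {
  set.seed(11)
  for (i in 1:8) {
    m <- random_tiny_model()
    for (j in 1:25) {
      sq <- random_tiny_seq()
      dp <- score_sequence(m, sq, mode = "global", want_parse = FALSE)$score
      or <- oracle_global(m, sq)
      if (is.infinite(or)) expect_lt(dp, -1e29)
      else expect_equal(dp, or, tolerance = 1e-9)
    }
  }
})

test_that("local DP equals enumeration over all subsequences", {
  set.seed(12)
  for (i in 1:4) {
    m <- random_tiny_model()
    for (j in 1:6) {
      sq <- random_tiny_seq(6)
      dp <- score_sequence(m, sq, mode = "local", want_parse = FALSE)$score
      expect_equal(dp, oracle_local(m, sq), tolerance = 1e-9)
    }
  }
})

test_that("score decomposes exactly into primary + secondary", {
  set.seed(13)
  for (i in 1:10) {
    sq <- sample_sequence(TINY)
    p <- score_sequence(TINY, as.character(sq), mode = "global")
    d <- decompose_score(p, TINY)
    expect_equal(unname(d[1] + d[2]), p$score, tolerance = 1e-9)
    expect_equal(p$primary_bits + p$secondary_bits, p$score,
                 tolerance = 1e-9)
  }
})

test_that("an all-N sequence scores with zero emission contribution", {
  p <- score_sequence(TINY, strrep("N", TINY$clen), mode = "global")
  # no pair can contribute covariation when every residue is ambiguous
  expect_equal(p$secondary_bits, 0, tolerance = 1e-9)
  # and the score must not depend on which emissions would be made:
  # an all-N parse scores transitions and slot costs only, so swapping in a
  # model with permuted emissions changes nothing
  expect_equal(p$score, p$primary_bits, tolerance = 1e-9)
})

test_that("a model trained on covarying pairs has positive secondary score", {
  m <- FS$registry$Ala
  sq <- sample_sequence(m, rng_seed = 5)
  p <- score_sequence(m, as.character(sq), mode = "global")
  expect_gt(p$secondary_bits, 0)
})

test_that("a pair-free model has zero secondary score", {
  m <- train_cm(seed_alignment(c("a", "b"), c("ACGTT", "ACGTA"), "....."))
  p <- score_sequence(m, "ACGTT", mode = "global")
  expect_equal(p$secondary_bits, 0)
})

test_that("empty sequences have a defined all-delete global score", {
  p <- score_sequence(TINY, "", mode = "global")
  expect_true(is.finite(p$score))
  expect_true(all(is.na(p$colpos)))
})

test_that("scoring is deterministic", {
  sq <- paste0("TT", "GGGCAAAGCCC", "AAG")
  p1 <- score_sequence(TINY, sq, mode = "local")
  p2 <- score_sequence(TINY, sq, mode = "local")
  expect_identical(p1$score, p2$score)
  expect_identical(p1$colpos, p2$colpos)
  expect_identical(c(p1$begin, p1$end), c(p2$begin, p2$end))
})

test_that("5'-truncated sequences at a boundary are flagged trunc5", {
  m <- FS$registry$Gly
  sq <- as.character(sample_sequence(m, rng_seed = 21))
  trunc <- substr(sq, 16, nchar(sq))  # first 15 nt missing, at seq start
  p <- score_sequence(m, trunc, mode = "local", allow_trunc = TRUE)
  expect_true(p$trunc5)
  expect_equal(p$begin, 0)
  # truncation must beat paying full deletion penalties
  p0 <- score_sequence(m, trunc, mode = "local", allow_trunc = FALSE)
  expect_gt(p$score, p0$score)
  # free-deleted columns are marked, not silently dropped
  expect_gt(sum(attr(p$colpos, "free")), 0)
})

test_that("3'-truncated sequences at a boundary are flagged trunc3", {
  m <- FS$registry$Gly
  sq <- as.character(sample_sequence(m, rng_seed = 22))
  trunc <- substr(sq, 1, nchar(sq) - 15)
  p <- score_sequence(m, trunc, mode = "local", allow_trunc = TRUE)
  expect_true(p$trunc3)
  expect_equal(p$end, nchar(trunc))
})

test_that("marginalization preserves column count and concentrates mass", {
  m <- TINY
  lp <- marginalize(m)
  expect_equal(lp$clen, m$clen)
  # model with no pairs: identical emissions
  m0 <- train_cm(seed_alignment(c("a", "b"), c("ACG", "ACG"), "..."))
  expect_equal(marginalize(m0)$e, m0$esingle)
  # a pair table concentrated on G:C gives marginals on G (left), C (right)
  mp <- train_cm(seed_alignment(paste0("s", 1:6), rep("GAC", 6), "<.>"))
  v <- which(mp$ntype == 3L)
  expect_equal(which.max(mp$esingle[mp$lcol[v], ]), 3L)  # G
  expect_equal(which.max(mp$esingle[mp$rcol[v], ]), 2L)  # C
})
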