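test_that("single-column Laplace log-odds match hand-computed values", {
  # one row, one unpaired column 'A', pseudocount 1, uniform background:
  # bits(A) = log2((2/5)/0.25), bits(C) = log2((1/5)/0.25)
  m <- train_cm(seed_alignment("s1", "A", "."))
  expect_equal(m$esingle[1, 1], log2((2 / 5) / 0.25), tolerance = 1e-12)
  expect_equal(m$esingle[1, 2], log2((1 / 5) / 0.25), tolerance = 1e-12)
})

test_that("pair Laplace log-odds match hand-computed values", {
  # one row with pair G:C -> bits(GC) = log2((2/17)/0.0625)
  m <- train_cm(seed_alignment("s1", "GAC", "<.>"))
  v <- which(m$ntype == 3L)
  # column-major indexing: left residue fastest; G=2, C=1 (0-based)
  expect_equal(m$epair[v, 2 + 4 * 1 + 1], log2((2 / 17) / 0.0625),
               tolerance = 1e-12)
})

test_that("majority-gap columns are excluded from the consensus", {
  a <- seed_alignment(c("a", "b", "c"),
                      c("A-CG", "A-CG", "ATCG"), "....")
  m <- train_cm(a)
  expect_equal(m$clen, 3)  # column 2 is 2/3 gaps -> insert-modeled
})

test_that("training without consensus columns errors", {
  expect_error(train_cm(seed_alignment(c("a", "b"), c("--", "AC"), "..")),
               "training error")
})

test_that("implied emission probabilities renormalize to 1", {
  m <- FS$registry$Ala
  expect_true(all(abs(rowSums(m$singleprob) - 1) < 1e-9))
  pp <- m$pairprob[m$ntype == 3L, , drop = FALSE]
  expect_true(all(abs(rowSums(pp) - 1) < 1e-9))
  # transitions are log2 probabilities normalized over each node's states
  for (v in which(m$ntype == 1L)) {
    expect_equal(sum(2^m$tr[v, 1:2]), 1, tolerance = 1e-9)
  }
  for (v in which(m$ntype == 3L)) {
    expect_equal(sum(2^m$tr[v, ]), 1, tolerance = 1e-9)
  }
})

test_that("anticodon masking replaces exactly the marked columns", {
  a <- FS$seeds$nuclear$Ala
  b <- mask_anticodons(a)
  cols <- which(strsplit(a$ac_line, "")[[1]] == "*")
  for (r in c(1, 5, 20)) {
    expect_equal(substr(b$rows[r], cols[1], cols[3]), "NNN")
    # everything else unchanged
    expect_equal(substr(b$rows[r], 1, cols[1] - 1),
                 substr(a$rows[r], 1, cols[1] - 1))
  }
  # idempotent
  expect_true(mask_anticodons(b) == b)
})

test_that("anticodon masking keeps gaps and warns when unmarked", {
  a <- seed_alignment(c("a", "b"), c("AAC-TAA", "AACATAA"), ".......",
                      ac_line = "...***.")
  b <- mask_anticodons(a)
  expect_equal(b$rows[1], "AAC-NNA")  # gap retained, others masked
  expect_equal(b$rows[2], "AACNNNA")
  a2 <- seed_alignment(c("a"), c("AACTT"), ".....")
  expect_warning(m <- mask_anticodons(a2), "no anticodon")
  expect_true(m == a2)
})

test_that("strand symmetry: mirrored model scores mirrored sequences equally", {
  a <- seed_alignment(c("a", "b", "c"),
                      c("GGCATAGCC", "GGCAAAGCC", "GGCATTGCC"),
                      "<<<...>>>")
  rc_rows <- vapply(a$rows, revcomp, character(1))
  a_rc <- seed_alignment(a$ids, unname(rc_rows), "<<<...>>>")
  m <- train_cm(a); m_rc <- train_cm(a_rc)
  for (sq in c("GGCATAGCC", "GGCAAAGCCA", "ACGTACGT")) {
    expect_equal(score_sequence(m, sq, mode = "global")$score,
                 score_sequence(m_rc, revcomp(sq), mode = "global")$score,
                 tolerance = 1e-9)
  }
})

test_that("model serialization round-trips at the stated precision", {
  m <- TINY
  f1 <- withr::local_tempfile(fileext = ".cm")
  f2 <- withr::local_tempfile(fileext = ".cm")
  write_cm(m, f1)
  m2 <- read_cm(f1)
  write_cm(m2, f2)
  expect_identical(readLines(f1), readLines(f2))  # exact at 3 decimals
  expect_equal(m2$clen, m$clen)
  expect_equal(m2$meta$name, m$meta$name)
  # scores under the re-read model agree to serialization precision
  s1 <- score_sequence(m, "GGGCAAAGCCC", mode = "global")$score
  s2 <- score_sequence(m2, "GGGCAAAGCCC", mode = "global")$score
  expect_equal(s1, s2, tolerance = 0.02)
})
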