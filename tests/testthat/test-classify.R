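test_that("anticodon-to-isotype mapping handles the standard and special
           cases", {
  tb <- decoding_table("eukaryote")
  expect_equal(anticodon_to_isotype("GTA", tb), "Tyr")
  expect_equal(anticodon_to_isotype("TCA", tb), "SeC")
  expect_setequal(anticodon_to_isotype("CAT", tb), c("iMet", "Met", "Ile2"))
  expect_equal(anticodon_to_isotype("NNN", tb), "Undet")
  tb_b <- decoding_table("bacteria")
  expect_setequal(anticodon_to_isotype("CAT", tb_b), c("fMet", "Met", "Ile2"))
})

test_that("the eukaryotic disallowed-anticodon set has exactly 15 members", {
  tb <- decoding_table("eukaryote")
  dis <- tb$anticodon[!tb$allowed]
  expect_length(dis, 15)
  expect_true(all(c("GGG", "ATC", "ATA") %in% dis))  # Pro, Asp, Tyr examples
  # bacteria and archaea have no disallowed set
  expect_equal(sum(!decoding_table("bacteria")$allowed), 0)
})

test_that("all 64 anticodons are covered in every table", {
  for (d in c("eukaryote", "bacteria", "archaea", "vert_mito")) {
    tb <- decoding_table(d)
    expect_equal(nrow(tb), 64)
    expect_equal(anyDuplicated(tb$anticodon), 0)
  }
  # mitochondrial code: TCA decodes Trp, not SeC
  expect_equal(anticodon_to_isotype("TCA", decoding_table("vert_mito")),
               "Trp")
})

test_that("anticodon extraction reads the marked columns of the parse", {
  m <- FS$registry$Met
  sq <- sample_sequence(m, rng_seed = 81)
  cp <- attr(sq, "colpos")
  p <- score_sequence(m, as.character(sq), mode = "global")
  ac <- extract_anticodon(p, m)
  expect_equal(nchar(ac), 3)
  if (!any(is.na(cp[m$ac_cols]))) expect_equal(ac, "CAT")
})

test_that("a deleted anticodon yields NNN", {
  m <- FS$registry$Met
  sq <- as.character(sample_sequence(m, rng_seed = 82))
  p <- score_sequence(m, sq, mode = "global")
  p$colpos[m$ac_cols[2]] <- NA_integer_  # simulate a deletion over position 35
  expect_equal(extract_anticodon(p, m), "NNN")
})

test_that("isotype scoring recovers the generating model", {
  set.seed(83)
  for (iso in c("Ala", "Gly", "SeC")) {
    sq <- as.character(sample_sequence(FS$registry[[iso]]))
    sc <- score_isotypes(sq, FS$registry)
    expect_equal(names(which.max(sc)), iso)
  }
  # registry of size 1: the argmax is that model
  sc1 <- score_isotypes("ACGTACGT", FS$registry["Ala"])
  expect_equal(names(sc1), "Ala")
})

test_that("identical models tie and the tie is flagged", {
  sq <- as.character(sample_sequence(FS$registry$Ala, rng_seed = 84))
  reg <- list(m1 = FS$registry$Ala, m2 = FS$registry$Ala)
  sc <- score_isotypes(sq, reg)
  expect_equal(unname(sc[1]), unname(sc[2]))
  cls <- classify_isotype(list(anticodon = "TGC", isotype_scores = sc),
                          decoding_table("eukaryote"))
  expect_true(cls$tie)
})

test_that("isotype/anticodon disagreement raises the IPD flag", {
  tb <- decoding_table("eukaryote")
  sc <- c(Met = 98.4, Leu = 2.6)
  cls <- classify_isotype(list(anticodon = "CAA", isotype_scores = sc), tb)
  expect_true(cls$ipd)
  expect_equal(cls$isotype_model, "Met")
  # agreement -> no flag
  cls2 <- classify_isotype(list(anticodon = "TGC",
                                isotype_scores = c(Ala = 70, Leu = 10)), tb)
  expect_false(cls2$ipd)
  expect_equal(cls2$isotype, "Ala")
})

test_that("CAU subtypes are resolved by the subtype models and are
           invariant to other registry members", {
  tb <- decoding_table("eukaryote")
  sq <- as.character(sample_sequence(FS$registry$Ile2, rng_seed = 85))
  sub_reg <- FS$registry[c("iMet", "Met", "Ile2")]
  full_reg <- FS$registry
  c1 <- classify_isotype(list(anticodon = "CAT",
                              isotype_scores = score_isotypes(sq, sub_reg)),
                         tb)
  c2 <- classify_isotype(list(anticodon = "CAT",
                              isotype_scores = score_isotypes(sq, full_reg)),
                         tb)
  expect_equal(c1$isotype, "Ile2")
  expect_equal(c2$isotype, c1$isotype)  # adding non-CAU models changes nothing
  expect_false(c2$ipd)
  # CAU subtype decided even when all three subtype scores are negative
  c3 <- classify_isotype(list(anticodon = "CAT",
                              isotype_scores = c(iMet = -5, Met = -2,
                                                 Ile2 = -9)), tb)
  expect_equal(c3$isotype, "Met")
})

test_that("classification is idempotent", {
  tb <- decoding_table("eukaryote")
  pred <- list(anticodon = "GTA", isotype_scores = c(Tyr = 88, Ala = 12))
  c1 <- classify_isotype(pred, tb)
  pred$isotype <- c1$isotype; pred$isotype_model <- c1$isotype_model
  c2 <- classify_isotype(pred, tb)
  expect_identical(c1, c2)
})
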