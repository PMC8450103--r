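test_that("splice removes exactly the interval", {
  s <- strrep("A", 40)
  s2 <- paste0(s, strrep("C", 20), strrep("G", 40))
  expect_equal(nchar(splice(s2, 40, 60)), 80)
  expect_equal(splice(s2, 40, 60), paste0(strrep("A", 40), strrep("G", 40)))
  expect_equal(splice(s2, 10, 10), s2)  # zero-length intron: identity
  # disjoint splices commute (remove the later one first)
  a <- splice(splice(s2, 70, 80), 10, 20)
  b <- splice(splice(s2, 10, 20), 60, 70)
  expect_equal(a, b)
  expect_error(splice(s2, 30, 10), "usage error")
})

test_that("a canonical intron at 37/38 is detected with exact bounds", {
  m <- FS$registry$Ala
  set.seed(91)
  sq <- NULL
  repeat {
    s <- sample_sequence(m)
    cp <- attr(s, "colpos")
    if (!any(is.na(cp[c(m$ac_cols, max(m$ac_cols) + 1L)]))) { sq <- s; break }
  }
  cp <- attr(sq, "colpos")
  ipos <- cp[max(m$ac_cols) + 1L]
  intr <- "GGTTAACCTTGGAACCTTAA"  # 20 nt
  prec <- paste0(substr(sq, 1, ipos), intr, substr(sq, ipos + 1, nchar(sq)))
  p <- score_sequence(m, prec, mode = "global")
  ci <- detect_canonical(p, m)
  expect_equal(nrow(ci), 1)
  expect_equal(ci$kind, "canonical")
  expect_equal(ci$end - ci$begin, 20)
  expect_lte(abs(ci$begin - ipos), 2)  # tolerate 1-2 nt alignment slippage

  # below the minimum intron length: no call
  prec5 <- paste0(substr(sq, 1, ipos), "GGTTA",
                  substr(sq, ipos + 1, nchar(sq)))
  expect_equal(nrow(detect_canonical(score_sequence(m, prec5,
                                                    mode = "global"), m)), 0)

  # a long insertion far from the anticodon is not a canonical intron
  dpos <- cp[12]
  precd <- paste0(substr(sq, 1, dpos), intr, substr(sq, dpos + 1, nchar(sq)))
  pd <- score_sequence(m, precd, mode = "global")
  expect_equal(nrow(detect_canonical(pd, m)), 0)
})

test_that("a single implanted BHB intron is spliced with exact bounds and
           strictly improves the score", {
  set.seed(92)
  m <- FS$registry$Gly
  sq <- as.character(sample_sequence(m))
  intr <- as.character(sample_sequence(FS$bhb_models$bhbA))
  at <- 30
  prec <- paste0(substr(sq, 1, at), intr, substr(sq, at + 1, nchar(sq)))
  base <- score_sequence(m, prec, mode = "local", want_parse = FALSE)$score
  nc <- search_noncanonical(prec, m, FS$bhb_models)
  expect_equal(nrow(nc$introns), 1)
  expect_gt(nc$score, base)  # acceptance rule: strict improvement
  expect_lte(abs(nc$introns$begin - at), 2)
  expect_lte(abs(nc$introns$end - (at + nchar(intr))), 2)
  expect_gte(nc$introns$bhb_bits, intron_config()$bhb_accept_bits)
})

test_that("a decoy insertion whose removal does not help is rejected", {
  set.seed(93)
  m <- FS$registry$Tyr
  sq <- as.character(sample_sequence(m))
  # no BHB motif present anywhere: nothing may be spliced
  nc <- search_noncanonical(sq, m, FS$bhb_models)
  expect_equal(nrow(nc$introns), 0)
  expect_equal(nc$score,
               score_sequence(m, sq, mode = "local", want_parse = FALSE)$score)
})

test_that("iteration terminates within max_iterations and respects the
           minimum mature length", {
  set.seed(94)
  m <- FS$registry$Ala
  sq <- as.character(sample_sequence(m))
  i1 <- as.character(sample_sequence(FS$bhb_models$bhbA))
  prec <- paste0(substr(sq, 1, 20), i1, substr(sq, 21, nchar(sq)))
  cfg <- intron_config(max_iterations = 1)
  nc <- search_noncanonical(prec, m, FS$bhb_models, cfg)
  expect_lte(nrow(nc$introns), 1)
  expect_true(all(nc$introns$iteration <= cfg$max_iterations))
  # a mature-length floor above the tRNA length blocks every splice
  cfg2 <- intron_config(min_mature_len = 200)
  nc2 <- search_noncanonical(prec, m, FS$bhb_models, cfg2)
  expect_equal(nrow(nc2$introns), 0)
})

test_that("the nested two-intron gene needs two iterations", {
  g <- FS$genomes[["archaeal_fixture"]]
  tr <- FS$truth$archaeal
  i2 <- which(tr$kind == "bhb2")
  prec <- substr(g, tr$begin[i2] + 1 - 60, tr$end[i2] + 60)
  nc <- search_noncanonical(prec, FS$domain_model, FS$bhb_models)
  expect_equal(nrow(nc$introns), 2)
  expect_equal(sort(unique(nc$introns$iteration)), c(1L, 2L))
})
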