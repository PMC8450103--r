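pred_row <- function(score, primary, secondary, isotype_score = 100,
                     anticodon = "TGC", isotype = "Ala") {
  data.frame(seq_id = "c", begin = 0L, end = 72L, strand = "+",
             score = score, primary_bits = primary,
             secondary_bits = secondary, isotype_score = isotype_score,
             anticodon = anticodon, isotype = isotype, note = "",
             stringsAsFactors = FALSE)
}

test_that("pseudogene rule: overall below 55 AND (primary < 10 OR
           secondary < 5)", {
  expect_true(classify_pseudogene(pred_row(54, 9, 20)))
  expect_false(classify_pseudogene(pred_row(56, 0, 0)))   # overall >= 55
  expect_false(classify_pseudogene(pred_row(54, 15, 8)))  # neither condition
  expect_true(classify_pseudogene(pred_row(54, 15, 4.9)))
  # boundary values are retained (strict "below")
  expect_false(classify_pseudogene(pred_row(55, 0, 0)))
  expect_false(classify_pseudogene(pred_row(54, 10, 5)))
})

test_that("secondary filter removes on any of the three conditions", {
  p <- rbind(pred_row(60, 40, 15, isotype_score = 80),
             pred_row(100, 60, 30, isotype_score = 69.9),
             pred_row(100, 60, 9.9, isotype_score = 100),
             pred_row(49.9, 30, 15, isotype_score = 100))
  rm <- secondary_filter(p)
  expect_equal(rm, c(FALSE, TRUE, TRUE, TRUE))
  # missing isotype score: removed with a warning
  p2 <- pred_row(100, 60, 30, isotype_score = NA_real_)
  expect_warning(rm2 <- secondary_filter(p2), "-Inf")
  expect_true(rm2)
})

test_that("tertiary dynamic threshold stops when the count reaches the cap", {
  # 60 predictions, one anticodon, scores 71.5, 72.5, ..., 130.5
  p <- do.call(rbind, lapply(71.5 + 0:59, function(s) pred_row(s, 50, 20)))
  rm <- tertiary_filter(p)
  expect_equal(sum(!rm), 40)
  expect_equal(sort(p$score[!rm]), 91.5 + 0:39)  # threshold stopped at 91
  # at or under the cap: untouched
  p10 <- do.call(rbind, lapply(seq(20, 200, length.out = 10),
                               function(s) pred_row(s, 50, 20)))
  expect_equal(sum(tertiary_filter(p10)), 0)
  # threshold saturates at 95 bits
  p100 <- do.call(rbind, lapply(rep(96, 100), function(s)
    pred_row(s, 50, 20)))
  expect_equal(sum(tertiary_filter(p100)), 0)
})

test_that("unexpected anticodons are flagged", {
  tb <- decoding_table("eukaryote")
  p <- rbind(pred_row(100, 60, 30, anticodon = "GGG", isotype = "Pro"),
             pred_row(100, 60, 30, anticodon = "TGC", isotype = "Ala"))
  out <- annotate_consistency(trna_predictions(p), tb)
  expect_match(out$note[1], "unexpected_anticodon")
  expect_equal(out$note[2], "")
})

test_that("the full filter reports Table-style per-stage counts", {
  set.seed(101)
  mk <- function(n, ...) {
    row <- pred_row(...)
    out <- row[rep(1, n), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  p <- rbind(
    mk(30, score = 40, primary = 5, secondary = 20),          # pseudogenes
    mk(20, score = 60, primary = 40, secondary = 20,
       isotype_score = 60),                                   # stage-2 fails
    do.call(rbind, lapply(71.5 + 0:59, function(s)
      pred_row(s, 50, 20, anticodon = "GCC", isotype = "Gly"))), # 60 > cap
    mk(10, score = 100, primary = 60, secondary = 30,
       anticodon = "GTA", isotype = "Tyr"))
  p <- trna_predictions(p)
  rep <- high_confidence_filter(p)
  expect_equal(rep$input, 120)
  expect_equal(unname(rep$removed["pseudogene"]), 30)
  expect_equal(unname(rep$removed["stage2"]), 20)
  expect_equal(unname(rep$removed["stage3"]), 20)
  expect_equal(rep$high_confidence, 50)
  # counts conserve
  expect_equal(rep$input,
               sum(rep$removed) + rep$flagged + rep$high_confidence)
  # set-inclusion chain
  expect_true(all(rep$stage[rep$stage == "high_confidence"] %in%
                    c("high_confidence")))
  expect_true(nrow(rep$hc_set) == rep$high_confidence)
})

test_that("the filter is order-independent and handles empty input", {
  p <- rbind(
    do.call(rbind, lapply(71.5 + 0:59, function(s)
      pred_row(s, 50, 20))),
    pred_row(40, 5, 20))
  p <- trna_predictions(p)
  set.seed(102)
  perm <- sample(nrow(p))
  r1 <- high_confidence_filter(p)
  r2 <- high_confidence_filter(p[perm, ])
  expect_equal(sort(r1$hc_set$score), sort(r2$hc_set$score))
  expect_equal(r1$removed, r2$removed)

  r0 <- high_confidence_filter(trna_predictions())
  expect_equal(r0$input, 0)
  expect_equal(unname(r0$removed), c(0L, 0L, 0L))
  expect_equal(r0$high_confidence, 0)
})

test_that("all predictions above all thresholds pass untouched", {
  p <- trna_predictions(do.call(rbind, lapply(1:20, function(i)
    pred_row(100, 60, 30))))
  rep <- high_confidence_filter(p)
  expect_equal(rep$high_confidence, 20)
  expect_equal(sum(rep$removed), 0)
})

test_that("non-eukaryotic use warns", {
  p <- trna_predictions(pred_row(100, 60, 30))
  expect_warning(high_confidence_filter(p, table = decoding_table("archaea")),
                 "not recommended")
})
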