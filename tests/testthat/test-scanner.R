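make_test_genome <- function(model, pos = 800, len = 2000, seed = 71,
                             strand = "+") {
  set.seed(seed)
  g <- strsplit(rand_dna(len), "")[[1]]
  sq <- as.character(sample_sequence(model))
  s <- if (strand == "-") revcomp(sq) else sq
  g[(pos + 1):(pos + nchar(s))] <- strsplit(s, "")[[1]]
  list(genome = c(tg = paste(g, collapse = "")), begin = pos,
       end = pos + nchar(s))
}

test_that("first pass finds a candidate window containing an implant", {
  m <- FS$registry$Ala
  tg <- make_test_genome(m)
  cand <- first_pass_scan(marginalize(m), tg$genome)
  expect_gt(nrow(cand), 0)
  hitrow <- cand[cand$begin <= tg$begin & cand$end >= tg$end, ]
  expect_gte(nrow(hitrow), 1)
  # raising the cutoff above the implant's first-pass score empties it
  cfghi <- scan_config(first_pass_cutoff = max(cand$bits) + 1,
                       report_cutoff = max(cand$bits) + 1)
  expect_equal(nrow(first_pass_scan(marginalize(m), tg$genome, cfghi)), 0)
})

test_that("1 kb of uniform random sequence yields no 10-bit candidates", {
  set.seed(72)
  g <- c(bg = rand_dna(1000))
  cand <- first_pass_scan(marginalize(FS$domain_model), g)
  expect_equal(nrow(cand), 0)
})

test_that("second pass reports exact boundaries and honors the cutoff", {
  m <- FS$registry$Gly
  tg <- make_test_genome(m, seed = 73)
  cand <- first_pass_scan(marginalize(m), tg$genome)
  hits <- second_pass(m, tg$genome, cand)
  expect_length(hits, 1)
  h <- hits[[1]]
  expect_lte(abs(h$begin - tg$begin), 3)
  expect_lte(abs(h$end - tg$end), 3)
  # threshold is >=: a cutoff just above the score excludes the hit, the
  # exact score includes it
  cfg_excl <- scan_config(report_cutoff = h$score + 0.1)
  cfg_incl <- scan_config(report_cutoff = h$score)
  expect_length(second_pass(m, tg$genome, cand, cfg_excl), 0)
  expect_length(second_pass(m, tg$genome, cand, cfg_incl), 1)
})

test_that("minus-strand implants are recovered with mirrored coordinates", {
  m <- FS$registry$Tyr
  tg <- make_test_genome(m, seed = 74, strand = "-")
  cand <- first_pass_scan(marginalize(m), tg$genome)
  hits <- second_pass(m, tg$genome, cand)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$strand, "-")
  expect_lte(abs(hits[[1]]$begin - tg$begin), 3)
  # reverse-complementing the genome maps the hit to the plus strand with
  # identical score
  L <- nchar(tg$genome[[1]])
  rcg <- c(tg = revcomp(tg$genome[[1]]))
  hits2 <- second_pass(m, rcg, first_pass_scan(marginalize(m), rcg))
  expect_length(hits2, 1)
  expect_equal(hits2[[1]]$strand, "+")
  expect_equal(hits2[[1]]$begin, L - hits[[1]]$end)
  expect_equal(hits2[[1]]$score, hits[[1]]$score, tolerance = 1e-9)
})

test_that("every default-pipeline hit lies inside a first-pass window", {
  m <- FS$registry$Met
  tg <- make_test_genome(m, seed = 75)
  cand <- first_pass_scan(marginalize(m), tg$genome)
  hits <- second_pass(m, tg$genome, cand)
  for (h in hits) {
    inside <- any(cand$strand == h$strand & cand$begin <= h$begin &
                    cand$end >= h$end)
    expect_true(inside)
  }
})

test_that("a truncated implant at the sequence start is flagged", {
  m <- FS$registry$Ala
  set.seed(76)
  sq <- as.character(sample_sequence(m))
  g <- c(tg = paste0(substr(sq, 14, nchar(sq)), rand_dna(400)))
  cand <- data.frame(seq_id = "tg", strand = "+", begin = 0L,
                     end = 150L, bits = NA_real_)
  hits <- second_pass(m, g, cand)
  expect_length(hits, 1)
  expect_match(hits[[1]]$model, "Ala")
  expect_true(hits[[1]]$parse$trunc5)
  expect_equal(hits[[1]]$begin, 0)
})

test_that("max mode is a superset of the two-pass pipeline", {
  m <- FS$registry$Leu
  tg <- make_test_genome(m, len = 1200, seed = 77)
  two <- second_pass(m, tg$genome, first_pass_scan(marginalize(m), tg$genome))
  mx <- scan_max(m, tg$genome)
  key <- function(h) paste(h$seq_id, h$strand, h$begin, h$end)
  expect_true(all(vapply(two, key, character(1)) %in%
                    vapply(mx, key, character(1))))
  expect_error(scan_max(m, tg$genome, scan_config(max_mode_window = 50,
                                                  max_mode_overlap = 10)),
               "usage error")
  expect_length(scan_max(m, c(empty = "")), 0)
})

test_that("overlap resolution keeps the top-scoring model at a locus", {
  h <- function(model, score, begin = 100, end = 170, strand = "+")
    list(seq_id = "c", strand = strand, begin = begin, end = end,
         score = score, model = model)
  out <- resolve_overlaps(list(h("m1", 80), h("m2", 60)))
  expect_length(out, 1)
  expect_equal(out[[1]]$score, 80)
  # disjoint hits are both retained
  out2 <- resolve_overlaps(list(h("m1", 80), h("m2", 60, 400, 470)))
  expect_length(out2, 2)
  # exact tie: lexicographically first model wins, deterministically
  out3 <- resolve_overlaps(list(h("mB", 50), h("mA", 50)))
  expect_equal(out3[[1]]$model, "mA")
})

test_that("raising the report cutoff never adds hits", {
  m <- FS$registry$SeC
  tg <- make_test_genome(m, seed = 78)
  cand <- first_pass_scan(marginalize(m), tg$genome)
  lo <- second_pass(m, tg$genome, cand, scan_config(report_cutoff = 20))
  hi <- second_pass(m, tg$genome, cand, scan_config(report_cutoff = 40))
  expect_lte(length(hi), length(lo))
})
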