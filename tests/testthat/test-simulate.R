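test_that("Markov training: degenerate, order-0 and uniform sources", {
  mA <- train_markov(c(a = strrep("A", 5000)), order = 5)
  ctxAA <- 1  # first lexicographic 5-mer is AAAAA
  expect_gt(mA$cond[ctxAA, 1], 0.99)

  m0 <- train_markov(c(a = "ACGTACGTACGT"), order = 0)
  expect_equal(dim(m0$cond), c(1L, 4L))
  expect_equal(sum(m0$cond), 1, tolerance = 1e-9)

  set.seed(121)
  src <- c(u = rand_dna(1e6))
  mu <- train_markov(src, order = 5)
  expect_true(all(abs(mu$cond - 0.25) < 0.05))
  expect_true(all(abs(rowSums(mu$cond) - 1) < 1e-9))

  expect_error(train_markov(character(0)), "empty")
  expect_warning(train_markov(c(a = "ACGTACGT"), order = 5), "noisy")
})

test_that("virtual genomes are deterministic and reproduce source k-mer
           frequencies", {
  set.seed(122)
  src <- c(u = rand_dna(1e6))
  m <- train_markov(src, order = 5)
  g1 <- generate_virtual_genome(m, 1e5, rng_seed = 7)
  g2 <- generate_virtual_genome(m, 1e5, rng_seed = 7)
  expect_identical(g1, g2)
  expect_equal(nchar(generate_virtual_genome(m, 10, rng_seed = 1)), 10)

  hx <- function(x) {
    f <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(x), 6)
    f / sum(f)
  }
  # expected L1 between two 1-Mb empirical hexamer profiles is about
  # 4096 * sqrt(2/pi) * sqrt(2 p (1-p) / 1e6) ~ 0.07 for p = 1/4096;
  # assert within that bound plus margin, and that longer genomes converge
  gl <- generate_virtual_genome(m, 1e6, rng_seed = 8)
  l1_long <- sum(abs(hx(gl) - hx(src[[1]])))
  expect_lt(l1_long, 0.09)
  gs <- generate_virtual_genome(m, 1e5, rng_seed = 8)
  l1_short <- sum(abs(hx(gs) - hx(src[[1]])))
  expect_lt(l1_long, l1_short)
})

test_that("fp_evaluate histogram bookkeeping", {
  r <- fp_evaluate(FS$registry$Ala, c(g = ""), score_floor = 10)
  expect_equal(r$n_hits, 0)
  expect_equal(nrow(r$histogram), 0)
  # floor above any hit: zero rows (implant scores ~80-100 bits)
  set.seed(123)
  g <- c(g = paste0(rand_dna(300),
                    as.character(sample_sequence(FS$registry$Ala)),
                    rand_dna(300)))
  r2 <- fp_evaluate(FS$registry$Ala, g, score_floor = 500)
  expect_equal(r2$n_hits, 0)
  r3 <- fp_evaluate(FS$registry$Ala, g, score_floor = 10)
  expect_gte(r3$n_hits, 1)
  expect_equal(sum(r3$histogram$count), r3$n_hits)
})

test_that("fixture sets are deterministic per seed", {
  a <- make_fixture_set(5, nuclear_rows = 25, mito_rows = 15,
                        nuclear_len = 15000)
  b <- make_fixture_set(5, nuclear_rows = 25, mito_rows = 15,
                        nuclear_len = 15000)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$truth, b$truth)
  expect_identical(a$seeds$nuclear$Ala$rows, b$seeds$nuclear$Ala$rows)
})

test_that("the fixture set honors its construction contract", {
  expect_gte(nrow(FS$truth$nuclear), 50)
  expect_equal(nchar(FS$genomes[["mito_fixture"]]), 16616)
  expect_equal(nrow(FS$truth$mito), 22)
  expect_true(any(FS$truth$nuclear$kind == "intron"))
  expect_true(any(FS$truth$nuclear$kind %in% c("trunc5", "trunc3")))
  expect_true(any(FS$truth$nuclear$strand == "-"))
})

test_that("fixture sets round-trip to disk as plain text", {
  d <- withr::local_tempdir()
  small <- make_fixture_set(6, nuclear_rows = 20, mito_rows = 12,
                            nuclear_len = 12000)
  write_fixture_set(small, d)
  expect_true(file.exists(file.path(d, "genomes.fa")))
  g <- read_fasta(file.path(d, "genomes.fa"))
  expect_equal(as.character(g[["nuclear_fixture"]]),
               small$genomes[["nuclear_fixture"]])
  a <- read_stockholm(file.path(d, "seed_Ala.sto"))
  expect_true(a == small$seeds$nuclear$Ala)
  bed <- utils::read.table(file.path(d, "nuclear_truth.bed"))
  expect_equal(nrow(bed), nrow(small$truth$nuclear))
})
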