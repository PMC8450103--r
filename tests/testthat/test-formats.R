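test_that("FASTA reading normalizes case and U->T and keeps record order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "acgu", ">y", "NNRY"), f)
  x <- read_fasta(f)
  expect_equal(names(x), c("x", "y"))
  expect_equal(as.character(x[["x"]]), "ACGT")
  expect_equal(as.character(x[["y"]]), "NNRY")  # ambiguity codes preserved
})

test_that("FASTA edge cases: empty file, invalid alphabet", {
  f <- withr::local_tempfile(fileext = ".fa")
  file.create(f)
  expect_length(read_fasta(f), 0)
  writeLines(c(">x", "ACGZ"), f)
  expect_error(read_fasta(f), "format error")
})

test_that("FASTA round-trips through write_fasta", {
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(g1 = "ACGTACGT", g2 = "TTTT"), f)
  x <- read_fasta(f)
  expect_equal(as.character(x), c(g1 = "ACGTACGT", g2 = "TTTT"))
})

test_that("Stockholm parsing accepts WUSS bracket variants and gap codes", {
  f <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               "s1  GGCAAGCC",
               "s2  GGCAAGCC",
               "#=GC SS_cons  <(,..:)>",
               "//"), f)
  a <- read_stockholm(f)
  pt <- parse_structure(a$ss_cons)
  expect_equal(sum(pt > 0), 4)  # two pairs
})

test_that("Stockholm structure errors are caught", {
  f <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "s1  GGCAAGC",
               "#=GC SS_cons  <<...>.", "//"), f)
  expect_error(read_stockholm(f), "unbalanced|structure")
  writeLines(c("# STOCKHOLM 1.0", "s1  GGCAAGC", "s2  GGCAAG",
               "#=GC SS_cons  <<...>>", "//"), f)
  expect_error(read_stockholm(f), "format error")
})

test_that("Stockholm write/read round-trip is the identity", {
  a <- FS$seeds$nuclear$Ala
  f <- withr::local_tempfile(fileext = ".sto")
  write_stockholm(a, f)
  b <- read_stockholm(f)
  expect_true(a == b)
  expect_equal(b$meta$isotype, "Ala")
  expect_equal(b$meta$anticodon, "TGC")
})

test_that("prediction writer follows the coordinate conventions", {
  p <- trna_predictions(data.frame(
    seq_id = c("chr", "chr"), begin = c(99L, 99L), end = c(172L, 172L),
    strand = c("+", "-"), score = c(80, 80), isotype = c("Ala", "Ala"),
    anticodon = c("TGC", "TGC"), note = c("", "pseudo"),
    stringsAsFactors = FALSE))
  f <- withr::local_tempfile(fileext = ".txt")
  write_predictions(p, f, "tabular")
  tab <- utils::read.table(f, sep = "\t", header = TRUE)
  expect_equal(tab$begin, c(100L, 172L))   # 1-based inclusive
  expect_equal(tab$end, c(172L, 100L))     # begin > end on minus strand
  expect_match(tab$note[2], "pseudo")

  fb <- withr::local_tempfile(fileext = ".bed")
  write_predictions(p, fb, "bed")
  bed <- utils::read.table(fb, sep = "\t")
  expect_equal(bed$V2, c(99L, 99L))        # BED is 0-based half-open
  expect_equal(bed$V3, c(172L, 172L))
  expect_equal(bed$V6, c("+", "-"))

  fg <- withr::local_tempfile(fileext = ".gff3")
  write_predictions(p, fg, "gff3")
  gff <- utils::read.table(fg, sep = "\t", comment.char = "#")
  expect_equal(gff$V4, c(100L, 100L))      # GFF3 is 1-based inclusive
  expect_equal(gff$V7, c("+", "-"))

  expect_error(write_predictions(p, f, "vcf"), "usage error")
})

test_that("tabular coordinate round-trip is the identity on both strands", {
  p <- trna_predictions(data.frame(
    seq_id = c("c1", "c1"), begin = c(10L, 500L), end = c(85L, 572L),
    strand = c("+", "-"), score = c(66.5, 23.1),
    isotype = c("Gly", "Ser"), anticodon = c("GCC", "TGA"),
    note = c("", "IPD"), intron_bounds = c("", "520-540"),
    stringsAsFactors = FALSE))
  f <- withr::local_tempfile(fileext = ".txt")
  write_predictions(p, f, "tabular")
  q <- read_predictions(f)
  expect_equal(q$begin, p$begin)
  expect_equal(q$end, p$end)
  expect_equal(q$strand, p$strand)
  expect_equal(q$score, p$score)
  expect_equal(q$intron_bounds, p$intron_bounds)
})

test_that("config reading: defaults, overrides, alternate models", {
  f <- withr::local_tempfile(fileext = ".conf")
  file.create(f)
  cfg <- read_config(f)
  expect_equal(cfg$scan$report_cutoff, 20)   # default reporting threshold
  expect_equal(cfg$scan$first_pass_cutoff, 10)

  writeLines(c("score_cutoff = 30", "model = /path/a.cm",
               "model = /path/b.cm"), f)
  cfg <- read_config(f)
  expect_equal(cfg$scan$report_cutoff, 30)   # high-stringency option
  expect_equal(cfg$models, c("/path/a.cm", "/path/b.cm"))

  writeLines("frobnicate = 1", f)
  expect_warning(read_config(f), "unknown key")
  writeLines("report_cutoff = twenty", f)
  expect_error(read_config(f), "non-numeric")
})
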