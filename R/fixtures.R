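# Deterministic fixture generation: toy seed alignments for nuclear,
# selenocysteine, mitochondrial and bulge-helix-bulge intron families,
# trained model registries, and implanted genomes with truth annotations.
# Everything is derived from the R RNG, so a fixture set is reproducible
# from its seed.

trna_ss_standard <- function() {
  paste0("(((((((", "..", "((((", "........", "))))", ".",
         "(((((", ".......", ")))))", "....",
         "(((((", ".......", ")))))", ")))))))", ".")
}

trna_ss_sec94 <- function() {  # 9-bp acceptor stem / 4-bp T-arm fold
  paste0("(((((((((", "..", "((((", "......", "))))", ".",
         "(((((", ".......", ")))))", "......",
         "((((", ".....", "))))", ")))))))))", ".")
}

trna_ss_mito <- function() {
  paste0("(((((((", ".", "(((", ".....", ")))", ".",
         "(((((", ".......", ")))))", "..",
         "((((", ".....", "))))", ")))))))", ".")
}

trna_ss_mito_darmless <- function() {  # no D-arm helix at all
  paste0("(((((((", ".", "....", ".",
         "(((((", ".......", ")))))", "..",
         "((((", ".....", "))))", ")))))))", ".")
}

# anticodon columns = positions 3-5 of the anticodon loop
ac_cols_for <- function(ss) {
  pt <- parse_structure(ss)
  # the anticodon stem is the second helix-closing loop: find all hairpin
  # loops and take the one whose loop is 7 nt; for these templates that is
  # unique except the T-loop, so take the first 7-nt loop after a 5-bp stem
  n <- nchar(ss)
  for (i in seq_len(n)) {
    if (pt[i] > i && all(pt[(i + 1):(pt[i] - 1)] == 0) &&
        (pt[i] - i - 1L) == 7L) {
      # 5-bp stem check: the 5 columns ending at i all paired consecutively
      if (i >= 5 && all(pt[(i - 4):i] > 0)) return(i + 3:5)
    }
  }
  stop("template without a 7-nt anticodon loop")
}

COMPL <- c(A = "T", C = "G", G = "C", T = "A")

rand_consensus <- function(ss, anticodon = NULL, ac_cols = NULL,
                           motif = NULL) {
  pt <- parse_structure(ss)
  n <- nchar(ss)
  cons <- character(n)
  for (i in seq_len(n)) {
    if (pt[i] == 0) cons[i] <- sample(DNA, 1)
    else if (pt[i] > i) { cons[i] <- sample(DNA, 1); cons[pt[i]] <- COMPL[cons[i]] }
  }
  if (!is.null(anticodon) && !is.null(ac_cols))
    cons[ac_cols] <- strsplit(anticodon, "")[[1]]
  if (!is.null(motif)) cons[motif$cols] <- strsplit(motif$seq, "")[[1]]
  cons
}

# mutate a consensus into an alignment row: unpaired columns substituted
# with prob `mut`; pairs replaced by a random complementary pair with prob
# `mut_pair` (compensatory substitution -- real tRNA stems covary strongly,
# and this diversity is what gives the trained pair tables their secondary
# structure signal); anticodon columns never touched
mutate_row <- function(cons, pt, mut, keep_cols = integer(0),
                       mut_pair = 0.25) {
  row <- cons
  for (i in seq_along(cons)) {
    if (i %in% keep_cols) next
    if (pt[i] == 0) {
      if (stats::runif(1) < mut) row[i] <- sample(DNA, 1)
    } else if (pt[i] > i && !(pt[i] %in% keep_cols)) {
      if (stats::runif(1) < mut_pair) {
        b <- sample(DNA, 1); row[i] <- b; row[pt[i]] <- COMPL[b]
      }
    }
  }
  row
}

# derive an isotype consensus from a shared base consensus: a fraction of
# the columns (identity elements) are resampled, pairs compensatorily
divergent_consensus <- function(base, pt, frac, keep_cols = integer(0)) {
  cons <- base
  for (i in seq_along(base)) {
    if (i %in% keep_cols || (pt[i] > 0 && pt[i] < i)) next
    if (stats::runif(1) < frac) {
      if (pt[i] == 0) cons[i] <- sample(DNA, 1)
      else { b <- sample(DNA, 1); cons[i] <- b; cons[pt[i]] <- COMPL[b] }
    }
  }
  cons
}

make_seed_fixture <- function(name, domain, isotype, anticodon, ss,
                              ac_cols = NULL, nrows = 50, mut = 0.05,
                              fold = "standard", motif = NULL,
                              cons = NULL) {
  pt <- parse_structure(ss)
  if (is.null(cons)) cons <- rand_consensus(ss, anticodon, ac_cols, motif)
  else if (!is.null(anticodon) && !is.null(ac_cols))
    cons[ac_cols] <- strsplit(anticodon, "")[[1]]
  rows <- vapply(seq_len(nrows), function(i)
    paste(mutate_row(cons, pt, mut, keep_cols = ac_cols), collapse = ""),
    character(1))
  ac_line <- NULL
  if (!is.null(ac_cols)) {
    a <- rep(".", nchar(ss)); a[ac_cols] <- "*"
    ac_line <- paste(a, collapse = "")
  }
  seed_alignment(ids = sprintf("%s_%03d", name, seq_len(nrows)), rows = rows,
                 ss_cons = ss, ac_line = ac_line,
                 meta = list(name = name, domain = domain, isotype = isotype,
                             anticodon = anticodon, fold = fold))
}

NUCLEAR_CLASSES <- data.frame(
  isotype = c("Ala", "Gly", "Leu", "Tyr", "iMet", "Met", "Ile2", "SeC"),
  anticodon = c("TGC", "GCC", "CAA", "GTA", "CAT", "CAT", "CAT", "TCA"),
  stringsAsFactors = FALSE)

implant <- function(genome_chars, seq, pos, strand) {
  s <- if (strand == "-") revcomp(seq) else seq
  ch <- strsplit(s, "")[[1]]
  genome_chars[(pos + 1):(pos + length(ch))] <- ch
  genome_chars
}

# sample until the full anticodon (and for introns, the column 3' of it)
# is emitted
sample_with_ac <- function(model, need_c37 = FALSE) {
  for (i in 1:50) {
    sq <- sample_sequence(model)
    cp <- attr(sq, "colpos")
    ok <- !is.null(model$ac_cols) && !any(is.na(cp[model$ac_cols]))
    if (ok && need_c37) ok <- !is.na(cp[max(model$ac_cols) + 1L])
    if (ok || is.null(model$ac_cols)) return(sq)
  }
  sq
}

#' Generate the full offline fixture set
#'
#' Builds toy seed alignments (nuclear isotypes including the three CAU
#' classes and a 9/4-fold SeC; two bulge-helix-bulge intron families; 22
#' vertebrate mitochondrial classes with a D-armless Ser-GCT), trains the
#' corresponding model registries, and implants sampled genes into random
#' background sequence: a ~100 kb nuclear genome with >= 50 implants (some
#' with canonical introns, some boundary-truncated, some
#' anticodon-mutated), a small archaeal genome with noncanonical-intron
#' genes (including a two-intron gene whose second motif only forms after
#' the first splice), and a ~16.6 kb mitochondrial genome with one implant
#' per class.  Truth annotations accompany every genome.  Deterministic per
#' seed.
#'
#' @param rng_seed integer seed
#' @param nuclear_rows alignment depth of the nuclear isotype seeds
#' @param mito_rows alignment depth of the mitochondrial seeds
#' @param nuclear_len nuclear fixture genome length
#' @return object of class \code{fixture_set}; see Details
#' @details The returned list carries \code{seeds} (seed alignments),
#'   \code{domain_model}, \code{sec_model}, \code{registry} (nuclear
#'   isotype models), \code{bhb_models}, \code{mito_registry},
#'   \code{genomes} (named character vector) and \code{truth} (list of
#'   truth data.frames, 0-based half-open coordinates).
#' @export
make_fixture_set <- function(rng_seed = 1, nuclear_rows = 400,
                             mito_rows = 80, nuclear_len = 100000) {
  set.seed(rng_seed)
  ss_std <- trna_ss_standard()
  ac_std <- ac_cols_for(ss_std)
  ss_sec <- trna_ss_sec94()
  ac_sec <- ac_cols_for(ss_sec)
  tloop_motif <- list(cols = (7 + 2 + 4 + 8 + 4 + 1 + 5 + 7 + 5 + 4 + 5) +
                        1:7, seq = "TTCGAAT")

  # --- nuclear isotype seeds and models -------------------------------------
  # all standard-fold isotypes share a common cloverleaf base consensus and
  # diverge at ~25% of columns (their identity elements); this mirrors real
  # tRNAs, keeps the pooled domain model sensitive, and keeps the isotype
  # models mutually discriminative
  pt_std <- parse_structure(ss_std)
  base_cons <- rand_consensus(ss_std, motif = tloop_motif)
  seeds_nuc <- list()
  for (i in seq_len(nrow(NUCLEAR_CLASSES))) {
    iso <- NUCLEAR_CLASSES$isotype[i]; ac <- NUCLEAR_CLASSES$anticodon[i]
    if (iso == "SeC") {
      seeds_nuc[[iso]] <- make_seed_fixture(iso, "eukaryote", iso, ac,
                                            ss_sec, ac_sec,
                                            nrows = nuclear_rows,
                                            fold = "sec_9_4")
    } else {
      cons_i <- divergent_consensus(base_cons, pt_std, 0.25,
                                    keep_cols = c(ac_std, tloop_motif$cols))
      seeds_nuc[[iso]] <- make_seed_fixture(iso, "eukaryote", iso, ac,
                                            ss_std, ac_std,
                                            nrows = nuclear_rows,
                                            cons = cons_i)
    }
  }
  registry <- lapply(seeds_nuc, train_cm)

  # pooled domain model (standard fold, anticodons masked)
  std <- setdiff(names(seeds_nuc), "SeC")
  pick <- lapply(std, function(iso) {
    a <- seeds_nuc[[iso]]
    keep <- seq_len(min(40L, length(a$rows)))
    a$rows <- a$rows[keep]; a$ids <- paste0(iso, "_", a$ids[keep])
    a
  })
  pooled <- seed_alignment(
    ids = unlist(lapply(pick, `[[`, "ids")),
    rows = unlist(lapply(pick, `[[`, "rows")),
    ss_cons = ss_std,
    ac_line = pick[[1]]$ac_line,
    meta = list(name = "domain", domain = "eukaryote"))
  domain_model <- train_cm(mask_anticodons(pooled))
  sec_aln <- seeds_nuc$SeC
  sec_aln$ids <- paste0("SeC_", sec_aln$ids)
  sec_aln$meta$name <- "domain_SeC"
  sec_model <- train_cm(mask_anticodons(sec_aln))

  # --- bulge-helix-bulge intron seeds ---------------------------------------
  ss_bhbA <- paste0("....", "((((((((((", "......", "))))))))))", "......")
  ss_bhbB <- paste0("....", "(((((((", ".....", ")))))))", "....")
  seeds_bhb <- list(
    bhbA = make_seed_fixture("bhbA", "archaea", NA, NULL, ss_bhbA,
                             nrows = 60, mut = 0.03),
    bhbB = make_seed_fixture("bhbB", "archaea", NA, NULL, ss_bhbB,
                             nrows = 60, mut = 0.03))
  bhb_models <- lapply(seeds_bhb, train_cm)

  # --- mitochondrial seeds and registry -------------------------------------
  ss_mt <- trna_ss_mito(); ac_mt <- ac_cols_for(ss_mt)
  ss_md <- trna_ss_mito_darmless(); ac_md <- ac_cols_for(ss_md)
  mc <- mito_classes()
  base_mt <- rand_consensus(ss_mt)
  pt_mt <- parse_structure(ss_mt)
  seeds_mito <- list()
  for (i in seq_len(nrow(mc))) {
    iso <- mc$isotype[i]; ac <- mc$anticodon[i]
    nm <- paste(iso, ac, sep = "-")
    darmless <- iso == "Ser" && ac == "GCT"
    seeds_mito[[nm]] <- make_seed_fixture(
      nm, "mito", iso, ac,
      if (darmless) ss_md else ss_mt,
      if (darmless) ac_md else ac_mt,
      nrows = mito_rows,
      fold = if (darmless) "d_armless" else "standard",
      cons = if (darmless) NULL else
        divergent_consensus(base_mt, pt_mt, 0.25, keep_cols = ac_mt))
  }
  mito_registry <- build_mito_registry(seeds_mito)

  # --- nuclear fixture genome -----------------------------------------------
  gch <- sample(DNA, nuclear_len, replace = TRUE)
  n_imp <- 52L
  kinds <- c(rep("plain", 40), rep("intron", 6), rep("ipd", 3),
             "trunc5", "trunc3", "plain", "plain")[1:n_imp]
  isos <- rep(NUCLEAR_CLASSES$isotype, length.out = n_imp)
  slots <- round(seq(500, nuclear_len - 600, length.out = n_imp)) +
    sample(-80:80, n_imp, replace = TRUE)
  truth_rows <- list()
  for (k in seq_len(n_imp)) {
    kind <- kinds[k]
    iso <- if (kind == "ipd") "Leu" else isos[k]
    m <- registry[[iso]]
    strand <- if (kind %in% c("trunc5", "trunc3")) "+"
              else sample(c("+", "-"), 1, prob = c(0.75, 0.25))
    sq <- sample_with_ac(m, need_c37 = kind == "intron")
    cp <- attr(sq, "colpos")
    s <- as.character(sq)
    ac_out <- NUCLEAR_CLASSES$anticodon[NUCLEAR_CLASSES$isotype == iso]
    if (kind == "ipd") {
      # Leu body carrying an Ala anticodon: model and anticodon disagree
      ch <- strsplit(s, "")[[1]]
      ch[cp[m$ac_cols]] <- c("T", "G", "C")
      s <- paste(ch, collapse = "")
      ac_out <- "TGC"
    }
    if (kind == "intron") {
      ipos <- cp[max(m$ac_cols) + 1L]
      ilen <- sample(15:25, 1)
      intr <- paste(sample(DNA, ilen, replace = TRUE), collapse = "")
      s <- paste0(substr(s, 1, ipos), intr, substr(s, ipos + 1, nchar(s)))
    }
    pos <- slots[k]
    if (kind == "trunc5") { s <- substr(s, 16, nchar(s)); pos <- 0L }
    if (kind == "trunc3") {
      s <- substr(s, 1, nchar(s) - 12)
      pos <- nuclear_len - nchar(s)
    }
    gch <- implant(gch, s, pos, strand)
    truth_rows[[k]] <- data.frame(
      seq_id = "nuclear_fixture", begin = pos, end = pos + nchar(s),
      strand = strand, isotype = iso, anticodon = ac_out, kind = kind,
      stringsAsFactors = FALSE)
  }
  nuclear_genome <- paste(gch, collapse = "")
  truth_nuclear <- do.call(rbind, truth_rows)

  # --- archaeal mini-genome with noncanonical introns -----------------------
  arch_len <- 8000L
  ach <- sample(DNA, arch_len, replace = TRUE)
  truth_arch <- list()
  # one-intron gene
  m1 <- registry$Ala
  sq <- sample_with_ac(m1); cp <- attr(sq, "colpos")
  i1 <- as.character(sample_sequence(bhb_models$bhbA))
  at <- cp[18L]  # inside the D-loop, away from the anticodon
  if (is.na(at)) at <- max(cp[seq_len(18L)], na.rm = TRUE)
  s1 <- paste0(substr(sq, 1, at), i1, substr(sq, at + 1, nchar(sq)))
  ach <- implant(ach, s1, 1000L, "+")
  truth_arch[[1]] <- data.frame(
    seq_id = "archaeal_fixture", begin = 1000L, end = 1000L + nchar(s1),
    strand = "+", isotype = "Ala", anticodon = "TGC", kind = "bhb1",
    stringsAsFactors = FALSE)
  # two introns in close proximity: the first interrupts the second's motif
  m2 <- registry$Gly
  sq2 <- sample_with_ac(m2); cp2 <- attr(sq2, "colpos")
  iA <- as.character(sample_sequence(bhb_models$bhbA))
  iB <- as.character(sample_sequence(bhb_models$bhbB))
  cut <- round(nchar(iB) / 2)
  nested <- paste0(substr(iB, 1, cut), iA, substr(iB, cut + 1, nchar(iB)))
  at2 <- cp2[45L]  # in the variable region between the two 3' arms
  if (is.na(at2)) at2 <- max(cp2[seq_len(45L)], na.rm = TRUE)
  s2 <- paste0(substr(sq2, 1, at2), nested, substr(sq2, at2 + 1, nchar(sq2)))
  ach <- implant(ach, s2, 3500L, "+")
  truth_arch[[2]] <- data.frame(
    seq_id = "archaeal_fixture", begin = 3500L, end = 3500L + nchar(s2),
    strand = "+", isotype = "Gly", anticodon = "GCC", kind = "bhb2",
    stringsAsFactors = FALSE)
  # intron-free control gene
  sq3 <- sample_with_ac(registry$Tyr)
  ach <- implant(ach, as.character(sq3), 6000L, "+")
  truth_arch[[3]] <- data.frame(
    seq_id = "archaeal_fixture", begin = 6000L,
    end = 6000L + nchar(sq3), strand = "+", isotype = "Tyr",
    anticodon = "GTA", kind = "plain", stringsAsFactors = FALSE)
  arch_genome <- paste(ach, collapse = "")
  truth_arch <- do.call(rbind, truth_arch)

  # --- mitochondrial fixture genome (~16.6 kb, like a vertebrate
  # mitogenome) ---------------------------------------------------------------
  mt_len <- 16616L
  mch <- sample(DNA, mt_len, replace = TRUE)
  mt_truth <- list()
  mpos <- round(seq(300, mt_len - 400, length.out = 22))
  for (i in seq_len(22)) {
    nm <- names(mito_registry)[i]
    strand <- sample(c("+", "-"), 1, prob = c(0.7, 0.3))
    sq <- sample_with_ac(mito_registry[[nm]])
    mch <- implant(mch, as.character(sq), mpos[i], strand)
    mt_truth[[i]] <- data.frame(
      seq_id = "mito_fixture", begin = mpos[i],
      end = mpos[i] + nchar(sq), strand = strand,
      isotype = registry_isotype(nm), anticodon = sub("^.*-", "", nm),
      kind = "plain", stringsAsFactors = FALSE)
  }
  mito_genome <- paste(mch, collapse = "")
  truth_mito <- do.call(rbind, mt_truth)

  structure(list(
    rng_seed = rng_seed,
    seeds = list(nuclear = seeds_nuc, domain = pooled, bhb = seeds_bhb,
                 mito = seeds_mito),
    domain_model = domain_model, sec_model = sec_model,
    registry = registry, bhb_models = bhb_models,
    mito_registry = mito_registry,
    genomes = c(nuclear_fixture = nuclear_genome,
                archaeal_fixture = arch_genome,
                mito_fixture = mito_genome),
    truth = list(nuclear = truth_nuclear, archaeal = truth_arch,
                 mito = truth_mito)
  ), class = "fixture_set")
}

#' @export
print.fixture_set <- function(x, ...) {
  cat("Fixture set (seed", x$rng_seed, ")\n")
  cat(" ", length(x$registry), "nuclear isotype models;",
      length(x$mito_registry), "mito models;",
      length(x$bhb_models), "BHB intron models\n")
  for (nm in names(x$genomes))
    cat(sprintf("  %s: %d nt, %d truth records\n", nm,
                nchar(x$genomes[[nm]]),
                nrow(x$truth[[sub("_fixture", "", nm)]])))
  invisible(x)
}

#' Write a fixture set to disk (FASTA + BED + Stockholm)
#' @param fs a [make_fixture_set()] result
#' @param dir output directory
#' @return \code{dir}, invisibly
#' @export
write_fixture_set <- function(fs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fs$genomes, file.path(dir, "genomes.fa"))
  for (nm in names(fs$truth)) {
    tr <- fs$truth[[nm]]
    bed <- data.frame(tr$seq_id, tr$begin, tr$end,
                      paste(tr$isotype, tr$anticodon, tr$kind, sep = "-"),
                      0L, tr$strand)
    utils::write.table(bed, file.path(dir, paste0(nm, "_truth.bed")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  for (nm in names(fs$seeds$nuclear))
    write_stockholm(fs$seeds$nuclear[[nm]],
                    file.path(dir, paste0("seed_", nm, ".sto")))
  for (nm in names(fs$seeds$mito))
    write_stockholm(fs$seeds$mito[[nm]],
                    file.path(dir, paste0("seed_mito_", nm, ".sto")))
  for (nm in names(fs$seeds$bhb))
    write_stockholm(fs$seeds$bhb[[nm]],
                    file.path(dir, paste0("seed_", nm, ".sto")))
  invisible(dir)
}
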