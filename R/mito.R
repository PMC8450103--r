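# Vertebrate mitochondrial search mode: a 22-model registry (one per
# isotype/anticodon class, including the D-armless Ser-GCT architecture),
# merge-and-top-score locus calling, and anticodon crosschecking.

#' The 22 vertebrate mitochondrial tRNA classes
#'
#' One tRNA per isotype except Leu and Ser, which have two each.
#' @return data.frame with \code{isotype} and \code{anticodon}
#' @export
mito_classes <- function() {
  data.frame(
    isotype = c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                "His", "Ile", "Leu", "Leu", "Lys", "Met", "Phe", "Pro",
                "Ser", "Ser", "Thr", "Trp", "Tyr", "Val"),
    anticodon = c("TGC", "TCG", "GTT", "GTC", "GCA", "TTG", "TTC", "TCC",
                  "GTG", "GAT", "TAA", "TAG", "TTT", "CAT", "GAA", "TGG",
                  "GCT", "TGA", "TGT", "TCA", "GTA", "TAC"),
    stringsAsFactors = FALSE)
}

#' Build the vertebrate mitochondrial model registry
#'
#' Trains one model per isotype/anticodon class with two rounds of training
#' within each class (train, re-align the members to the intermediate model,
#' retrain).  The Ser-GCT seed alignment must use the D-armless fold.
#'
#' @param alns list of 22 [seed_alignment()]s, each with \code{isotype} and
#'   \code{anticodon} metadata
#' @param pseudocount passed to [train_cm()]
#' @return named list of 22 models (class \code{mito_registry})
#' @export
build_mito_registry <- function(alns, pseudocount = 1) {
  want <- mito_classes()
  want_names <- paste(want$isotype, want$anticodon, sep = "-")
  got <- vapply(alns, function(a)
    paste(a$meta$isotype, a$meta$anticodon, sep = "-"), character(1))
  missing <- setdiff(want_names, got)
  if (length(missing))
    stop("registry error: missing mitochondrial class(es): ",
         paste(missing, collapse = ", "))
  if (length(alns) != 22L)
    stop("registry error: expected 22 seed alignments, got ", length(alns))
  reg <- lapply(alns, function(a) {
    a$meta$name <- paste(a$meta$isotype, a$meta$anticodon, sep = "-")
    m1 <- train_cm(a, pseudocount = pseudocount)
    seqs <- gsub("[-._~]", "", a$rows)
    names(seqs) <- a$ids
    a2 <- align_to_model(m1, seqs, meta = a$meta)
    train_cm(a2, pseudocount = pseudocount)
  })
  names(reg) <- got
  structure(reg[want_names], class = c("mito_registry", "list"))
}

#' Scan a (mitochondrial) genome with the full mito registry
#'
#' Scans both strands with all 22 models (two-pass per model), merges
#' overlapping same-strand hits keeping the top-scoring model, reports the
#' winning model's identity as the isotype, extracts the anticodon from the
#' structural parse, and flags predictions whose anticodon-implied isotype
#' disagrees with the winning model (\code{inconsistent_isotype}).
#'
#' @param seqs genome sequences
#' @param registry a [build_mito_registry()] registry
#' @param report_cutoff reporting threshold in bits (default 20; evaluation
#'   harnesses may use 0)
#' @param cfg a [scan_config()]
#' @return a [trna_predictions()] table with the winning model in
#'   \code{isotype_model}
#' @export
mito_scan <- function(seqs, registry, report_cutoff = 20,
                      cfg = scan_config()) {
  stopifnot(report_cutoff >= 0)
  cfg$first_pass_cutoff <- min(cfg$first_pass_cutoff, report_cutoff)
  cfg$report_cutoff <- report_cutoff
  seqs <- as_seq_char(seqs)
  table <- decoding_table("vert_mito")
  hits <- list()
  for (nm in names(registry)) {
    model <- registry[[nm]]
    prof <- marginalize(model)
    cand <- first_pass_scan(prof, seqs, cfg)
    hh <- second_pass(model, seqs, cand, cfg)
    for (h in hh) { h$model <- nm; hits[[length(hits) + 1L]] <- h }
  }
  hits <- resolve_overlaps(hits)
  if (length(hits) == 0L) return(trna_predictions())
  rows <- lapply(hits, function(h) {
    m <- registry[[h$model]]
    ac <- extract_anticodon(h$parse, m)
    iso_model <- registry_isotype(h$model)
    ac_iso <- anticodon_to_isotype(ac, table)
    note <- ""
    if (!("Undet" %in% ac_iso) && !(iso_model %in% ac_iso))
      note <- add_flag(note, "inconsistent_isotype")
    if (isTRUE(h$parse$trunc5)) note <- add_flag(note, "trunc_start")
    if (isTRUE(h$parse$trunc3)) note <- add_flag(note, "trunc_end")
    data.frame(seq_id = h$seq_id, begin = h$begin, end = h$end,
               strand = h$strand, score = h$score,
               primary_bits = h$parse$primary_bits,
               secondary_bits = h$parse$secondary_bits,
               model = h$model, anticodon = ac, isotype = iso_model,
               isotype_model = h$model, isotype_score = h$score,
               note = note, intron_bounds = "", stringsAsFactors = FALSE)
  })
  trna_predictions(do.call(rbind, rows))
}
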