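# The default search pipeline: first-pass candidate gathering, structural
# second pass (or exhaustive single-pass mode), overlap resolution, intron
# detection, isotype classification.

seg_to_genomic <- function(wb, we, strand, b, e) {
  if (strand == "+") c(wb + b, wb + e) else c(we - e, we - b)
}

#' Scan sequences for tRNA genes
#'
#' Runs the full detection-and-classification pipeline: a structure-free
#' first-pass scan at \code{cfg$scan$first_pass_cutoff} bits gathers
#' candidate windows (with flanking sequence), the structural second pass
#' rescans them and keeps hits at or above \code{cfg$scan$report_cutoff}
#' bits (default 20); with \code{mode = "max"} the structural model is
#' instead slid exhaustively over the whole sequence.  When several scan
#' models are supplied, the top-scoring model wins at each overlapping
#' locus.  Detected genes are checked for canonical introns; in archaeal
#' mode, noncanonical bulge-helix-bulge introns are searched by iterative
#' splicing and rescoring, and reported scores are based on the predicted
#' mature tRNA.  If an isotype-model registry is supplied, each mature
#' sequence is scored against every registry model and disagreements
#' between the anticodon-derived and model-derived isotype are flagged
#' (\code{IPD}).
#'
#' @param seqs sequences (DNAStringSet, named character vector, or file
#'   path of a FASTA file)
#' @param scan_models a [train_cm()] model or list of models
#' @param isotype_registry optional named list of isotype-specific models
#' @param domain decoding-table domain (\code{"eukaryote"},
#'   \code{"bacteria"}, \code{"archaea"})
#' @param mode \code{"default"} (two-pass) or \code{"max"} (exhaustive
#'   single pass)
#' @param cfg configuration list as from [default_config()]
#' @param bhb_models list of bulge-helix-bulge intron models (archaeal
#'   noncanonical intron search; used when \code{domain = "archaea"})
#' @return a [trna_predictions()] table; per-row isotype score maps are in
#'   \code{attr(x, "isotype_scores")}
#' @export
trna_scan <- function(seqs, scan_models, isotype_registry = NULL,
                      domain = c("eukaryote", "bacteria", "archaea"),
                      mode = c("default", "max"), cfg = default_config(),
                      bhb_models = NULL) {
  domain <- match.arg(domain)
  mode <- match.arg(mode)
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- read_fasta(seqs)
  seqs <- as_seq_char(seqs)
  if (inherits(scan_models, "trna_cm")) scan_models <- list(scan_models)
  table <- decoding_table(domain)

  # archaeal genes with multiple noncanonical introns can score below the
  # reporting threshold before splicing; gather hits at the first-pass
  # cutoff and apply the reporting threshold to the final (mature) score
  scan_cfg <- cfg$scan
  intron_mode <- domain == "archaea" && length(bhb_models) > 0
  if (intron_mode)
    scan_cfg$report_cutoff <- -Inf

  hits <- list()
  for (model in scan_models) {
    if (mode == "max") {
      hh <- scan_max(model, seqs, scan_cfg)
    } else {
      prof <- marginalize(model)
      cand <- first_pass_scan(prof, seqs, scan_cfg)
      # the structure-free pass cannot see boundary-truncated genes (their
      # missing columns would be charged as deletions), so the two boundary
      # windows are always rescanned structurally with truncation allowed
      w <- model$clen + scan_cfg$candidate_flank
      for (id in names(seqs)) {
        L <- nchar(seqs[[id]])
        bw <- unique(rbind(
          data.frame(seq_id = id, strand = c("+", "-"), begin = 0L,
                     end = min(L, w), bits = NA_real_),
          data.frame(seq_id = id, strand = c("+", "-"),
                     begin = max(0L, L - w), end = L, bits = NA_real_)))
        cand <- rbind(cand, bw)
      }
      # genes interrupted by large noncanonical introns can fall below the
      # structure-free first-pass cutoff; every BHB motif hit therefore
      # seeds an extra candidate window wide enough to hold the whole gene
      if (intron_mode) {
        for (bm in bhb_models) {
          bcand <- first_pass_scan(marginalize(bm), seqs, scan_cfg)
          if (nrow(bcand)) {
            ext <- model$clen + scan_cfg$candidate_flank
            for (i in seq_len(nrow(bcand))) {
              L <- nchar(seqs[[bcand$seq_id[i]]])
              cand <- rbind(cand, data.frame(
                seq_id = bcand$seq_id[i], strand = bcand$strand[i],
                begin = max(0L, bcand$begin[i] - ext),
                end = min(L, bcand$end[i] + ext), bits = NA_real_))
            }
          }
        }
      }
      hh <- second_pass(model, seqs, cand, scan_cfg)
    }
    hits <- c(hits, hh)
  }
  hits <- resolve_overlaps(hits)
  if (length(hits) == 0L) return(trna_predictions())

  model_by_name <- scan_models
  names(model_by_name) <- vapply(scan_models, function(m) m$meta$name,
                                 character(1))
  rows <- list(); iso_scores <- list()
  for (h in hits) {
    model <- model_by_name[[h$model]]
    parse <- h$parse
    score <- h$score
    prim <- parse$primary_bits; sec <- parse$secondary_bits
    gb <- h$begin; ge <- h$end
    anticodon <- extract_anticodon(parse, model)
    note <- ""
    if (isTRUE(parse$trunc5)) note <- add_flag(note, "trunc_start")
    if (isTRUE(parse$trunc3)) note <- add_flag(note, "trunc_end")
    intron_strs <- character(0)
    mature_seq <- h$gene_seq

    # canonical intron: a long insertion one nucleotide 3' of the anticodon
    can <- detect_canonical(parse, model, cfg$intron)
    if (nrow(can)) {
      ib <- can$begin[1] - parse$begin; ie <- can$end[1] - parse$begin
      mature_seq <- splice(h$gene_seq, ib, ie)
      g <- seg_to_genomic(h$window[1], h$window[2], h$strand,
                          can$begin[1], can$end[1])
      intron_strs <- c(intron_strs, paste0(g[1] + 1L, "-", g[2]))
      resc <- score_sequence(model, mature_seq, mode = "local")
      score <- resc$score
      prim <- resc$primary_bits; sec <- resc$secondary_bits
    }

    # noncanonical BHB introns (archaeal mode)
    if (domain == "archaea" && length(bhb_models) && nrow(can) == 0L) {
      L <- nchar(seqs[[h$seq_id]])
      pb <- max(0L, gb - cfg$intron$flank)
      pe <- min(L, ge + cfg$intron$flank)
      prec <- substr(seqs[[h$seq_id]], pb + 1L, pe)
      if (h$strand == "-") prec <- revcomp(prec)
      nc <- search_noncanonical(prec, model, bhb_models, cfg$intron)
      if (nrow(nc$introns)) {
        # precursor orientation: 5'->3' of the gene
        for (r in seq_len(nrow(nc$introns))) {
          ic <- c(nc$introns$begin[r], nc$introns$end[r])
          g <- if (h$strand == "+") c(pb + ic[1], pb + ic[2])
               else c(pe - ic[2], pe - ic[1])
          intron_strs <- c(intron_strs, paste0(g[1] + 1L, "-", g[2]))
        }
        mp <- nc$mature_parse
        mb <- nc$coord_map[mp$begin + 1L]
        me <- nc$coord_map[mp$end] + 1L
        g <- if (h$strand == "+") c(pb + mb, pb + me)
             else c(pe - me, pe - mb)
        gb <- g[1]; ge <- g[2]
        score <- nc$score
        prim <- mp$primary_bits; sec <- mp$secondary_bits
        mature_seq <- nc$mature_seq
        anticodon <- extract_anticodon(mp, model)
      }
    }

    iso <- anticodon_to_isotype(anticodon, table)[1]
    iso_model <- ""; iso_score <- NA_real_
    scmap <- NULL
    if (!is.null(isotype_registry)) {
      scmap <- score_isotypes(mature_seq, isotype_registry)
      cls <- classify_isotype(list(anticodon = anticodon,
                                   isotype_scores = scmap), table)
      iso <- cls$isotype
      iso_model <- cls$isotype_model
      iso_score <- cls$isotype_score
      if (cls$ipd) note <- add_flag(note, "IPD")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = h$seq_id, begin = gb, end = ge, strand = h$strand,
      score = score, primary_bits = prim, secondary_bits = sec,
      model = h$model, anticodon = anticodon, isotype = iso,
      isotype_model = if (!is.null(isotype_registry))
        registry_isotype(iso_model) else "",
      isotype_score = iso_score, note = note,
      intron_bounds = paste(intron_strs, collapse = ","),
      stringsAsFactors = FALSE)
    iso_scores[length(rows)] <- list(scmap)
  }
  out <- trna_predictions(do.call(rbind, rows))
  keep <- out$score >= cfg$scan$report_cutoff
  out <- out[keep, , drop = FALSE]
  class(out) <- c("trna_predictions", "data.frame")
  attr(out, "isotype_scores") <- iso_scores[keep]
  out
}
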