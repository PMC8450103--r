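# Categorized comparison of two annotation sets (nuclear four-category and
# mitochondrial five-category schemes).

# greedy one-to-one matching by overlap length (ties: larger overlap, then
# leftmost prediction); returns matrix of matched index pairs
match_overlaps <- function(preds, refs) {
  pairs <- list()
  for (i in seq_len(nrow(preds))) {
    for (j in seq_len(nrow(refs))) {
      if (preds$seq_id[i] != refs$seq_id[j]) next
      ov <- min(preds$end[i], refs$end[j]) - max(preds$begin[i], refs$begin[j])
      if (ov > 0) pairs[[length(pairs) + 1L]] <- c(i, j, ov)
    }
  }
  if (length(pairs) == 0L)
    return(matrix(integer(0), ncol = 3))
  pm <- do.call(rbind, pairs)
  pm <- pm[order(-pm[, 3], preds$begin[pm[, 1]], pm[, 1], pm[, 2]), ,
           drop = FALSE]
  used_p <- logical(nrow(preds)); used_r <- logical(nrow(refs))
  keep <- logical(nrow(pm))
  for (k in seq_len(nrow(pm))) {
    i <- pm[k, 1]; j <- pm[k, 2]
    if (!used_p[i] && !used_r[j]) {
      keep[k] <- TRUE; used_p[i] <- TRUE; used_r[j] <- TRUE
    }
  }
  pm[keep, , drop = FALSE]
}

reciprocal50 <- function(p, r, i, j) {
  ov <- min(p$end[i], r$end[j]) - max(p$begin[i], r$begin[j])
  ov >= 0.5 * (p$end[i] - p$begin[i]) && ov >= 0.5 * (r$end[j] - r$begin[j])
}

#' Compare two tRNA annotation sets
#'
#' Nuclear mode uses four categories: \emph{consistent} (same strand,
#' matching isotype and anticodon, both boundary offsets within the
#' tolerance), \emph{isotype_mismatch} (same genomic locus, >= 50%
#' reciprocal overlap, but different identity), \emph{novel} (prediction
#' with no matching reference) and \emph{not_detected} (reference with no
#' matching prediction).  Mitochondrial mode adds \emph{position_mismatch}:
#' same isotype but different strand, or overlapping with boundary offsets
#' beyond the tolerance.  Matching between the two sets is one-to-one,
#' greedy by overlap length.
#'
#' @param preds,refs [trna_predictions()]-like data.frames (internal
#'   0-based half-open coordinates) with \code{seq_id}, \code{begin},
#'   \code{end}, \code{strand}, \code{isotype}, \code{anticodon}
#' @param mode \code{"nuclear"} (tolerance 10 nt) or \code{"mito"}
#'   (tolerance 15 nt)
#' @param cfg a [compare_config()]
#' @return object of class \code{comparison_result} with per-record labels
#'   and category counts
#' @export
compare_annotations <- function(preds, refs, mode = c("nuclear", "mito"),
                                cfg = compare_config()) {
  mode <- match.arg(mode)
  tol <- if (mode == "nuclear") cfg$nuclear_tolerance else cfg$mito_tolerance
  preds <- as.data.frame(preds); refs <- as.data.frame(refs)
  pm <- match_overlaps(preds, refs)
  pred_label <- rep("novel", nrow(preds))
  ref_label <- rep("not_detected", nrow(refs))
  for (k in seq_len(nrow(pm))) {
    i <- pm[k, 1]; j <- pm[k, 2]
    same_strand <- preds$strand[i] == refs$strand[j]
    same_iso <- identical(preds$isotype[i], refs$isotype[j])
    same_id <- same_iso &&
      (mode == "mito" || identical(preds$anticodon[i], refs$anticodon[j]))
    off_ok <- abs(preds$begin[i] - refs$begin[j]) <= tol &&
      abs(preds$end[i] - refs$end[j]) <= tol
    lab <- NULL
    if (same_id && same_strand && off_ok) {
      lab <- "consistent"
    } else if (mode == "mito" && same_iso && (!same_strand || !off_ok)) {
      lab <- "position_mismatch"
    } else if (!same_id && same_strand && reciprocal50(preds, refs, i, j)) {
      lab <- "isotype_mismatch"
    }
    if (!is.null(lab)) { pred_label[i] <- lab; ref_label[j] <- lab }
  }
  counts <- c(consistent = sum(pred_label == "consistent"),
              isotype_mismatch = sum(pred_label == "isotype_mismatch"),
              position_mismatch = if (mode == "mito")
                sum(pred_label == "position_mismatch") else NA_integer_,
              novel = sum(pred_label == "novel"),
              not_detected = sum(ref_label == "not_detected"))
  structure(list(mode = mode, tolerance = tol, counts = counts,
                 pred_label = pred_label, ref_label = ref_label),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Annotation comparison (", x$mode, " mode, ±", x$tolerance,
      " nt)\n", sep = "")
  ct <- x$counts[!is.na(x$counts)]
  for (nm in names(ct))
    cat(sprintf("  %-18s %6d\n", nm, ct[[nm]]))
  invisible(x)
}
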