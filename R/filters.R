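# Pseudogene classification and the three-stage high-confidence filter.
# All thresholds use strict "below": boundary values are retained.

#' Pseudogene rule
#'
#' A prediction is classified as a possible pseudogene iff its overall
#' score is below 55 bits AND (its primary sequence score is below 10 bits
#' OR its secondary structure score is below 5 bits); thresholds from
#' \code{cfg}.
#'
#' @param pred list/one-row data.frame with \code{score},
#'   \code{primary_bits}, \code{secondary_bits} (vectorized over rows when
#'   given a data.frame)
#' @param cfg a [filter_config()]
#' @return logical
#' @export
classify_pseudogene <- function(pred, cfg = filter_config()) {
  pred$score < cfg$pseudo_overall &
    (pred$primary_bits < cfg$pseudo_primary |
       pred$secondary_bits < cfg$pseudo_secondary)
}

#' Second-stage filter
#'
#' Removes any prediction with isotype-specific model score below 70 bits,
#' overall score below 50 bits, or secondary structure score below 10 bits
#' (strict; thresholds from \code{cfg}).  A missing isotype score is
#' treated as -Inf (removed) with a warning.
#'
#' @param preds a [trna_predictions()] table
#' @param cfg a [filter_config()]
#' @return logical vector: TRUE = removed
#' @export
secondary_filter <- function(preds, cfg = filter_config()) {
  iso <- preds$isotype_score
  if (any(is.na(iso))) {
    warning("missing isotype score treated as -Inf")
    iso[is.na(iso)] <- -Inf
  }
  iso < cfg$stage2_isotype | preds$score < cfg$stage2_overall |
    preds$secondary_bits < cfg$stage2_secondary
}

#' Third-stage dynamic per-anticodon threshold
#'
#' For every anticodon with more than \code{cfg$stage3_max_per_anticodon}
#' predictions, a dynamic threshold starts at \code{cfg$stage3_start} bits
#' and rises one bit at a time, removing predictions scoring below it, until
#' the anticodon's count is no longer over the cap or the threshold reaches
#' \code{cfg$stage3_cap} bits.  Anticodons at or under the cap are left
#' untouched.
#'
#' @param preds a [trna_predictions()] table
#' @param cfg a [filter_config()]
#' @return logical vector: TRUE = removed
#' @export
tertiary_filter <- function(preds, cfg = filter_config()) {
  removed <- rep(FALSE, nrow(preds))
  for (ac in unique(preds$anticodon)) {
    idx <- which(preds$anticodon == ac)
    if (length(idx) <= cfg$stage3_max_per_anticodon) next
    t <- cfg$stage3_start
    keep <- preds$score[idx] >= t
    while (sum(keep) > cfg$stage3_max_per_anticodon && t < cfg$stage3_cap) {
      t <- t + 1
      keep <- keep & preds$score[idx] >= t
    }
    removed[idx[!keep]] <- TRUE
  }
  removed
}

#' Consistency annotation
#'
#' Flags predictions whose anticodon is in the domain's disallowed set
#' (\code{unexpected_anticodon}) and carries over the isotype-prediction
#' disagreement flag (\code{IPD}).  Flagged predictions are excluded from
#' the high-confidence set but reported with their flags.
#'
#' @param preds a [trna_predictions()] table
#' @param table a [decoding_table()]
#' @return the table with updated \code{note} column
#' @export
annotate_consistency <- function(preds, table) {
  if (nrow(preds) == 0L) return(preds)
  bad <- table$anticodon[!table$allowed]
  hit <- preds$anticodon %in% bad
  preds$note[hit] <- add_flag(preds$note[hit], "unexpected_anticodon")
  preds
}

#' Three-stage high-confidence filter
#'
#' Applies, in order: the pseudogene rule, the second-stage score filter,
#' the third-stage dynamic per-anticodon threshold, and the consistency
#' annotation (unexpected anticodon, IPD).  Consistency-flagged predictions
#' survive the score stages but are excluded from the high-confidence set
#' and reported separately.  Intended for eukaryotic predictions; invoking
#' it on bacterial or archaeal output warns.
#'
#' @param preds a classified [trna_predictions()] table
#' @param cfg a [filter_config()]
#' @param table a [decoding_table()]
#' @return object of class \code{filter_report}: the per-stage removal
#'   counts, per-prediction stage labels, and the high-confidence set
#' @export
high_confidence_filter <- function(preds, cfg = filter_config(),
                                   table = decoding_table("eukaryote")) {
  if (!identical(attr(table, "domain"), "eukaryote"))
    warning("the high-confidence filter is designed for eukaryotic ",
            "predictions; not needed (and not recommended) elsewhere")
  n <- nrow(preds)
  stage <- rep("high_confidence", n)
  if (n) {
    pseudo <- classify_pseudogene(preds, cfg)
    preds$note[pseudo] <- add_flag(preds$note[pseudo], "pseudo")
    stage[pseudo] <- "pseudogene"
    live <- !pseudo
    rm2 <- rep(FALSE, n)
    rm2[live] <- secondary_filter(preds[live, , drop = FALSE], cfg)
    stage[rm2] <- "stage2"
    live <- live & !rm2
    rm3 <- rep(FALSE, n)
    rm3[live] <- tertiary_filter(preds[live, , drop = FALSE], cfg)
    stage[rm3] <- "stage3"
    live <- live & !rm3
    preds <- annotate_consistency(preds, table)
    flagged <- live & (has_flag(preds$note, "unexpected_anticodon") |
                         has_flag(preds$note, "IPD"))
    stage[flagged] <- "flagged"
  }
  report <- list(
    input = n,
    removed = c(pseudogene = sum(stage == "pseudogene"),
                stage2 = sum(stage == "stage2"),
                stage3 = sum(stage == "stage3")),
    flagged = sum(stage == "flagged"),
    high_confidence = sum(stage == "high_confidence"),
    stage = stage,
    predictions = preds,
    hc_set = preds[stage == "high_confidence", , drop = FALSE]
  )
  class(report) <- "filter_report"
  report
}

#' @export
print.filter_report <- function(x, ...) {
  cat("High-confidence filter report\n")
  cat(sprintf("  total tRNA predictions      %6d\n", x$input))
  cat(sprintf("  possible pseudogenes        %6d\n", x$removed["pseudogene"]))
  cat(sprintf("  removed by secondary filter %6d\n", x$removed["stage2"]))
  cat(sprintf("  removed by tertiary filter  %6d\n", x$removed["stage3"]))
  cat(sprintf("  inconsistencies (flagged)   %6d\n", x$flagged))
  cat(sprintf("  high confidence set         %6d\n", x$high_confidence))
  invisible(x)
}
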