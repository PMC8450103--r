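# Isotype classification: anticodon extraction, decoding tables, comparative
# model scoring, and disagreement flagging.

#' Load a packaged anticodon decoding table
#'
#' Tables map every anticodon to an isotype via the reverse-complement codon
#' under the appropriate genetic code, mark anticodons not used by the
#' domain's decoding strategy (the eukaryotic table has exactly 15
#' disallowed entries), and carry the special cases: CAT decodes as
#' initiator/formyl methionine, elongator methionine or Ile2 (resolved by
#' comparative model scoring) and TCA decodes selenocysteine in nuclear
#' domains (tryptophan in vertebrate mitochondria).
#'
#' @param domain one of \code{"eukaryote"}, \code{"bacteria"},
#'   \code{"archaea"}, \code{"vert_mito"}
#' @return data.frame of class \code{decoding_table} with columns
#'   \code{anticodon}, \code{isotype}, \code{allowed}, and attribute
#'   \code{"domain"}
#' @export
decoding_table <- function(domain = c("eukaryote", "bacteria", "archaea",
                                      "vert_mito")) {
  domain <- match.arg(domain)
  path <- system.file("extdata", "decoding", paste0(domain, ".tsv"),
                      package = "cloverleaf", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "domain") <- domain
  class(df) <- c("decoding_table", "data.frame")
  df
}

CAU_SUBTYPES <- c("iMet", "fMet", "Met", "Ile2")

#' Map an anticodon to its isotype
#'
#' Standard-code mapping via the reverse-complement codon.  \code{CAT}
#' returns the three-way ambiguity set (initiator/formyl Met, elongator Met,
#' Ile2); \code{TCA} returns SeC in nuclear domains; \code{NNN} (or any
#' anticodon containing an ambiguity code) returns \code{"Undet"}.
#'
#' @param anticodon 3-mer (DNA alphabet)
#' @param table a [decoding_table()]
#' @return character vector of length 1 (or the ambiguity set for CAT)
#' @export
anticodon_to_isotype <- function(anticodon, table) {
  if (grepl("[^ACGT]", anticodon)) return("Undet")
  domain <- attr(table, "domain")
  if (anticodon == "CAT" && domain != "vert_mito") {
    ini <- if (identical(domain, "bacteria")) "fMet" else "iMet"
    return(c(ini, "Met", "Ile2"))
  }
  hit <- table$isotype[table$anticodon == anticodon]
  if (length(hit) == 0L) return("Undet")
  hit
}

#' Extract the anticodon from a structural parse
#'
#' Returns the residues emitted at the model's three anticodon consensus
#' columns, in order.  If any anticodon column was deleted in the parse the
#' anticodon is undetermined (\code{"NNN"}); insertions elsewhere in the
#' anticodon loop do not affect the result.
#'
#' @param parse a [score_sequence()] result with a parse
#' @param model the model that produced it (must carry anticodon columns)
#' @return a 3-mer or \code{"NNN"}
#' @export
extract_anticodon <- function(parse, model) {
  if (is.null(model$ac_cols)) return("NNN")
  pos <- parse$colpos[model$ac_cols]
  if (any(is.na(pos))) return("NNN")
  paste(c(DNA, "N")[parse$seq_int[pos] + 1L], collapse = "")
}

#' Score a sequence against a registry of isotype-specific models
#'
#' Global structural score of the (predicted mature) tRNA sequence against
#' every model in the registry.
#'
#' @param seq character string (the mature tRNA sequence)
#' @param registry named list of [train_cm()] models
#' @return named numeric vector of bit scores
#' @export
score_isotypes <- function(seq, registry) {
  stopifnot(length(registry) > 0)
  vapply(registry, function(m)
    score_sequence(m, seq, mode = "global", want_parse = FALSE)$score,
    numeric(1))
}

# model-registry names may be "Ala" or "Ala-TGC"; the isotype part is
# everything before the first '-'
registry_isotype <- function(name) sub("-.*$", "", name)

#' Classify one prediction by comparative isotype-model scoring
#'
#' Sets \code{isotype_model} to the highest-scoring registry model and flags
#' isotype-prediction disagreement (IPD) whenever the anticodon-derived
#' isotype (resolving CAT through the three CAU-subtype models) differs from
#' the model-derived one.  For CAT anticodons the reported isotype is the
#' top-scoring subtype model regardless of its absolute score.
#'
#' @param pred one-row list/data.frame with \code{anticodon} and
#'   \code{isotype_scores} (named numeric vector)
#' @param table a [decoding_table()]
#' @return list with \code{isotype}, \code{isotype_model},
#'   \code{isotype_score}, \code{ipd} (logical), \code{tie} (logical)
#' @export
classify_isotype <- function(pred, table) {
  sc <- pred$isotype_scores
  best <- names(sc)[order(-sc, names(sc))][1]
  tie <- sum(sc == max(sc)) > 1L
  by_model <- registry_isotype(best)
  ac_iso <- anticodon_to_isotype(pred$anticodon, table)
  if (length(ac_iso) > 1L) {
    # CAU three-way ambiguity: decide by the subtype models present
    sub <- sc[registry_isotype(names(sc)) %in% CAU_SUBTYPES]
    if (length(sub)) {
      top_sub <- registry_isotype(names(sub)[order(-sub, names(sub))][1])
      iso <- top_sub
      ipd <- !(by_model %in% top_sub)
    } else {
      iso <- ac_iso[1]
      ipd <- !(by_model %in% ac_iso)
    }
  } else {
    iso <- ac_iso
    ipd <- !identical(by_model, ac_iso) && !identical(ac_iso, "Undet")
    if (identical(ac_iso, "Undet")) iso <- "Undet"
    else iso <- ac_iso
  }
  list(isotype = iso, isotype_model = best, isotype_score = unname(max(sc)),
       ipd = ipd || tie, tie = tie)
}
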