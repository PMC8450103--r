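# The prediction table and its external representations.
#
# Internal coordinates are 0-based half-open on the plus strand of the query
# sequence, with an explicit strand field; conversion to the 1-based output
# conventions happens only in the writers (tabular output uses begin > end
# on the minus strand).

PRED_COLS <- c("seq_id", "begin", "end", "strand", "score", "primary_bits",
               "secondary_bits", "model", "anticodon", "isotype",
               "isotype_model", "isotype_score", "note", "intron_bounds")

#' Construct an (empty or partial) prediction table
#' @param df data.frame with a subset of the prediction columns
#' @return data.frame of class \code{trna_predictions}
#' @export
trna_predictions <- function(df = NULL) {
  base <- data.frame(seq_id = character(0), begin = integer(0),
                     end = integer(0), strand = character(0),
                     score = numeric(0), primary_bits = numeric(0),
                     secondary_bits = numeric(0), model = character(0),
                     anticodon = character(0), isotype = character(0),
                     isotype_model = character(0), isotype_score = numeric(0),
                     note = character(0), intron_bounds = character(0),
                     stringsAsFactors = FALSE)
  if (!is.null(df) && nrow(df)) {
    for (cn in setdiff(PRED_COLS, names(df))) {
      df[[cn]] <- if (cn %in% c("score", "primary_bits", "secondary_bits",
                                "isotype_score")) NA_real_
      else if (cn %in% c("begin", "end")) NA_integer_
      else ""
    }
    base <- df[, PRED_COLS]
  }
  class(base) <- c("trna_predictions", "data.frame")
  base
}

#' @export
print.trna_predictions <- function(x, ...) {
  cat("tRNA predictions:", nrow(x), "loci\n")
  if (nrow(x)) {
    df <- as.data.frame(x)
    df$score <- round(df$score, 1)
    print(utils::head(df[, c("seq_id", "begin", "end", "strand", "score",
                             "isotype", "anticodon", "note")], 20),
          row.names = FALSE)
    if (nrow(x) > 20) cat("...", nrow(x) - 20, "more\n")
  }
  invisible(x)
}

has_flag <- function(note, flag) {
  vapply(strsplit(note %||% "", ","), function(f) flag %in% f, logical(1))
}

add_flag <- function(note, flag) {
  ifelse(nzchar(note), ifelse(has_flag(note, flag), note,
                              paste(note, flag, sep = ",")), flag)
}

#' Write predictions to tabular, GFF3, or BED output
#'
#' Tabular output is 1-based inclusive with begin > end on the minus strand;
#' GFF3 is 1-based inclusive with an explicit strand column; BED is 0-based
#' half-open.  The note column carries the \code{pseudo},
#' \code{trunc_start}, \code{trunc_end}, \code{IPD} and
#' \code{unexpected_anticodon} flags; with \code{detail} the highest-scoring
#' isotype model and its score are included.
#'
#' @param preds a [trna_predictions()] table
#' @param path output file
#' @param style one of \code{"tabular"}, \code{"gff3"}, \code{"bed"}
#' @param detail include isotype-model detail columns (tabular only)
#' @return \code{path}, invisibly
#' @export
write_predictions <- function(preds, path, style = c("tabular", "gff3", "bed"),
                              detail = FALSE) {
  if (!is.character(style) || length(style) != 1 ||
      !style %in% c("tabular", "gff3", "bed")) {
    style <- tryCatch(match.arg(style), error = function(e)
      stop("usage error: unknown output style"))
  }
  p <- as.data.frame(preds)
  if (style == "tabular") {
    n <- nrow(p)
    b1 <- ifelse(p$strand == "-", p$end, p$begin + 1L)
    e1 <- ifelse(p$strand == "-", p$begin + 1L, p$end)
    hdr <- c("seq_id", "trna_no", "begin", "end", "isotype", "anticodon",
             "intron_bounds", "score", "note")
    df <- data.frame(p$seq_id, seq_len(n), b1, e1, p$isotype, p$anticodon,
                     ifelse(nzchar(p$intron_bounds), p$intron_bounds, "0-0"),
                     formatC(p$score, digits = 1, format = "f"), p$note,
                     stringsAsFactors = FALSE)
    names(df) <- hdr
    if (detail) {
      df$isotype_model <- p$isotype_model
      df$isotype_score <- formatC(p$isotype_score, digits = 1, format = "f")
    }
    con <- file(path, "w")
    writeLines(paste(names(df), collapse = "\t"), con)
    if (n) utils::write.table(df, con, sep = "\t", quote = FALSE,
                              row.names = FALSE, col.names = FALSE)
    close(con)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = p$seq_id,
    ranges = IRanges::IRanges(start = p$begin + 1L, end = p$end),
    strand = p$strand)
  if (style == "gff3") {
    gr$type <- "tRNA"
    gr$score <- p$score
    gr$source <- "cloverleaf"
    gr$ID <- sprintf("tRNA-%s-%s-%d", p$isotype, p$anticodon, seq_len(nrow(p)))
    gr$isotype <- p$isotype
    gr$anticodon <- p$anticodon
    if (any(nzchar(p$note))) gr$note <- p$note
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    gr$name <- sprintf("tRNA-%s-%s", p$isotype, p$anticodon)
    gr$score <- pmin(pmax(round(p$score * 10), 0), 1000)
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

#' Read a tabular prediction file written by [write_predictions()]
#' @param path file path
#' @return a [trna_predictions()] table (internal 0-based coordinates)
#' @export
read_predictions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(seq_id = "character",
                                         anticodon = "character",
                                         isotype = "character"))
  if (nrow(df) == 0L) return(trna_predictions())
  minus <- df$begin > df$end
  out <- data.frame(
    seq_id = df$seq_id,
    begin = ifelse(minus, df$end, df$begin) - 1L,
    end = ifelse(minus, df$begin, df$end),
    strand = ifelse(minus, "-", "+"),
    score = as.numeric(df$score),
    model = "", anticodon = df$anticodon, isotype = df$isotype,
    note = ifelse(is.na(df$note), "", as.character(df$note)),
    intron_bounds = ifelse(df$intron_bounds == "0-0", "",
                           df$intron_bounds),
    stringsAsFactors = FALSE)
  if ("isotype_model" %in% names(df)) {
    out$isotype_model <- df$isotype_model
    out$isotype_score <- as.numeric(df$isotype_score)
  }
  trna_predictions(out)
}
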