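# Two-pass genome scanning plus the exhaustive single-pass mode.

# run the first-pass DP on one oriented sequence, returning merged maximal
# segments >= cutoff (coordinates in the oriented frame)
first_pass_segments <- function(profile, s_int, cutoff) {
  r <- linear_scan(profile, s_int, cutoff)
  if (length(r$start) == 0L)
    return(data.frame(begin = integer(0), end = integer(0),
                      bits = numeric(0)))
  df <- data.frame(begin = r$start, end = r$end, bits = r$score)
  df <- df[order(df$begin, df$end), , drop = FALSE]
  out <- list(); cur <- df[1, ]
  for (i in seq_len(nrow(df))[-1]) {
    if (df$begin[i] <= cur$end) {
      cur$end <- max(cur$end, df$end[i]); cur$bits <- max(cur$bits, df$bits[i])
    } else {
      out[[length(out) + 1L]] <- cur; cur <- df[i, ]
    }
  }
  out[[length(out) + 1L]] <- cur
  do.call(rbind, out)
}

#' First-pass structure-free candidate scan
#'
#' Runs the linear-profile local scan over both strands of every input
#' sequence.  Each maximal local segment scoring at least
#' \code{cfg$first_pass_cutoff} bits becomes a candidate window, extended by
#' \code{cfg$candidate_flank} nucleotides on each side, clamped to the
#' sequence and merged with overlapping same-strand candidates.
#'
#' @param profile a [marginalize()] linear profile
#' @param seqs sequences (DNAStringSet or named character vector)
#' @param cfg a [scan_config()]
#' @return data.frame of candidates: \code{seq_id}, \code{strand},
#'   \code{begin}, \code{end} (forward 0-based half-open window),
#'   \code{bits} (best first-pass score inside)
#' @export
first_pass_scan <- function(profile, seqs, cfg = scan_config()) {
  seqs <- as_seq_char(seqs)
  out <- list()
  for (id in names(seqs)) {
    L <- nchar(seqs[[id]])
    fwd <- seq_to_int(seqs[[id]])
    for (strand in c("+", "-")) {
      s_int <- if (strand == "+") fwd else seq_to_int(revcomp(seqs[[id]]))
      seg <- first_pass_segments(profile, s_int, cfg$first_pass_cutoff)
      if (nrow(seg) == 0L) next
      b <- pmax(0L, seg$begin - cfg$candidate_flank)
      e <- pmin(L, seg$end + cfg$candidate_flank)
      if (strand == "-") { tmp <- b; b <- L - e; e <- L - tmp }
      df <- data.frame(seq_id = id, strand = strand, begin = b, end = e,
                       bits = seg$bits, stringsAsFactors = FALSE)
      df <- df[order(df$begin), , drop = FALSE]
      merged <- list(); cur <- df[1, ]
      for (i in seq_len(nrow(df))[-1]) {
        if (df$begin[i] <= cur$end) {
          cur$end <- max(cur$end, df$end[i])
          cur$bits <- max(cur$bits, df$bits[i])
        } else { merged[[length(merged) + 1L]] <- cur; cur <- df[i, ] }
      }
      merged[[length(merged) + 1L]] <- cur
      out[[length(out) + 1L]] <- do.call(rbind, merged)
    }
  }
  if (length(out) == 0L)
    return(data.frame(seq_id = character(0), strand = character(0),
                      begin = integer(0), end = integer(0),
                      bits = numeric(0)))
  do.call(rbind, out)
}

# structural scoring of one candidate window; returns a hit list or NULL
score_window <- function(model, seqs, seq_id, strand, wb, we, cutoff,
                         allow_trunc = TRUE) {
  L <- nchar(seqs[[seq_id]])
  segment <- substr(seqs[[seq_id]], wb + 1L, we)
  if (strand == "-") segment <- revcomp(segment)
  gene5_at_bound <- if (strand == "+") wb == 0L else we == L
  gene3_at_bound <- if (strand == "+") we == L else wb == 0L
  s_int <- seq_to_int(segment)
  res <- cm_dp(cm_for_cpp(model), s_int, 1L,
               allow_trunc && gene5_at_bound, allow_trunc && gene3_at_bound,
               TRUE)
  if (res$score < cutoff) return(NULL)
  a <- res$begin; b <- res$end
  if (b <= a) return(NULL)
  if (strand == "+") { gb <- wb + a; ge <- wb + b }
  else { gb <- we - b; ge <- we - a }
  cp <- res$colpos
  free <- cp == -2L
  cp[cp < 0L] <- NA_integer_
  cp <- cp + 1L
  attr(cp, "free") <- free
  parse <- structure(list(score = res$score, begin = a, end = b,
                          trunc5 = res$trunc5, trunc3 = res$trunc3,
                          mode = "local", model_name = model$meta$name,
                          seq_int = s_int, colpos = cp),
                     class = "cm_parse")
  dec <- decompose_parse(parse, model)
  parse$primary_bits <- unname(dec[[1]]); parse$secondary_bits <- unname(dec[[2]])
  list(seq_id = seq_id, strand = strand, begin = gb, end = ge,
       score = res$score, model = model$meta$name, parse = parse,
       window = c(wb, we), gene_seq = substr(segment, a + 1L, b))
}

#' Second-pass structural scoring of first-pass candidates
#'
#' Scores every candidate window with the full structural model (local mode;
#' truncated parses allowed when the window touches a sequence boundary) and
#' keeps hits at or above \code{cfg$report_cutoff} with the exact genomic
#' coordinates of the emitted+inserted span.
#'
#' @param model a [train_cm()] model
#' @param seqs sequences as given to [first_pass_scan()]
#' @param candidates candidate data.frame from [first_pass_scan()]
#' @param cfg a [scan_config()]
#' @return list of hits (each a list with \code{seq_id}, \code{strand},
#'   \code{begin}, \code{end}, \code{score}, \code{model}, \code{parse},
#'   \code{gene_seq})
#' @export
second_pass <- function(model, seqs, candidates, cfg = scan_config()) {
  seqs <- as_seq_char(seqs)
  hits <- list()
  for (i in seq_len(nrow(candidates))) {
    h <- score_window(model, seqs, candidates$seq_id[i],
                      candidates$strand[i], candidates$begin[i],
                      candidates$end[i], cfg$report_cutoff)
    if (!is.null(h)) hits[[length(hits) + 1L]] <- h
  }
  hits
}

#' Exhaustive single-pass structural scan
#'
#' Slides windows of \code{cfg$max_mode_window} nucleotides (overlapping by
#' \code{cfg$max_mode_overlap}) over both strands and scores each window
#' structurally; duplicate hits from overlapping windows are deduplicated by
#' coordinates.  On any genome its hit set is a superset of (or equal to)
#' the default two-pass pipeline's.
#'
#' @inheritParams second_pass
#' @return list of hits as in [second_pass()]
#' @export
scan_max <- function(model, seqs, cfg = scan_config()) {
  seqs <- as_seq_char(seqs)
  if (cfg$max_mode_window < model$clen)
    stop("usage error: max-mode window smaller than the model span")
  step <- cfg$max_mode_window - cfg$max_mode_overlap
  hits <- list()
  for (id in names(seqs)) {
    L <- nchar(seqs[[id]])
    if (L == 0L) next
    last <- max(0L, L - cfg$max_mode_window)
    starts <- unique(c(seq(0L, last, by = step), last))
    for (wb in starts) {
      we <- min(L, wb + cfg$max_mode_window)
      for (strand in c("+", "-")) {
        h <- score_window(model, seqs, id, strand, wb, we,
                          cfg$report_cutoff)
        if (!is.null(h)) hits[[length(hits) + 1L]] <- h
      }
    }
  }
  # dedupe by coordinates, keep best score
  if (length(hits) == 0L) return(hits)
  key <- vapply(hits, function(h)
    paste(h$seq_id, h$strand, h$begin, h$end), character(1))
  keep <- !duplicated(key)
  sc <- vapply(hits, `[[`, numeric(1), "score")
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    keep[idx] <- FALSE; keep[idx[which.max(sc[idx])]] <- TRUE
  }
  hits[keep]
}

#' Keep the top-scoring hit at each overlapping locus
#'
#' Among hits from (possibly) different models that overlap by at least one
#' nucleotide on the same strand, only the highest-scoring is retained; ties
#' break to the lexicographically first model name, then the leftmost begin.
#'
#' @param hits list of hits (from [second_pass()] / [scan_max()], possibly
#'   concatenated across models)
#' @return filtered list of hits
#' @export
resolve_overlaps <- function(hits) {
  if (length(hits) <= 1L) return(hits)
  sc <- vapply(hits, `[[`, numeric(1), "score")
  mod <- vapply(hits, `[[`, character(1), "model")
  beg <- vapply(hits, function(h) as.integer(h$begin), integer(1))
  ord <- order(-sc, mod, beg)
  kept <- list()
  for (i in ord) {
    h <- hits[[i]]
    clash <- any(vapply(kept, function(k)
      k$seq_id == h$seq_id && k$strand == h$strand &&
        k$begin < h$end && h$begin < k$end, logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- h
  }
  ord2 <- order(vapply(kept, `[[`, character(1), "seq_id"),
                vapply(kept, function(h) as.integer(h$begin), integer(1)))
  kept[ord2]
}
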