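# Canonical intron detection from the structural parse, and noncanonical
# bulge-helix-bulge (BHB) intron search by iterative splice-and-rescore.

#' Remove an interval from a sequence
#'
#' @param seq character string
#' @param begin,end 0-based half-open bounds of the intron within \code{seq}
#' @return the spliced sequence
#' @export
splice <- function(seq, begin, end) {
  if (begin > end) stop("usage error: inverted intron bounds")
  n <- nchar(seq)
  if (begin < 0 || end > n) stop("usage error: intron bounds outside sequence")
  paste0(substr(seq, 1, begin), substr(seq, end + 1, n))
}

#' Detect a canonical intron from a parse
#'
#' A canonical tRNA intron lies one nucleotide downstream of the anticodon
#' (between positions 37 and 38).  Any insertion of at least
#' \code{cfg$min_intron_len} residues attached between the consensus column
#' one position 3' of the anticodon and its successor is reported with
#' exact bounds.
#'
#' @param parse a [score_sequence()] parse of the precursor
#' @param model the model (with anticodon columns in its metadata)
#' @param cfg an [intron_config()]
#' @return data.frame with columns \code{kind}, \code{begin}, \code{end}
#'   (0-based half-open, in the parsed sequence's coordinates),
#'   \code{bhb_bits}, \code{iteration}; zero rows if none found
#' @export
detect_canonical <- function(parse, model, cfg = intron_config()) {
  empty <- data.frame(kind = character(0), begin = integer(0),
                      end = integer(0), bhb_bits = numeric(0),
                      iteration = integer(0))
  if (is.null(model$ac_cols)) return(empty)
  c37 <- max(model$ac_cols) + 1L
  if (c37 >= model$clen) return(empty)
  # the canonical location is the 37/38 junction, but random intron ends
  # can absorb one or two flanking consensus residues in the alignment, so
  # attachment anywhere in the anticodon loop around that junction counts
  cand_cols <- max(1L, model$ac_cols[1] - 1L):min(model$clen - 1L, c37 + 2L)
  best <- NULL
  for (cc in cand_cols) {
    p1 <- parse$colpos[cc]
    if (is.na(p1)) next
    later <- parse$colpos[(cc + 1L):model$clen]
    later <- later[!is.na(later)]
    if (length(later) == 0L) next
    p2 <- min(later)
    gap <- p2 - p1 - 1L
    if (gap >= cfg$min_intron_len && (is.null(best) || gap > best$gap))
      best <- list(p1 = p1, p2 = p2, gap = gap)
  }
  if (is.null(best)) return(empty)
  data.frame(kind = "canonical", begin = best$p1, end = best$p2 - 1L,
             bhb_bits = NA_real_, iteration = 0L)
}

#' Search for noncanonical (bulge-helix-bulge) introns
#'
#' Implements the iterative splice-and-rescore procedure: the candidate
#' locus is extended by \code{cfg$flank} nucleotides on each side, scanned
#' with every BHB model, and every BHB hit of at least
#' \code{cfg$bhb_accept_bits} bits is tentatively spliced out.  A splice is
#' accepted only if the score of the predicted mature tRNA with the intron
#' removed is higher than the unspliced form.  Iteration continues until no
#' accepted splice improves the score, \code{cfg$max_iterations} is
#' reached, or the mature length would drop below \code{cfg$min_mature_len}
#' (introns lying in such close proximity that one must be removed before
#' the second BHB motif can form are recovered in later iterations).  The
#' reported score is that of the final mature sequence.
#'
#' @param precursor character string: candidate locus already extended with
#'   flanking sequence (gene orientation)
#' @param trna_model the domain tRNA model used for rescoring
#' @param bhb_models list of BHB intron models
#' @param cfg an [intron_config()]
#' @return list with \code{mature_seq}, \code{mature_parse} (local parse of
#'   the final mature sequence within the spliced precursor),
#'   \code{introns} (data.frame: precursor-coordinate 0-based half-open
#'   bounds, \code{bhb_bits}, \code{iteration}), and \code{score}
#' @export
search_noncanonical <- function(precursor, trna_model, bhb_models,
                                cfg = intron_config()) {
  cur <- precursor
  # map from current coordinates back to precursor coordinates
  coord <- seq_len(nchar(precursor)) - 1L
  introns <- list()
  base <- score_sequence(trna_model, cur, mode = "local")
  for (iter in seq_len(cfg$max_iterations)) {
    best <- NULL
    for (bm in bhb_models) {
      bp <- score_sequence(bm, cur, mode = "local", want_parse = FALSE)
      if (bp$score < cfg$bhb_accept_bits) next
      ilen <- bp$end - bp$begin
      if (ilen < cfg$min_intron_len) next
      spliced <- splice(cur, bp$begin, bp$end)
      sp <- score_sequence(trna_model, spliced, mode = "local")
      mature_len <- sp$end - sp$begin
      if (mature_len < cfg$min_mature_len) next
      if (sp$score > base$score &&
          (is.null(best) || sp$score > best$sp$score)) {
        best <- list(bp = bp, sp = sp, spliced = spliced)
      }
    }
    if (is.null(best)) break
    introns[[length(introns) + 1L]] <- data.frame(
      kind = "noncanonical",
      begin = coord[best$bp$begin + 1L],
      end = coord[best$bp$end] + 1L,
      bhb_bits = best$bp$score, iteration = iter)
    keep <- setdiff(seq_len(nchar(cur)), (best$bp$begin + 1L):best$bp$end)
    coord <- coord[keep]
    cur <- best$spliced
    base <- best$sp
  }
  mature_seq <- substr(cur, base$begin + 1L, base$end)
  list(mature_seq = mature_seq, mature_parse = base, coord_map = coord,
       introns = if (length(introns)) do.call(rbind, introns) else
         data.frame(kind = character(0), begin = integer(0),
                    end = integer(0), bhb_bits = numeric(0),
                    iteration = integer(0)),
       score = base$score)
}
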