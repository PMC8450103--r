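# Scoring sequences against a trained profile-SCFG.

cm_for_cpp <- function(model) {
  list(n = model$n, clen = model$clen, root = model$root,
       ntype = model$ntype, lcol = model$lcol, rcol = model$rcol,
       child = model$child, bl = model$bl, br = model$br,
       tr = model$tr, insl = model$insl, insr = model$insr,
       esingle = model$esingle, epair = model$epair)
}

#' Score a sequence against a profile-SCFG model
#'
#' Computes the maximum-bit-score structural parse by CYK-style dynamic
#' programming over the model's guide tree.  In \code{global} mode the whole
#' sequence must be generated by the model; in \code{local} mode the model is
#' aligned to the best-scoring subsequence and flanking residues are
#' unpenalized (the model itself is still traversed in full).  With
#' \code{allow_trunc}, consensus columns at one sequence boundary may be
#' left unemitted at zero penalty ("truncated hit"); pairs losing one side
#' are scored by the marginal of the remaining side.  N (and other ambiguity
#' codes) emit at 0 bits against the uniform background.
#'
#' @param model a [train_cm()] model
#' @param seq a character string, \code{DNAString}, or integer-encoded
#'   sequence
#' @param mode \code{"global"} or \code{"local"}
#' @param allow_trunc allow boundary-truncated parses (local mode only)
#' @param want_parse return the per-column alignment (needed for anticodon
#'   extraction, intron detection and score decomposition)
#' @return object of class \code{cm_parse}: \code{score},
#'   \code{primary_bits}, \code{secondary_bits} (score == primary +
#'   secondary), \code{begin}/\code{end} (0-based half-open span of the
#'   scored subsequence), \code{trunc5}/\code{trunc3}, and \code{colpos}
#'   (per consensus column: 1-based emitted position, NA if deleted, with
#'   attribute \code{"free"} marking truncation-deleted columns)
#' @export
score_sequence <- function(model, seq, mode = c("local", "global"),
                           allow_trunc = FALSE, want_parse = TRUE) {
  mode <- match.arg(mode)
  s <- if (is.integer(seq)) seq else seq_to_int(as_seq_char(seq)[[1]])
  res <- cm_dp(cm_for_cpp(model), s, ifelse(mode == "global", 0L, 1L),
               allow_trunc, allow_trunc, want_parse)
  parse <- list(score = res$score, begin = res$begin, end = res$end,
                trunc5 = res$trunc5, trunc3 = res$trunc3,
                mode = mode, model_name = model$meta$name, seq_int = s)
  if (!is.null(res$colpos)) {
    cp <- res$colpos
    free <- cp == -2L
    cp[cp < 0L] <- NA_integer_
    cp <- cp + 1L  # to 1-based
    attr(cp, "free") <- free
    parse$colpos <- cp
    dec <- decompose_parse(parse, model)
    parse$primary_bits <- unname(dec[1])
    parse$secondary_bits <- unname(dec[2])
  }
  structure(parse, class = "cm_parse")
}

#' @export
print.cm_parse <- function(x, ...) {
  cat(sprintf("Parse vs %s: %.2f bits", x$model_name %||% "?", x$score))
  if (!is.null(x$primary_bits))
    cat(sprintf(" (primary %.2f + secondary %.2f)", x$primary_bits,
                x$secondary_bits))
  cat(sprintf("; span [%d,%d)", x$begin, x$end))
  if (isTRUE(x$trunc5)) cat(" trunc5")
  if (isTRUE(x$trunc3)) cat(" trunc3")
  cat("\n")
  invisible(x)
}

# primary/secondary decomposition of a computed parse: primary re-scores
# every matched pair with the sum of its two marginal single-column scores;
# secondary is the remainder (covariation signal).
decompose_parse <- function(parse, model) {
  cp <- parse$colpos
  s <- parse$seq_int
  sec <- 0
  for (v in which(model$ntype == NT_PAIR)) {
    i <- model$lcol[v]; j <- model$rcol[v]
    pi <- cp[i]; pj <- cp[j]
    if (is.na(pi) || is.na(pj)) next
    x <- s[pi]; y <- s[pj]
    if (x >= 4L || y >= 4L) next  # ambiguity already scored marginally
    e2 <- model$epair[v, x + 4L * y + 1L]  # column-major: left fastest
    sec <- sec + (e2 - model$esingle[i, x + 1L] - model$esingle[j, y + 1L])
  }
  c(primary = parse$score - sec, secondary = sec)
}

#' Decompose a parse score into primary and secondary components
#'
#' The primary (sequence-only) score re-scores the identical parse with every
#' pair emission replaced by the sum of its two marginal single-residue
#' scores, transitions unchanged; the secondary (structure) score is the
#' remainder, so \code{score == primary + secondary} exactly.
#'
#' @param parse a [score_sequence()] result with a parse
#' @param model the model that produced it
#' @return named numeric vector \code{c(primary, secondary)}
#' @export
decompose_score <- function(parse, model) {
  if (is.null(parse$colpos))
    stop("parse has no alignment; call score_sequence(want_parse = TRUE)")
  decompose_parse(parse, model)
}

#' Collapse a structural model to a structure-free linear profile
#'
#' Each pair column is released into its two marginal single columns (column
#' order preserved); per-column match/delete costs and per-gap insert
#' parameters are carried over.  This is the first-pass scanning profile.
#'
#' @param model a [train_cm()] model
#' @return object of class \code{linear_profile}
#' @export
marginalize <- function(model) {
  clen <- model$clen
  trM <- numeric(clen); trD <- numeric(clen)
  for (v in seq_len(model$n)) {
    ty <- model$ntype[v]
    if (ty == NT_SL) {
      trM[model$lcol[v]] <- model$tr[v, 1]; trD[model$lcol[v]] <- model$tr[v, 2]
    } else if (ty == NT_SR) {
      trM[model$rcol[v]] <- model$tr[v, 1]; trD[model$rcol[v]] <- model$tr[v, 2]
    } else if (ty == NT_PAIR) {
      p <- 2^model$tr[v, ]
      trM[model$lcol[v]] <- log2(p[1] + p[3]); trD[model$lcol[v]] <- log2(p[2] + p[4])
      trM[model$rcol[v]] <- log2(p[1] + p[4]); trD[model$rcol[v]] <- log2(p[2] + p[3])
    }
  }
  gpo <- rep(-1, clen + 1); gpe <- rep(0.5, clen + 1)
  sg <- slot_gaps(list(ntype = model$ntype, lcol = model$lcol,
                       rcol = model$rcol, child = model$child,
                       bl = model$bl, br = model$br, root = model$root))
  canon <- sg[!duplicated(sg$gap), ]
  for (r in seq_len(nrow(canon))) {
    g <- canon$gap[r]
    pr <- if (canon$side[r] == "l") model$insl[canon$node[r], ]
          else model$insr[canon$node[r], ]
    gpo[g + 1L] <- pr[1]; gpe[g + 1L] <- pr[2]
  }
  structure(list(clen = clen, e = model$esingle, trM = trM, trD = trD,
                 gpo = gpo, gpe = gpe, name = model$meta$name),
            class = "linear_profile")
}

#' @export
print.linear_profile <- function(x, ...) {
  cat("Linear (structure-free) profile:", x$name %||% "<unnamed>", "-",
      x$clen, "columns\n")
  invisible(x)
}
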