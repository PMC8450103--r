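# Training compact profile-SCFG ("covariance model") objects from seed
# alignments.
#
# Parameterization: consensus columns are alignment columns with gap fraction
# < 0.5.  Single-column emissions are Laplace-smoothed log-odds against a
# fixed background; pair columns carry a 16-cell log-odds table plus the two
# marginal single-column tables (used by the structure-free first pass, by
# left/right-only emission, and by the primary/secondary score
# decomposition).  Transitions are per-node log2 usage probabilities; insert
# slots are geometric (open/extend) trained from the non-consensus columns
# falling in each inter-column gap.

#' Train a profile-SCFG model from a seed alignment
#'
#' Builds the guide tree from the consensus structure restricted to consensus
#' columns (gap fraction < 0.5), then estimates emission log-odds (in bits,
#' base 2) with pseudocount \code{pseudocount} per cell, per-node transition
#' probabilities, and geometric insert-slot parameters.  IUPAC ambiguity
#' codes contribute fractionally (uniformly over their residue set).
#'
#' @param aln a [seed_alignment()]
#' @param pseudocount Laplace pseudocount added per emission cell and per
#'   transition usage count (default 1)
#' @param background background residue probabilities (default uniform 0.25)
#' @return an object of class \code{trna_cm}
#' @examples
#' aln <- seed_alignment("s1", "GGGAAACCC", "<<<...>>>")
#' m <- train_cm(aln)
#' m$clen
#' @export
train_cm <- function(aln, pseudocount = 1, background = rep(0.25, 4)) {
  stopifnot(inherits(aln, "seed_alignment"))
  a <- pseudocount
  bg <- background / sum(background)
  M <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  N <- nrow(M); W <- ncol(M)
  isgap <- matrix(M %in% GAP_CHARS, N, W)
  gapfrac <- colMeans(isgap)
  ccols <- which(gapfrac < 0.5)
  clen <- length(ccols)
  if (clen == 0L) stop("training error: no consensus columns")

  pt_full <- parse_structure(aln$ss_cons)
  # consensus-level pairing: both partners must be consensus columns
  cidx <- integer(W); cidx[ccols] <- seq_len(clen)
  pt <- integer(clen)
  for (k in seq_len(clen)) {
    p <- pt_full[ccols[k]]
    if (p > 0L && cidx[p] > 0L) pt[k] <- cidx[p]
  }
  ss <- rep(".", clen)
  ss[pt > 0 & pt > seq_len(clen)] <- "<"
  ss[pt > 0 & pt < seq_len(clen)] <- ">"
  ss <- paste(ss, collapse = "")
  gt <- build_guide_tree(ss)
  n <- gt$n

  frac_at <- function(ch) {
    # rows of iupac_frac for a character vector; gaps give NA rows
    out <- matrix(NA_real_, length(ch), 4)
    ok <- !(ch %in% GAP_CHARS)
    bad <- ok & !is_iupac(ch)
    if (any(bad))
      stop("format error: invalid residue '", ch[which(bad)[1]], "'")
    out[ok, ] <- iupac_frac[ch[ok], , drop = FALSE]
    out
  }

  esingle <- matrix(0, clen, 4)
  epair <- matrix(0, n, 16)
  tr <- matrix(0, n, 4)
  insl <- matrix(-1, n, 2)
  insr <- matrix(-1, n, 2)
  singleprob <- matrix(NA_real_, clen, 4)
  pairprob <- matrix(NA_real_, n, 16)
  bg2 <- as.vector(outer(bg, bg))

  for (v in seq_len(n)) {
    ty <- gt$ntype[v]
    if (ty %in% c(NT_SL, NT_SR)) {
      col <- if (ty == NT_SL) gt$lcol[v] else gt$rcol[v]
      ch <- M[, ccols[col]]
      fr <- frac_at(ch)
      emit <- !isgap[, ccols[col]]
      cnt <- colSums(fr[emit, , drop = FALSE])
      ne <- sum(emit)
      p <- (cnt + a) / (ne + 4 * a)
      singleprob[col, ] <- p
      esingle[col, ] <- log2(p / bg)
      tr[v, 1:2] <- log2((c(sum(emit), N - sum(emit)) + a) / (N + 2 * a))
    } else if (ty == NT_PAIR) {
      i <- ccols[gt$lcol[v]]; j <- ccols[gt$rcol[v]]
      gl <- isgap[, i]; gr <- isgap[, j]
      both <- !gl & !gr
      cnt16 <- rep(0, 16)
      if (any(both)) {
        fl <- frac_at(M[both, i]); fr2 <- frac_at(M[both, j])
        for (r in seq_len(sum(both)))
          cnt16 <- cnt16 + as.vector(outer(fl[r, ], fr2[r, ]))
      }
      np <- sum(both)
      p16 <- (cnt16 + a) / (np + 16 * a)
      pairprob[v, ] <- p16
      epair[v, ] <- log2(p16 / bg2)
      pm <- matrix(p16, 4, 4)  # rows = left residue, cols = right residue
      singleprob[gt$lcol[v], ] <- rowSums(pm)
      singleprob[gt$rcol[v], ] <- colSums(pm)
      esingle[gt$lcol[v], ] <- log2(rowSums(pm) / bg)
      esingle[gt$rcol[v], ] <- log2(colSums(pm) / bg)
      use <- c(sum(both), sum(gl & gr), sum(!gl & gr), sum(gl & !gr))
      tr[v, ] <- log2((use + a) / (N + 4 * a))
    }
  }

  # insert slots: which slots exist per node type
  for (v in seq_len(n)) {
    ty <- gt$ntype[v]
    if (ty %in% c(NT_ROOT, NT_SL, NT_PAIR, NT_BIF, NT_END))
      insl[v, ] <- c(a / (N + 2 * a), 0.5)
    if (ty %in% c(NT_ROOT, NT_SR, NT_PAIR))
      insr[v, ] <- c(a / (N + 2 * a), 0.5)
  }
  # train the canonical slot of each inter-column gap from the non-consensus
  # columns lying in that gap
  sg <- slot_gaps(gt)
  canon <- sg[!duplicated(sg$gap), ]
  bnd <- c(0L, ccols, W + 1L)
  for (r in seq_len(nrow(canon))) {
    g <- canon$gap[r]
    lo <- if (g == 0L) 0L else ccols[g]
    hi <- if (g == clen) W + 1L else ccols[g + 1L]
    cols_in <- setdiff(seq_len(W), ccols)
    cols_in <- cols_in[cols_in > lo & cols_in < hi]
    k <- if (length(cols_in))
      rowSums(!isgap[, cols_in, drop = FALSE]) else rep(0L, N)
    n1 <- sum(k >= 1); tot <- sum(k)
    po <- (n1 + a) / (N + 2 * a)
    pe <- (tot - n1 + a) / (tot + 2 * a)
    if (canon$side[r] == "l") insl[canon$node[r], ] <- c(po, pe)
    else insr[canon$node[r], ] <- c(po, pe)
  }

  ac_cols <- NULL
  if (!is.null(aln$ac_line)) {
    st <- which(strsplit(aln$ac_line, "")[[1]] == "*")
    if (length(st) == 3L) {
      if (!all(st %in% ccols))
        stop("training error: anticodon columns are not consensus columns")
      ac_cols <- cidx[st]
    }
  }

  meta <- aln$meta
  meta$name <- meta$name %||% meta$isotype %||% "model"
  structure(list(
    meta = meta, bg = bg, pseudocount = a,
    n = n, clen = clen, root = gt$root,
    ntype = gt$ntype, lcol = gt$lcol, rcol = gt$rcol,
    child = gt$child, bl = gt$bl, br = gt$br,
    tr = tr, insl = insl, insr = insr,
    esingle = esingle, epair = epair,
    singleprob = singleprob, pairprob = pairprob,
    ss = ss, ac_cols = ac_cols, nseq = N
  ), class = "trna_cm")
}

#' @export
print.trna_cm <- function(x, ...) {
  cat("Profile-SCFG model:", x$meta$name %||% "<unnamed>", "\n")
  cat("  consensus length:", x$clen, "columns;",
      sum(x$ntype == NT_PAIR), "base pairs;",
      sum(x$ntype == NT_BIF), "bifurcations\n")
  if (!is.null(x$meta$isotype))
    cat("  isotype:", x$meta$isotype,
        if (!is.null(x$meta$anticodon)) paste0("(", x$meta$anticodon, ")"),
        "\n")
  if (!is.null(x$ac_cols))
    cat("  anticodon columns:", paste(x$ac_cols, collapse = ","), "\n")
  cat("  trained on", x$nseq, "sequences\n")
  invisible(x)
}

#' @export
summary.trna_cm <- function(object, ...) {
  x <- object
  cons <- vapply(seq_len(x$clen), function(c) DNA[which.max(x$esingle[c, ])],
                 character(1))
  cat("Profile-SCFG model:", x$meta$name %||% "<unnamed>", "\n")
  cat("  consensus:", paste(cons, collapse = ""), "\n")
  cat("  structure:", x$ss, "\n")
  info <- rowSums(2^x$esingle * x$bg[col(x$esingle)] * x$esingle)
  cat("  mean per-column information:", round(mean(info), 3), "bits\n")
  invisible(x)
}
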