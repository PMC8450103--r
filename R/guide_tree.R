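# Guide-tree construction from a consensus secondary-structure string.

OPENERS <- c("<", "(", "[", "{")
CLOSERS <- c(">", ")", "]", "}")
UNPAIRED <- c(".", ",", "-", "_", ":", "~")

#' Parse a consensus structure string into a pairing table
#'
#' Accepts the WUSS-style bracket variants \code{<>}, \code{()}, \code{[]},
#' \code{{}} for base pairs and \code{. , - _ : ~} for unpaired columns.
#' Brackets must be balanced and strictly nested (no pseudoknots).
#'
#' @param ss structure string
#' @return integer vector, \code{pt[i]} = partner column of i (0 if unpaired)
#' @export
parse_structure <- function(ss) {
  ch <- strsplit(ss, "", fixed = TRUE)[[1]]
  n <- length(ch)
  pt <- integer(n)
  stack_pos <- integer(0)
  stack_type <- integer(0)
  for (i in seq_len(n)) {
    oi <- match(ch[i], OPENERS)
    ci <- match(ch[i], CLOSERS)
    if (!is.na(oi)) {
      stack_pos <- c(stack_pos, i)
      stack_type <- c(stack_type, oi)
    } else if (!is.na(ci)) {
      if (length(stack_pos) == 0L)
        stop("structure error: unbalanced brackets at column ", i)
      k <- length(stack_pos)
      if (stack_type[k] != ci)
        stop("structure error: crossing or mismatched brackets at column ", i)
      pt[i] <- stack_pos[k]
      pt[stack_pos[k]] <- i
      stack_pos <- stack_pos[-k]
      stack_type <- stack_type[-k]
    } else if (!(ch[i] %in% UNPAIRED)) {
      stop("structure error: unexpected character '", ch[i], "' at column ", i)
    }
  }
  if (length(stack_pos) > 0L)
    stop("structure error: unbalanced brackets (", length(stack_pos),
         " unclosed)")
  pt
}

# node type codes shared with the C++ scorer
NT_ROOT <- 0L; NT_SL <- 1L; NT_SR <- 2L; NT_PAIR <- 3L; NT_BIF <- 4L
NT_END <- 5L

#' Build a guide tree from a consensus secondary structure
#'
#' Decomposes a nested structure into PAIR, SINGLE (left/right emitting),
#' BIFURCATION, ROOT and END nodes.  The in-order traversal of emitting nodes
#' recovers the structure exactly; a bifurcation arises exactly where a loop
#' encloses two or more helices.
#'
#' @param ss consensus structure string (see [parse_structure()])
#' @return an object of class \code{guide_tree}: parallel vectors
#'   \code{ntype}, \code{lcol}, \code{rcol}, \code{child}, \code{bl},
#'   \code{br}, with \code{root} index
#' @examples
#' gt <- build_guide_tree("<<...>>")
#' table(gt$ntype)
#' @export
build_guide_tree <- function(ss) {
  pt <- parse_structure(ss)
  env <- new.env()
  env$ntype <- integer(0); env$lcol <- integer(0); env$rcol <- integer(0)
  env$child <- integer(0); env$bl <- integer(0); env$br <- integer(0)
  add <- function(ty, lc = 0L, rc = 0L, ch = 0L, bl = 0L, br = 0L) {
    env$ntype <- c(env$ntype, ty); env$lcol <- c(env$lcol, lc)
    env$rcol <- c(env$rcol, rc); env$child <- c(env$child, ch)
    env$bl <- c(env$bl, bl); env$br <- c(env$br, br)
    length(env$ntype)
  }
  build <- function(i, j) {
    if (i > j) return(add(NT_END))
    if (pt[i] == 0L) {
      ch <- build(i + 1L, j)
      return(add(NT_SL, lc = i, ch = ch))
    }
    if (pt[j] == 0L) {
      ch <- build(i, j - 1L)
      return(add(NT_SR, rc = j, ch = ch))
    }
    if (pt[i] == j) {
      ch <- build(i + 1L, j - 1L)
      return(add(NT_PAIR, lc = i, rc = j, ch = ch))
    }
    k <- pt[i]
    l <- build(i, k)
    r <- build(k + 1L, j)
    add(NT_BIF, bl = l, br = r)
  }
  n <- nchar(ss)
  ch <- build(1L, n)
  root <- add(NT_ROOT, ch = ch)
  structure(list(ntype = env$ntype, lcol = env$lcol, rcol = env$rcol,
                 child = env$child, bl = env$bl, br = env$br,
                 root = root, n = length(env$ntype), clen = n, ss = ss),
            class = "guide_tree")
}

#' @export
print.guide_tree <- function(x, ...) {
  cnt <- table(factor(x$ntype, levels = 0:5,
                      labels = c("ROOT", "SINGLE_L", "SINGLE_R", "PAIR",
                                 "BIF", "END")))
  cat("Guide tree over", x$clen, "consensus columns\n")
  print(cnt)
  invisible(x)
}

# Generation-order traversal: for every insert slot, record the gap
# (number of consensus columns emitted before the slot) it sits in.
# Returns data.frame(node, side in {"l","r"}, gap in 0..clen).
slot_gaps <- function(gt) {
  env <- new.env(); env$last <- 0L
  env$node <- integer(0); env$side <- character(0); env$gap <- integer(0)
  slot <- function(v, side) {
    env$node <- c(env$node, v); env$side <- c(env$side, side)
    env$gap <- c(env$gap, env$last)
  }
  walk <- function(v) {
    ty <- gt$ntype[v]
    if (ty == NT_END) { slot(v, "l"); return(invisible()) }
    if (ty == NT_SL) {
      env$last <- gt$lcol[v]; slot(v, "l"); walk(gt$child[v])
    } else if (ty == NT_SR) {
      walk(gt$child[v]); slot(v, "r"); env$last <- gt$rcol[v]
    } else if (ty == NT_PAIR) {
      env$last <- gt$lcol[v]; slot(v, "l"); walk(gt$child[v])
      slot(v, "r"); env$last <- gt$rcol[v]
    } else if (ty == NT_BIF) {
      walk(gt$bl[v]); slot(v, "l"); walk(gt$br[v])
    } else { # ROOT
      slot(v, "l"); walk(gt$child[v]); slot(v, "r")
    }
  }
  walk(gt$root)
  data.frame(node = env$node, side = env$side, gap = env$gap,
             stringsAsFactors = FALSE)
}
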