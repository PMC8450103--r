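#' @useDynLib cloverleaf, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats simulate runif
#' @importFrom utils head read.table write.table
#' @import methods
NULL

DNA <- c("A", "C", "G", "T")

GAP_CHARS <- c("-", ".", "_", "~")

# fractional residue weights for IUPAC codes (each row sums to 1)
iupac_frac <- local({
  sets <- list(
    A = "A", C = "C", G = "G", T = "T", U = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
    D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T")
  )
  m <- matrix(0, length(sets), 4, dimnames = list(names(sets), DNA))
  for (i in seq_along(sets)) m[i, sets[[i]]] <- 1 / length(sets[[i]])
  m
})

is_iupac <- function(ch) ch %in% rownames(iupac_frac)

#' Convert a nucleotide string to the internal integer encoding
#'
#' A,C,G,T map to 0..3; N and all other IUPAC ambiguity codes map to 4
#' (scored as background).  U is normalized to T.
#' @param x a single character string
#' @return integer vector
#' @keywords internal
seq_to_int <- function(x) {
  ch <- strsplit(toupper(chartr("Uu", "Tt", x)), "", fixed = TRUE)[[1]]
  i <- match(ch, DNA) - 1L
  i[is.na(i)] <- 4L
  i
}

int_to_seq <- function(i) paste(c(DNA, "N")[i + 1L], collapse = "")

#' Reverse complement of a nucleotide string
#' @param x character string (IUPAC codes allowed)
#' @return character string
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# normalize any sequence-ish input to a named character vector
as_seq_char <- function(x) {
  if (inherits(x, "XStringSet")) {
    out <- as.character(x)
  } else if (inherits(x, "XString")) {
    out <- as.character(x)
    names(out) <- "seq1"
  } else if (is.character(x)) {
    out <- x
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  } else {
    stop("cannot interpret input as nucleotide sequences")
  }
  toupper(chartr("Uu", "Tt", out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
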