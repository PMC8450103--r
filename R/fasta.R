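# FASTA input/output (thin wrappers over Biostrings with the package's
# normalization rules).

#' Read a multi-record FASTA file
#'
#' Records are uppercased and U is normalized to T; IUPAC ambiguity codes
#' are preserved.  Malformed records or residues outside the IUPAC DNA
#' alphabet raise a format error.
#'
#' @param path file path
#' @return a \code{DNAStringSet}
#' @export
read_fasta <- function(path) {
  x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                error = function(e) stop("format error reading ", path, ": ",
                                         conditionMessage(e)))
  if (length(x) == 0L) return(Biostrings::DNAStringSet())
  if (any(!nzchar(names(x))))
    stop("format error: record with empty id in ", path)
  ch <- toupper(chartr("Uu", "Tt", as.character(x)))
  bad <- grepl("[^ACGTRYSWKMBDHVN]", ch)
  if (any(bad)) {
    ln <- which(bad)[1]
    stop("format error: invalid residue in record '", names(x)[ln], "'")
  }
  out <- Biostrings::DNAStringSet(ch)
  names(out) <- names(x)
  out
}

#' Write sequences to a FASTA file
#' @param seqs DNAStringSet or named character vector
#' @param path file path
#' @return \code{path}, invisibly
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "XStringSet"))
    seqs <- Biostrings::DNAStringSet(as_seq_char(seqs))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
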