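# Fifth-order Markov virtual genomes and the false-positive evaluation
# harness.

#' Train a Markov chain on genomic sequence
#'
#' Conditional distributions are estimated from (order+1)-mer counts with a
#' pseudocount of 1; windows containing non-ACGT characters are skipped.
#'
#' @param seqs source sequences (DNAStringSet or character)
#' @param order chain order (default 5)
#' @return object of class \code{markov_model}: \code{order}, \code{cond}
#'   (4^order x 4 conditional matrix), \code{init} (initial distribution
#'   over order-mers), \code{source_len}
#' @export
train_markov <- function(seqs, order = 5) {
  if (length(seqs) == 0L) stop("empty input")
  if (!inherits(seqs, "XStringSet"))
    seqs <- Biostrings::DNAStringSet(as_seq_char(seqs))
  if (length(seqs) == 0L || sum(Biostrings::width(seqs)) == 0L)
    stop("empty input")
  total <- sum(Biostrings::width(seqs))
  if (total < 4^(order + 1))
    warning("source shorter than 4^(order+1); conditionals will be noisy")
  kcnt <- colSums(Biostrings::oligonucleotideFrequency(seqs, order + 1))
  icnt <- colSums(Biostrings::oligonucleotideFrequency(seqs, max(order, 1)))
  cond <- matrix(kcnt, ncol = 4, byrow = TRUE) + 1
  cond <- cond / rowSums(cond)
  init <- icnt + 1
  init <- init / sum(init)
  structure(list(order = order, cond = cond, init = init,
                 source_len = total),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("Markov chain of order", x$order, "trained on", x$source_len, "nt\n")
  invisible(x)
}

#' Generate a virtual genome from a Markov model
#'
#' Deterministic under a fixed seed; as the length grows, the k-mer
#' frequency profile converges to the training source's.
#'
#' @param m a [train_markov()] model
#' @param length genome length (must exceed the order)
#' @param rng_seed optional integer seed
#' @return character string
#' @export
generate_virtual_genome <- function(m, length, rng_seed = NULL) {
  stopifnot(length > m$order)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  v <- markov_generate(m$cond, m$init, m$order, as.integer(length))
  int_to_seq(v)
}

#' False-positive evaluation on virtual genomes
#'
#' Runs the default two-pass scan with every model over every genome,
#' resolves overlapping hits, and tallies hit scores at or above
#' \code{score_floor} into 1-bit histogram bins.
#'
#' @param models list of [train_cm()] models (scan models)
#' @param genomes list/vector of genome sequences
#' @param score_floor minimum reported score in bits (default 10)
#' @param cfg a [scan_config()]
#' @return list of class \code{fp_result}: \code{histogram} (data.frame
#'   \code{bin_lo}, \code{bin_hi}, \code{count}), \code{n_hits},
#'   \code{max_score}, \code{total_nt}, \code{scores}
#' @export
fp_evaluate <- function(models, genomes, score_floor = 10,
                        cfg = scan_config()) {
  if (!is.list(models) || inherits(models, "trna_cm")) models <- list(models)
  genomes <- as_seq_char(genomes)
  cfg$report_cutoff <- max(score_floor, cfg$first_pass_cutoff)
  cfg$first_pass_cutoff <- min(cfg$first_pass_cutoff, score_floor)
  scores <- numeric(0)
  total_nt <- 0
  for (g in seq_along(genomes)) {
    gseq <- genomes[g]
    total_nt <- total_nt + nchar(gseq)
    hits <- list()
    for (m in models) {
      prof <- marginalize(m)
      cand <- first_pass_scan(prof, gseq, cfg)
      hh <- second_pass(m, gseq, cand, cfg)
      hits <- c(hits, hh)
    }
    hits <- resolve_overlaps(hits)
    scores <- c(scores, vapply(hits, `[[`, numeric(1), "score"))
  }
  scores <- scores[scores >= score_floor]
  if (length(scores)) {
    lo <- floor(min(scores)):floor(max(scores))
    cnt <- vapply(lo, function(b) sum(scores >= b & scores < b + 1),
                  integer(1))
    hist <- data.frame(bin_lo = lo, bin_hi = lo + 1, count = cnt)
    hist <- hist[hist$count > 0, , drop = FALSE]
  } else {
    hist <- data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                       count = integer(0))
  }
  structure(list(histogram = hist, n_hits = length(scores),
                 max_score = if (length(scores)) max(scores) else -Inf,
                 total_nt = total_nt, scores = scores),
            class = "fp_result")
}

#' @export
print.fp_result <- function(x, ...) {
  cat("False-positive scan:", x$n_hits, "hits over",
      format(x$total_nt, big.mark = ","), "nt")
  if (x$n_hits)
    cat("; max score", round(x$max_score, 1), "bits")
  cat("\n")
  if (nrow(x$histogram)) print(x$histogram, row.names = FALSE)
  invisible(x)
}
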