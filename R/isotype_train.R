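# Two-round isotype-specific model training.

#' Align sequences to a model's consensus columns
#'
#' Globally parses each sequence against \code{model} and assembles a seed
#' alignment over the model's consensus columns (inserted residues are not
#' given alignment columns).  The consensus structure and anticodon marker
#' of the model are carried over.
#'
#' @param model a [train_cm()] model
#' @param seqs character vector (or DNAStringSet) of sequences
#' @param meta metadata list for the resulting alignment
#' @return a [seed_alignment()]
#' @export
align_to_model <- function(model, seqs, meta = model$meta) {
  seqs <- as_seq_char(seqs)
  rows <- vapply(seqs, function(sq) {
    p <- score_sequence(model, sq, mode = "global")
    ch <- strsplit(sq, "")[[1]]
    out <- rep("-", model$clen)
    ok <- !is.na(p$colpos)
    out[ok] <- ch[p$colpos[ok]]
    paste(out, collapse = "")
  }, character(1))
  ac <- NULL
  if (!is.null(model$ac_cols)) {
    ac <- rep(".", model$clen); ac[model$ac_cols] <- "*"
    ac <- paste(ac, collapse = "")
  }
  seed_alignment(ids = names(seqs), rows = unname(rows), ss_cons = model$ss,
                 ac_line = ac, meta = meta)
}

#' Two-round training of isotype-specific models
#'
#' Round 1 groups the training sequences by their (anticodon-derived) isotype
#' label, aligns each group to the domain-level model and trains intermediate
#' models.  Round 2 rescores every sequence against all intermediate models,
#' regroups each sequence by its highest-scoring model regardless of the
#' anticodon-derived label (mutated anticodons on otherwise typical tRNA
#' bodies are thereby reassigned), re-aligns each new group to its
#' intermediate model and trains the final models.
#'
#' @param seqs character vector of training sequences
#' @param labels isotype label per sequence
#' @param domain_model domain-level [train_cm()] model used for alignment
#' @param pseudocount passed to [train_cm()]
#' @return named list of final models, one per surviving isotype group
#' @export
train_isotype_models <- function(seqs, labels, domain_model, pseudocount = 1) {
  seqs <- as_seq_char(seqs)
  stopifnot(length(seqs) == length(labels))
  groups <- split(seqs, labels)
  inter <- lapply(names(groups), function(iso) {
    aln <- align_to_model(domain_model, groups[[iso]],
                          meta = list(name = iso, isotype = iso,
                                      domain = domain_model$meta$domain))
    train_cm(aln, pseudocount = pseudocount)
  })
  names(inter) <- names(groups)

  sc <- vapply(seqs, function(sq) {
    vapply(inter, function(m)
      score_sequence(m, sq, mode = "global", want_parse = FALSE)$score,
      numeric(1))
  }, numeric(length(inter)))
  if (length(inter) == 1L) sc <- matrix(sc, nrow = 1,
                                        dimnames = list(names(inter), NULL))
  best <- names(inter)[apply(sc, 2, which.max)]

  final <- list()
  for (iso in names(inter)) {
    members <- seqs[best == iso]
    if (length(members) == 0L) {
      warning("isotype group '", iso, "' empty after round 2; model omitted")
      next
    }
    aln <- align_to_model(inter[[iso]], members,
                          meta = list(name = iso, isotype = iso,
                                      domain = domain_model$meta$domain))
    final[[iso]] <- train_cm(aln, pseudocount = pseudocount)
  }
  final
}
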