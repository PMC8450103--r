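# Sampling sequences from the generative model implied by a trained
# profile-SCFG (emission probabilities = background * 2^logodds; transition
# and insert probabilities as trained).

sample_node <- function(model, v, env) {
  ty <- model$ntype[v]
  emit <- function(col) {
    x <- sample.int(4L, 1L, prob = model$singleprob[col, ])
    env$chars <- c(env$chars, DNA[x]); env$cols <- c(env$cols, col)
  }
  slot <- function(pr) {
    if (pr[1] < 0) return(invisible())
    if (stats::runif(1) < pr[1]) {
      repeat {
        x <- sample.int(4L, 1L, prob = model$bg)
        env$chars <- c(env$chars, DNA[x]); env$cols <- c(env$cols, 0L)
        if (stats::runif(1) >= pr[2]) break
      }
    }
  }
  if (ty == NT_END) { slot(model$insl[v, ]); return(invisible()) }
  if (ty == NT_SL) {
    if (stats::runif(1) < 2^model$tr[v, 1]) emit(model$lcol[v])
    slot(model$insl[v, ])
    sample_node(model, model$child[v], env)
  } else if (ty == NT_SR) {
    sample_node(model, model$child[v], env)
    slot(model$insr[v, ])
    if (stats::runif(1) < 2^model$tr[v, 1]) emit(model$rcol[v])
  } else if (ty == NT_PAIR) {
    st <- sample.int(4L, 1L, prob = 2^model$tr[v, ])
    if (st == 1L) {
      xy <- sample.int(16L, 1L, prob = model$pairprob[v, ])
      x <- ((xy - 1L) %% 4L) + 1L; y <- ((xy - 1L) %/% 4L) + 1L
      env$chars <- c(env$chars, DNA[x]); env$cols <- c(env$cols, model$lcol[v])
    }
    if (st == 3L) emit(model$lcol[v])
    slot(model$insl[v, ])
    sample_node(model, model$child[v], env)
    slot(model$insr[v, ])
    if (st == 1L) {
      env$chars <- c(env$chars, DNA[y]); env$cols <- c(env$cols, model$rcol[v])
    }
    if (st == 4L) emit(model$rcol[v])
  } else if (ty == NT_BIF) {
    sample_node(model, model$bl[v], env)
    slot(model$insl[v, ])
    sample_node(model, model$br[v], env)
  } else { # ROOT
    slot(model$insl[v, ])
    sample_node(model, model$child[v], env)
    slot(model$insr[v, ])
  }
  invisible()
}

#' Sample a sequence from a trained model
#'
#' Draws a parse and residues from the probabilistic model implied by the
#' trained log-odds plus background.  Deterministic under a fixed seed.
#'
#' @param model a [train_cm()] model
#' @param rng_seed optional integer seed (uses the current RNG state if NULL)
#' @return character string with attribute \code{"colpos"}: for each
#'   consensus column the 1-based position it was emitted at (NA if the
#'   sampled parse deleted it)
#' @export
sample_sequence <- function(model, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  env <- new.env()
  env$chars <- character(0); env$cols <- integer(0)
  sample_node(model, model$root, env)
  out <- paste(env$chars, collapse = "")
  colpos <- rep(NA_integer_, model$clen)
  hit <- env$cols > 0L
  colpos[env$cols[hit]] <- which(hit)
  attr(out, "colpos") <- colpos
  out
}

#' Simulate sequences from a profile-SCFG
#'
#' @param object a [train_cm()] model
#' @param nsim number of sequences
#' @param seed optional integer seed
#' @param ... unused
#' @return character vector of sampled sequences
#' @export
simulate.trna_cm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(nsim), function(i) as.character(sample_sequence(object)),
         character(1))
}
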