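# Exhaustive parse enumeration: an independent oracle for the structural
# DP.  Enumerates every legal parse (state assignment per node, insert count
# per slot, bifurcation splits) of a subsequence and returns the score of
# each parse; the scorer under test must equal the maximum.  Only feasible
# for tiny models/sequences.

slot_cost_r <- function(po, pe, k) {
  if (po < 0) return(if (k == 0) 0 else -Inf)
  if (k == 0) return(log2(1 - po))
  log2(po) + (k - 1) * log2(pe) + log2(1 - pe)
}

em1_r <- function(model, col, x) if (x >= 4) 0 else model$esingle[col, x + 1]

em2_r <- function(model, v, x, y) {
  if (x >= 4 && y >= 4) return(0)
  if (x >= 4) return(model$esingle[model$rcol[v], y + 1])
  if (y >= 4) return(model$esingle[model$lcol[v], x + 1])
  model$epair[v, x + 4 * y + 1]
}

# all parse scores of s[(a+1)..b] (0-based half-open [a,b)) under subtree v
# (memo caches the full score vector per (node, range); this only shares
# repeated subproblems between parses, the enumeration itself is exhaustive)
enumerate_parses <- function(model, s, v, a, b, skip_root_slots = FALSE,
                             memo = new.env(parent = emptyenv())) {
  key <- paste0(v, ":", a, ":", b, ":", skip_root_slots)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  res <- enumerate_parses_impl(model, s, v, a, b, skip_root_slots, memo)
  memo[[key]] <- res
  res
}

enumerate_parses_impl <- function(model, s, v, a, b, skip_root_slots, memo) {
  ty <- model$ntype[v]
  len <- b - a
  tr <- model$tr[v, ]
  out <- numeric(0)
  if (ty == 5L) {  # END: everything is insert
    return(slot_cost_r(model$insl[v, 1], model$insl[v, 2], len))
  }
  if (ty == 1L) {  # SINGLE_L
    for (k in 0:max(0, len - 1)) {  # match + k inserts
      if (len < 1 + k) break
      sub <- enumerate_parses(model, s, model$child[v], a + 1 + k, b, memo = memo)
      out <- c(out, tr[1] + em1_r(model, model$lcol[v], s[a + 1]) +
                 slot_cost_r(model$insl[v, 1], model$insl[v, 2], k) + sub)
    }
    for (k in 0:len) {  # delete + k inserts
      sub <- enumerate_parses(model, s, model$child[v], a + k, b, memo = memo)
      out <- c(out, tr[2] +
                 slot_cost_r(model$insl[v, 1], model$insl[v, 2], k) + sub)
    }
    return(out)
  }
  if (ty == 2L) {  # SINGLE_R: child, inserts, emitted residue at b-1
    for (k in 0:max(0, len - 1)) {
      if (len < 1 + k) break
      sub <- enumerate_parses(model, s, model$child[v], a, b - 1 - k, memo = memo)
      out <- c(out, tr[1] + em1_r(model, model$rcol[v], s[b]) +
                 slot_cost_r(model$insr[v, 1], model$insr[v, 2], k) + sub)
    }
    for (k in 0:len) {
      sub <- enumerate_parses(model, s, model$child[v], a, b - k, memo = memo)
      out <- c(out, tr[2] +
                 slot_cost_r(model$insr[v, 1], model$insr[v, 2], k) + sub)
    }
    return(out)
  }
  if (ty == 3L) {  # PAIR
    inner <- function(aa, bb) {
      res <- numeric(0)
      for (k1 in 0:(bb - aa)) {
        for (k2 in 0:(bb - aa - k1)) {
          sub <- enumerate_parses(model, s, model$child[v], aa + k1, bb - k2, memo = memo)
          res <- c(res,
                   slot_cost_r(model$insl[v, 1], model$insl[v, 2], k1) +
                     slot_cost_r(model$insr[v, 1], model$insr[v, 2], k2) +
                     sub)
        }
      }
      res
    }
    if (len >= 2)
      out <- c(out, tr[1] + em2_r(model, v, s[a + 1], s[b]) +
                 inner(a + 1, b - 1))
    if (len >= 1) {
      out <- c(out, tr[3] + em1_r(model, model$lcol[v], s[a + 1]) +
                 inner(a + 1, b))
      out <- c(out, tr[4] + em1_r(model, model$rcol[v], s[b]) +
                 inner(a, b - 1))
    }
    out <- c(out, tr[2] + inner(a, b))
    return(out)
  }
  if (ty == 4L) {  # BIF with mid slot before the right child
    for (m in a:b) {
      left <- enumerate_parses(model, s, model$bl[v], a, m, memo = memo)
      if (!length(left)) next
      for (k in 0:(b - m)) {
        right <- enumerate_parses(model, s, model$br[v], m + k, b, memo = memo)
        if (!length(right)) next
        cost <- slot_cost_r(model$insl[v, 1], model$insl[v, 2], k)
        out <- c(out, as.vector(outer(left + cost, right, `+`)))
      }
    }
    return(out)
  }
  # ROOT
  if (skip_root_slots)
    return(enumerate_parses(model, s, model$child[v], a, b, memo = memo))
  for (k1 in 0:len) {
    for (k2 in 0:(len - k1)) {
      sub <- enumerate_parses(model, s, model$child[v], a + k1, b - k2, memo = memo)
      out <- c(out, slot_cost_r(model$insl[v, 1], model$insl[v, 2], k1) +
                 slot_cost_r(model$insr[v, 1], model$insr[v, 2], k2) + sub)
    }
  }
  out
}

# oracle global score: max over all parses (-Inf if none)
oracle_global <- function(model, seq) {
  s <- if (is.integer(seq)) seq else cloverleaf:::seq_to_int(seq)
  sc <- enumerate_parses(model, s, model$root, 0L, length(s))
  if (length(sc)) max(sc) else -Inf
}

# oracle local score: best over all subsequences, root slots skipped
oracle_local <- function(model, seq) {
  s <- if (is.integer(seq)) seq else cloverleaf:::seq_to_int(seq)
  L <- length(s)
  best <- -Inf
  for (a in 0:L) for (b in a:L) {
    sc <- enumerate_parses(model, s, model$root, a, b,
                           skip_root_slots = TRUE)
    if (length(sc)) best <- max(best, max(sc))
  }
  best
}

# a random tiny model for oracle testing: <= 6 consensus columns
random_tiny_model <- function() {
  ss <- sample(c("......", "<<..>>", ".<..>.", "<.><.>", "..<>..", "....",
                 "<<<>>>", ".....","<..>.."), 1)
  n <- nchar(ss)
  rows <- vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
  # occasionally introduce a gap so delete transitions get trained
  if (runif(1) < 0.5) {
    pos <- sample(n, 1)
    substr(rows[1], pos, pos) <- "-"
  }
  train_cm(seed_alignment(paste0("r", 1:3), rows, ss,
                          meta = list(name = "tiny")))
}

random_tiny_seq <- function(maxlen = 8) {
  len <- sample(0:maxlen, 1)
  paste(sample(c("A", "C", "G", "T", "A", "C", "G", "T", "N"), len,
               replace = TRUE), collapse = "")
}
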