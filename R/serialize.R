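# Plain-text model serialization.  Bit scores are written to 3 decimals and
# insert/transition probabilities to 6; a write/read/write cycle is
# byte-identical.

FMT_BITS <- function(x) formatC(x, digits = 3, format = "f")
FMT_PROB <- function(x) formatC(x, digits = 6, format = "f")

#' Write a profile-SCFG model to a plain-text file
#' @param model a [train_cm()] model
#' @param path file path
#' @return \code{path}, invisibly
#' @export
write_cm <- function(model, path) {
  m <- model
  out <- c("CLOVERLEAF-CM 1",
           paste("NAME", m$meta$name %||% "model"),
           paste("DOMAIN", m$meta$domain %||% "-"),
           paste("ISOTYPE", m$meta$isotype %||% "-"),
           paste("ANTICODON", m$meta$anticodon %||% "-"),
           paste("FOLD", m$meta$fold %||% "standard"),
           paste("CLEN", m$clen), paste("NSEQ", m$nseq),
           paste("SS", m$ss),
           paste("ACCOLS", if (is.null(m$ac_cols)) "-" else
             paste(m$ac_cols, collapse = ",")),
           paste("BG", paste(FMT_PROB(m$bg), collapse = " ")),
           paste("NODES", m$n, "ROOT", m$root))
  for (v in seq_len(m$n)) {
    out <- c(out, paste("NODE", v, m$ntype[v], m$lcol[v], m$rcol[v],
                        m$child[v], m$bl[v], m$br[v],
                        paste(FMT_BITS(m$tr[v, ]), collapse = " "),
                        paste(FMT_PROB(m$insl[v, ]), collapse = " "),
                        paste(FMT_PROB(m$insr[v, ]), collapse = " ")))
  }
  for (c in seq_len(m$clen))
    out <- c(out, paste("ESINGLE", c,
                        paste(FMT_BITS(m$esingle[c, ]), collapse = " ")))
  for (v in which(m$ntype == NT_PAIR))
    out <- c(out, paste("EPAIR", v,
                        paste(FMT_BITS(m$epair[v, ]), collapse = " ")))
  writeLines(out, path)
  invisible(path)
}

#' Read a profile-SCFG model written by [write_cm()]
#' @param path file path
#' @return a \code{trna_cm} model
#' @export
read_cm <- function(path) {
  lines <- readLines(path)
  if (!grepl("^CLOVERLEAF-CM", lines[1]))
    stop("format error: not a model file: ", path)
  kv <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, " "))][1]
    sub(paste0("^", key, " "), "", ln)
  }
  clen <- as.integer(kv("CLEN"))
  hdr <- strsplit(kv("NODES"), " ")[[1]]
  n <- as.integer(hdr[1]); root <- as.integer(hdr[3])
  m <- list(meta = list(), bg = as.numeric(strsplit(kv("BG"), " ")[[1]]),
            n = n, clen = clen, root = root,
            ntype = integer(n), lcol = integer(n), rcol = integer(n),
            child = integer(n), bl = integer(n), br = integer(n),
            tr = matrix(0, n, 4), insl = matrix(-1, n, 2),
            insr = matrix(-1, n, 2), esingle = matrix(0, clen, 4),
            epair = matrix(0, n, 16), ss = kv("SS"),
            nseq = as.integer(kv("NSEQ")), pseudocount = NA_real_)
  for (k in c("name", "domain", "isotype", "anticodon", "fold")) {
    val <- kv(toupper(k))
    if (!is.na(val) && val != "-") m$meta[[k]] <- val
  }
  acc <- kv("ACCOLS")
  m$ac_cols <- if (acc == "-") NULL else
    as.integer(strsplit(acc, ",")[[1]])
  for (ln in lines[startsWith(lines, "NODE ")]) {
    f <- strsplit(ln, " ")[[1]]
    v <- as.integer(f[2])
    m$ntype[v] <- as.integer(f[3]); m$lcol[v] <- as.integer(f[4])
    m$rcol[v] <- as.integer(f[5]); m$child[v] <- as.integer(f[6])
    m$bl[v] <- as.integer(f[7]); m$br[v] <- as.integer(f[8])
    m$tr[v, ] <- as.numeric(f[9:12])
    m$insl[v, ] <- as.numeric(f[13:14])
    m$insr[v, ] <- as.numeric(f[15:16])
  }
  for (ln in lines[startsWith(lines, "ESINGLE ")]) {
    f <- strsplit(ln, " ")[[1]]
    m$esingle[as.integer(f[2]), ] <- as.numeric(f[3:6])
  }
  for (ln in lines[startsWith(lines, "EPAIR ")]) {
    f <- strsplit(ln, " ")[[1]]
    m$epair[as.integer(f[2]), ] <- as.numeric(f[3:18])
  }
  # reconstruct sampling tables from the log-odds
  m$singleprob <- 2^m$esingle * rep(m$bg, each = clen)
  m$pairprob <- 2^m$epair * rep(as.vector(outer(m$bg, m$bg)), each = n)
  m$pairprob[m$ntype != NT_PAIR, ] <- NA_real_
  structure(m, class = "trna_cm")
}
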