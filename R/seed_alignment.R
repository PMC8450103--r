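# Structure-annotated seed alignments and Stockholm I/O.

#' Construct a seed alignment
#'
#' A seed alignment holds aligned sequences, a consensus secondary-structure
#' annotation and, optionally, a marker line flagging the three anticodon
#' columns.  It is the training substrate for profile-SCFG models.
#'
#' @param ids sequence identifiers
#' @param rows aligned sequences (equal length, gaps as '-' or '.')
#' @param ss_cons consensus structure string, same width as the rows
#' @param ac_line optional marker line of '.' and '*' with exactly three
#'   consecutive starred columns (the anticodon), or NULL
#' @param meta list with optional entries \code{name}, \code{domain}
#'   (eukaryote|bacteria|archaea|mito), \code{isotype}, \code{anticodon},
#'   \code{fold} (standard|sec_9_4|sec_8_5|d_armless)
#' @return object of class \code{seed_alignment}
#' @export
seed_alignment <- function(ids, rows, ss_cons, ac_line = NULL, meta = list()) {
  rows <- toupper(chartr("Uu", "Tt", rows))
  w <- unique(nchar(rows))
  if (length(ids) != length(rows)) stop("format error: ids/rows mismatch")
  if (length(rows) == 0L) stop("format error: empty alignment")
  if (length(w) != 1L) stop("format error: ragged alignment rows")
  if (nchar(ss_cons) != w)
    stop("format error: SS_cons width differs from rows")
  parse_structure(ss_cons)  # validates balance/nesting
  if (!is.null(ac_line)) {
    if (nchar(ac_line) != w)
      stop("format error: anticodon marker width differs from rows")
    st <- which(strsplit(ac_line, "")[[1]] == "*")
    if (!(length(st) %in% c(0L, 3L)))
      stop("format error: anticodon marker must flag 0 or 3 columns")
    if (length(st) == 3L) {
      if (!all(diff(st) == 1L))
        stop("format error: anticodon columns must be consecutive")
      pt <- parse_structure(ss_cons)
      if (any(pt[st] != 0L))
        stop("format error: anticodon columns must be unpaired")
    }
    if (length(st) == 0L) ac_line <- NULL
  }
  structure(list(ids = ids, rows = rows, ss_cons = ss_cons,
                 ac_line = ac_line, meta = meta),
            class = "seed_alignment")
}

#' @export
print.seed_alignment <- function(x, ...) {
  cat("Seed alignment:", x$meta$name %||% "<unnamed>", "\n")
  cat(" ", length(x$rows), "rows x", nchar(x$rows[1]), "columns;",
      if (is.null(x$ac_line)) "no anticodon marker" else "anticodon marked",
      "\n")
  if (!is.null(x$meta$isotype))
    cat("  isotype:", x$meta$isotype,
        if (!is.null(x$meta$anticodon)) paste0("(", x$meta$anticodon, ")"),
        "\n")
  invisible(x)
}

#' @export
`==.seed_alignment` <- function(e1, e2) {
  identical(e1$ids, e2$ids) && identical(e1$rows, e2$rows) &&
    identical(e1$ss_cons, e2$ss_cons) && identical(e1$ac_line, e2$ac_line)
}

#' Read a Stockholm seed alignment
#'
#' Reads one Stockholm-format alignment with a \code{#=GC SS_cons} consensus
#' structure line and an optional \code{#=GC AC} anticodon marker line
#' ('.'/'*').  Alignment metadata is carried on \code{#=GF NAME},
#' \code{#=GF DOMAIN}, \code{#=GF ISOTYPE}, \code{#=GF ANTICODON} and
#' \code{#=GF FOLD} lines.  Multi-block ("interleaved") files are supported.
#'
#' @param path file path
#' @return a [seed_alignment()]
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^# STOCKHOLM", lines[1]))
    stop("format error: missing '# STOCKHOLM' header in ", path)
  rows <- list(); ss <- ""; ac <- ""; meta <- list()
  ord <- character(0)
  for (ln in lines[-1]) {
    if (grepl("^//", ln) || !nzchar(trimws(ln))) next
    if (grepl("^#=GF\\s", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) >= 3)
        meta[[tolower(f[2])]] <- paste(f[-(1:2)], collapse = " ")
    } else if (grepl("^#=GC\\s", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) != 3) stop("format error: bad #=GC line: ", ln)
      if (f[2] == "SS_cons") ss <- paste0(ss, f[3])
      if (f[2] == "AC") ac <- paste0(ac, f[3])
    } else if (grepl("^#", ln)) {
      next
    } else {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) != 2) stop("format error: bad alignment line: ", ln)
      if (!(f[1] %in% ord)) ord <- c(ord, f[1])
      rows[[f[1]]] <- paste0(rows[[f[1]]] %||% "", f[2])
    }
  }
  if (length(rows) == 0L) stop("format error: no alignment rows in ", path)
  if (!nzchar(ss)) stop("format error: no #=GC SS_cons line in ", path)
  m <- list(name = meta$name, domain = meta$domain, isotype = meta$isotype,
            anticodon = meta$anticodon, fold = meta$fold)
  seed_alignment(ids = ord, rows = unlist(rows[ord], use.names = FALSE),
                 ss_cons = ss, ac_line = if (nzchar(ac)) ac else NULL,
                 meta = m[!vapply(m, is.null, logical(1))])
}

#' Write a Stockholm seed alignment
#'
#' Inverse of [read_stockholm()]; \code{read_stockholm(write_stockholm(a))}
#' reproduces \code{a} exactly.
#'
#' @param aln a [seed_alignment()]
#' @param path file path
#' @return \code{path}, invisibly
#' @export
write_stockholm <- function(aln, path) {
  wid <- max(nchar(aln$ids), nchar("#=GC SS_cons")) + 2L
  pad <- function(s) formatC(s, width = -wid)
  out <- c("# STOCKHOLM 1.0")
  for (k in c("name", "domain", "isotype", "anticodon", "fold")) {
    if (!is.null(aln$meta[[k]]))
      out <- c(out, paste("#=GF", toupper(k), aln$meta[[k]]))
  }
  out <- c(out, paste0(pad(aln$ids), aln$rows),
           paste0(pad("#=GC SS_cons"), aln$ss_cons))
  if (!is.null(aln$ac_line))
    out <- c(out, paste0(pad("#=GC AC"), aln$ac_line))
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Replace the anticodon columns of every row by NNN
#'
#' Used when building domain-level detection models so that anticodon identity
#' does not bias detection toward common isotypes.  Gapped positions in the
#' marked columns are left as gaps; all other columns are unchanged.  The
#' operation is idempotent.
#'
#' @param aln a [seed_alignment()] with a marked anticodon
#' @return the masked [seed_alignment()]
#' @export
mask_anticodons <- function(aln) {
  if (is.null(aln$ac_line)) {
    warning("no anticodon columns marked; returning alignment unchanged")
    return(aln)
  }
  cols <- which(strsplit(aln$ac_line, "")[[1]] == "*")
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  sub <- m[, cols, drop = FALSE]
  sub[!(sub %in% GAP_CHARS)] <- "N"
  m[, cols] <- sub
  aln$rows <- apply(m, 1, paste, collapse = "")
  aln
}
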