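# Typed configuration records with every pipeline threshold, plus the
# INI-style configuration-file reader.

#' Scanner configuration
#'
#' @param first_pass_cutoff bit cutoff of the structure-free first pass
#'   (default 10)
#' @param report_cutoff reporting threshold of the structural second pass
#'   (default 20)
#' @param candidate_flank flanking nucleotides added to first-pass candidate
#'   windows (default 60)
#' @param max_mode_window window length of the exhaustive single-pass mode
#'   (default 200)
#' @param max_mode_overlap overlap of consecutive windows (default 150)
#' @return list of class \code{scan_config}
#' @export
scan_config <- function(first_pass_cutoff = 10, report_cutoff = 20,
                        candidate_flank = 60, max_mode_window = 200,
                        max_mode_overlap = 150) {
  stopifnot(first_pass_cutoff <= report_cutoff, candidate_flank >= 0,
            max_mode_overlap < max_mode_window)
  structure(list(first_pass_cutoff = first_pass_cutoff,
                 report_cutoff = report_cutoff,
                 candidate_flank = candidate_flank,
                 max_mode_window = max_mode_window,
                 max_mode_overlap = max_mode_overlap),
            class = "scan_config")
}

#' Post-scan filter configuration
#'
#' Defaults are the production thresholds: pseudogene rule 55/10/5 bits,
#' second-stage rule 70/50/10 bits, third-stage dynamic threshold starting
#' at 71 bits and saturating at 95 bits with at most 40 retained predictions
#' per anticodon.
#'
#' @param pseudo_overall,pseudo_primary,pseudo_secondary pseudogene rule
#' @param stage2_isotype,stage2_overall,stage2_secondary second-stage rule
#' @param stage3_start,stage3_cap,stage3_max_per_anticodon third-stage rule
#' @return list of class \code{filter_config}
#' @export
filter_config <- function(pseudo_overall = 55, pseudo_primary = 10,
                          pseudo_secondary = 5, stage2_isotype = 70,
                          stage2_overall = 50, stage2_secondary = 10,
                          stage3_start = 71, stage3_cap = 95,
                          stage3_max_per_anticodon = 40) {
  stopifnot(stage3_start <= stage3_cap)
  structure(list(pseudo_overall = pseudo_overall,
                 pseudo_primary = pseudo_primary,
                 pseudo_secondary = pseudo_secondary,
                 stage2_isotype = stage2_isotype,
                 stage2_overall = stage2_overall,
                 stage2_secondary = stage2_secondary,
                 stage3_start = stage3_start, stage3_cap = stage3_cap,
                 stage3_max_per_anticodon = stage3_max_per_anticodon),
            class = "filter_config")
}

#' Noncanonical-intron search configuration
#'
#' @param flank nucleotides of flanking sequence added around candidates
#'   (default 60)
#' @param min_mature_len minimum length of a reported mature tRNA (default
#'   70)
#' @param bhb_accept_bits minimum bulge-helix-bulge model score for a
#'   candidate intron (default 10)
#' @param min_intron_len minimum intron length (default 8)
#' @param max_iterations maximum splice-and-rescore iterations (default 3)
#' @return list of class \code{intron_config}
#' @export
intron_config <- function(flank = 60, min_mature_len = 70,
                          bhb_accept_bits = 10, min_intron_len = 8,
                          max_iterations = 3) {
  stopifnot(flank > 0, min_mature_len > 0, min_intron_len > 0,
            max_iterations > 0)
  structure(list(flank = flank, min_mature_len = min_mature_len,
                 bhb_accept_bits = bhb_accept_bits,
                 min_intron_len = min_intron_len,
                 max_iterations = max_iterations),
            class = "intron_config")
}

#' Annotation-comparison configuration
#' @param nuclear_tolerance boundary tolerance for nuclear comparisons
#'   (default 10 nt)
#' @param mito_tolerance boundary tolerance for mitochondrial comparisons
#'   (default 15 nt)
#' @return list of class \code{compare_config}
#' @export
compare_config <- function(nuclear_tolerance = 10, mito_tolerance = 15) {
  stopifnot(nuclear_tolerance >= 0, mito_tolerance >= 0)
  structure(list(nuclear_tolerance = nuclear_tolerance,
                 mito_tolerance = mito_tolerance),
            class = "compare_config")
}

#' Default full configuration
#' @return list with elements \code{scan}, \code{filter}, \code{intron},
#'   \code{compare} and \code{models} (alternate model paths)
#' @export
default_config <- function() {
  list(scan = scan_config(), filter = filter_config(),
       intron = intron_config(), compare = compare_config(),
       models = character(0))
}

CONFIG_KEYS <- list(
  scan = names(formals(scan_config)),
  filter = names(formals(filter_config)),
  intron = names(formals(intron_config)),
  compare = names(formals(compare_config))
)

#' Read an INI-style configuration file
#'
#' Recognized keys are the argument names of [scan_config()],
#' [filter_config()], [intron_config()] and [compare_config()]
#' (\code{score_cutoff} is accepted as an alias for \code{report_cutoff});
#' repeated \code{model} entries form an ordered list of alternate model
#' paths.  Every omitted threshold keeps its default.  Unknown keys warn,
#' non-numeric values for numeric keys are an error.
#'
#' @param path file path
#' @return a configuration list as from [default_config()]
#' @export
read_config <- function(path) {
  cfg <- default_config()
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|;|\\[)", lines) & nzchar(trimws(lines))]
  vals <- list(); models <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(f) != 2) stop("config error: bad line: ", ln)
    key <- trimws(f[1]); val <- trimws(f[2])
    if (key == "score_cutoff") key <- "report_cutoff"
    if (key == "model") { models <- c(models, val); next }
    grp <- names(CONFIG_KEYS)[vapply(CONFIG_KEYS, function(k) key %in% k,
                                     logical(1))]
    if (length(grp) == 0L) {
      warning("config: unknown key '", key, "' ignored")
      next
    }
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num)) stop("config error: non-numeric value for '", key, "'")
    vals[[grp[1]]][[key]] <- num
  }
  for (grp in names(vals)) {
    cur <- unclass(cfg[[grp]])
    cur[names(vals[[grp]])] <- vals[[grp]]
    cfg[[grp]] <- do.call(paste0(if (grp == "scan") "scan" else grp,
                                 "_config"), cur)
  }
  cfg$models <- models
  cfg
}
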