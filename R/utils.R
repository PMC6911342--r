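# Internal helpers shared across modules. All coordinates in this package are
# 0-based, half-open [start, end) on the forward strand unless a function
# documents otherwise; BED output uses the same convention, SAM output
# converts to 1-based POS on write.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

abort_config <- function(msg) abort(msg, class = "phloemir_config_error")
abort_input <- function(msg) abort(msg, class = "phloemir_input_error")
abort_stats <- function(msg) abort(msg, class = "phloemir_stats_error")

check_dna <- function(x, what = "sequence") {
  if (length(x) == 0 || any(is.na(x)) || any(nchar(x) == 0)) {
    abort_input(paste0(what, " must be one or more non-empty strings"))
  }
  if (any(grepl("[^ACGT]", x))) {
    abort_input(paste0(what, " must contain only uppercase A/C/G/T"))
  }
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' Vectorised over its input; uppercase ACGT only.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTG") # "CACGT"
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

random_dna <- function(n_chars) {
  paste(sample(DNA_BASES, n_chars, replace = TRUE), collapse = "")
}

# Run `expr` under a fixed RNG state when seed is non-NULL, leaving the
# caller's RNG untouched.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Half-open interval overlap
intervals_overlap <- function(s1, e1, s2, e2) {
  s1 < e2 & s2 < e1
}
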