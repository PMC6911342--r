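# In-silico PCR: primer-site scanning with a 3'-exact rule and amplicon
# prediction. Used to validate species-discriminating primer pairs (a pair
# that anneals to one species' sequence but carries 3'-terminal mismatches
# against the other yields a product only from the first).

#' Construct and validate a primer pair
#'
#' @param forward,reverse Primer sequences, 15-30 nt, ACGT.
#' @param max_mismatch Total mismatches tolerated per annealing site
#'   (default 2).
#' @param three_prime_exact Number of 3'-terminal bases that must match
#'   exactly (default 3).
#' @param size_range Admissible amplicon lengths in bp.
#' @return A `primer_pair` list.
#' @export
primer_pair <- function(forward, reverse, max_mismatch = 2,
                        three_prime_exact = 3, size_range = c(40, 10000)) {
  check_dna(c(forward, reverse), "primer")
  lens <- nchar(c(forward, reverse))
  if (any(lens < 15) || any(lens > 30)) {
    abort_config("primer lengths must be within 15-30 nt")
  }
  if (three_prime_exact > min(lens)) {
    abort_config("three_prime_exact must not exceed the primer length")
  }
  structure(list(forward = forward, reverse = reverse,
                 max_mismatch = max_mismatch,
                 three_prime_exact = three_prime_exact,
                 size_range = size_range),
            class = "primer_pair")
}

#' Find primer annealing sites on a template
#'
#' Scans both strands with a sliding window. A site qualifies when the
#' total mismatch count is at most `max_mismatch` and the primer's
#' 3'-terminal `three_prime_exact` bases match exactly. For plus-strand
#' sites the primer reads along the template; for minus-strand sites the
#' reverse complement of the primer matches the forward template, and the
#' primer's 3' end sits at the left edge of the matched window.
#'
#' @param primer Primer sequence.
#' @param template Template sequence (longer than the primer).
#' @param max_mismatch Total mismatches tolerated (default 2).
#' @param three_prime_exact 3'-terminal bases requiring exact match
#'   (default 3).
#' @return Tibble: `position` (0-based start of the matched template
#'   window), `strand`, `mismatches`.
#' @export
find_primer_sites <- function(primer, template, max_mismatch = 2,
                              three_prime_exact = 3) {
  check_dna(primer, "primer")
  check_dna(template, "template")
  plen <- nchar(primer)
  tlen <- nchar(template)
  if (plen >= tlen) abort_input("primer must be shorter than the template")
  tch <- strsplit(template, "", fixed = TRUE)[[1]]
  scan <- function(pseq, strand) {
    pch <- strsplit(pseq, "", fixed = TRUE)[[1]]
    # indices of the primer's 3'-terminal bases within the matched window
    tail_idx <- if (strand == "+") (plen - three_prime_exact + 1):plen
                else 1:three_prime_exact
    offs <- 0:(tlen - plen)
    res <- lapply(offs, function(o) {
      win <- tch[(o + 1):(o + plen)]
      mm <- sum(win != pch)
      if (mm > max_mismatch) return(NULL)
      if (any(win[tail_idx] != pch[tail_idx])) return(NULL)
      tibble(position = o, strand = strand, mismatches = mm)
    })
    res[!vapply(res, is.null, logical(1))]
  }
  rows <- c(scan(primer, "+"), scan(revcomp(primer), "-"))
  if (length(rows) == 0) {
    return(tibble(position = integer(), strand = character(),
                  mismatches = integer()))
  }
  bind_rows(rows)
}

#' Predict PCR amplicons from a primer pair on a template
#'
#' An amplicon spans from the 5' end of a plus-strand site of one primer to
#' the 5' end of a minus-strand site of the other (both primer footprints
#' included); both role assignments (forward on plus / reverse on minus and
#' vice versa) are considered. Products outside `size_range` are dropped.
#' No product yields an empty tibble, not an error.
#'
#' @param pair A [primer_pair()].
#' @param template Template sequence.
#' @return Tibble: `start`, `end` (0-based half-open on the template),
#'   `length` (bp), `orientation` (`FR` or `RF`).
#' @export
in_silico_pcr <- function(pair, template) {
  stopifnot(inherits(pair, "primer_pair"))
  sites <- function(p) find_primer_sites(p, template, pair$max_mismatch,
                                         pair$three_prime_exact)
  f <- sites(pair$forward)
  r <- sites(pair$reverse)
  flen <- nchar(pair$forward)
  rlen <- nchar(pair$reverse)
  combine <- function(plus, minus, plus_len, minus_len, orientation) {
    plus <- plus[plus$strand == "+", , drop = FALSE]
    minus <- minus[minus$strand == "-", , drop = FALSE]
    if (nrow(plus) == 0 || nrow(minus) == 0) return(NULL)
    grid <- expand.grid(i = seq_len(nrow(plus)), j = seq_len(nrow(minus)))
    a <- plus$position[grid$i]
    b <- minus$position[grid$j]
    len <- b + minus_len - a
    ok <- b >= a + plus_len & len >= pair$size_range[1] &
      len <= pair$size_range[2]
    if (!any(ok)) return(NULL)
    tibble(start = a[ok], end = (b + minus_len)[ok], length = len[ok],
           orientation = orientation)
  }
  out <- bind_rows(combine(f, r, flen, rlen, "FR"),
                   combine(r, f, rlen, flen, "RF"))
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(start = integer(), end = integer(), length = integer(),
                  orientation = character()))
  }
  arrange(out, .data$start, .data$length)
}

#' Read a primer table
#'
#' Three-column tab-separated file: `name`, `forward`, `reverse`.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_primers <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}
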