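# Diagnosis of AC/LC-discordant (chimeric) contigs: six-frame ORF finding
# plus a concordance check between the dominant coverage peak and the
# precursor interval. A contig whose coverage peak misses the precursor
# while AC dwarfs LC is an assembly artifact fusing a highly expressed
# (often protein-coding) transcript with a low-abundance precursor.

#' Find open reading frames in all six frames
#'
#' ORFs run from an ATG to the next in-frame stop codon (stop included) or
#' to the last complete codon of the sequence; within each stop-delimited
#' segment the first ATG is reported. Reverse-strand ORFs are reported in
#' forward coordinates with strand "-".
#'
#' @param seq ACGT string.
#' @param min_orf_len Minimum ORF length in nt (default 150; always a
#'   multiple of 3 is reported).
#' @param contig_id Optional contig label carried on the output.
#' @return Tibble: `contig_id`, `start`, `end` (0-based half-open, forward
#'   coordinates), `strand`, `frame` (0-2 within its strand), `length`.
#' @export
find_orfs <- function(seq, min_orf_len = 150, contig_id = NA_character_) {
  check_dna(seq, "contig sequence")
  L <- nchar(seq)
  scan_strand <- function(s) {
    out <- list()
    for (frame in 0:2) {
      n_codons <- (nchar(s) - frame) %/% 3
      if (n_codons < 1) next
      starts <- frame + (seq_len(n_codons) - 1L) * 3L
      codons <- substring(s, starts + 1L, starts + 3L)
      is_stop <- codons %in% STOP_CODONS
      is_atg <- codons == "ATG"
      seg_start <- 1L
      i <- 1L
      boundaries <- c(which(is_stop), n_codons + 1L)
      for (b in boundaries) {
        if (b > n_codons && seg_start > n_codons) break
        seg_end <- min(b, n_codons) # codon index of stop (or last codon)
        atg <- which(is_atg[seg_start:seg_end])
        if (length(atg)) {
          a <- seg_start + atg[1] - 1L
          orf_start <- starts[a]
          orf_end <- starts[seg_end] + 3L
          if (orf_end - orf_start >= min_orf_len) {
            out[[length(out) + 1L]] <- c(orf_start, orf_end, frame)
          }
        }
        seg_start <- b + 1L
        if (seg_start > n_codons) break
      }
    }
    out
  }
  fwd <- scan_strand(seq)
  rev <- scan_strand(revcomp(seq))
  rows <- c(
    lapply(fwd, function(x) tibble(contig_id = contig_id, start = x[1],
                                   end = x[2], strand = "+", frame = x[3],
                                   length = x[2] - x[1])),
    lapply(rev, function(x) tibble(contig_id = contig_id, start = L - x[2],
                                   end = L - x[1], strand = "-", frame = x[3],
                                   length = x[2] - x[1])))
  if (length(rows) == 0) {
    return(tibble(contig_id = character(), start = integer(), end = integer(),
                  strand = character(), frame = integer(), length = integer()))
  }
  arrange(bind_rows(rows), .data$start, .data$strand)
}

#' Locate the dominant coverage peak of a profile
#'
#' The peak is the longest maximal run of positions with depth at or above
#' `peak_frac` of the profile maximum (ties resolve to the leftmost run).
#'
#' @param profile A `coverage_profile` with at least one read.
#' @param peak_frac Fraction of the maximum depth defining the peak
#'   (default 0.5).
#' @return A list with `start`, `end` (0-based half-open).
#' @export
coverage_peak <- function(profile, peak_frac = 0.5) {
  if (profile$contig_len == 0) abort_input("empty profile")
  mx <- max(profile$depth)
  if (mx == 0) abort_input("profile has no coverage; no peak is defined")
  above <- profile$depth >= peak_frac * mx
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  list(start = starts[best] - 1L, end = ends[best])
}

#' Diagnose whether average coverage misrepresents precursor abundance
#'
#' Verdict `ac_misleading` when the dominant coverage peak does not overlap
#' the precursor interval and `AC / (LC + 1) >= discordance_ratio`;
#' otherwise `concordant`. Also flags whether the peak overlaps any ORF —
#' the typical explanation being a chimeric contig fusing a highly
#' expressed protein-coding transcript with the precursor.
#'
#' @param profile A `coverage_profile`.
#' @param precursor_interval Length-2 vector, 0-based half-open.
#' @param orfs ORF tibble from [find_orfs()] (may be empty).
#' @param discordance_ratio Minimum `AC / (LC + 1)` to call discordance
#'   (default 5).
#' @param mature_interval Interval used for LC; defaults to
#'   `precursor_interval`.
#' @param peak_frac Passed to [coverage_peak()].
#' @return A one-row tibble (`discordance_report`): contig, AC, LC, peak
#'   interval, overlap flags, ratio, `verdict`.
#' @export
diagnose_discordance <- function(profile, precursor_interval, orfs = NULL,
                                 discordance_ratio = 5,
                                 mature_interval = precursor_interval,
                                 peak_frac = 0.5) {
  if (profile$contig_len == 0 || profile$n_reads == 0) {
    abort_input("empty profile: discordance is undefined without coverage")
  }
  peak <- coverage_peak(profile, peak_frac)
  ac <- average_coverage(profile)
  lc <- local_coverage(profile, mature_interval)$lc
  over_prec <- intervals_overlap(peak$start, peak$end,
                                 precursor_interval[1], precursor_interval[2])
  over_orf <- if (is.null(orfs) || nrow(orfs) == 0) FALSE else {
    any(intervals_overlap(peak$start, peak$end, orfs$start, orfs$end))
  }
  ratio <- ac / (lc + 1)
  verdict <- if (!over_prec && ratio >= discordance_ratio) "ac_misleading" else "concordant"
  tibble(contig_id = profile$contig_id, ac = ac, lc = lc,
         peak_start = peak$start, peak_end = peak$end,
         peak_overlaps_precursor = over_prec, peak_overlaps_orf = over_orf,
         ratio = ratio, verdict = verdict)
}
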