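# Read mapping and the two abundance statistics. Average coverage (AC) is
# the mean read depth over a whole contig; local coverage (LC) is the depth
# at the central nucleotide of the mature miRNA within a precursor-bearing
# contig. LC, not AC, is the selection statistic: chimeric contigs make AC
# misleading because most of their reads come from a fused, unrelated
# transcript.

#' Map reads to contigs by k-mer seeding and ungapped extension
#'
#' Candidate placements come from exact matches of the read's first and last
#' k-mer on either strand; each candidate is verified by full-length ungapped
#' mismatch counting and the placement minimising mismatches wins. Reads
#' exceeding `max_mismatch` are unmapped; reads whose best placements tie on
#' different contigs are discarded as ambiguous (deterministic coverage).
#'
#' @param reads Tibble with `id`, `seq`.
#' @param contigs Tibble with `id`, `seq`.
#' @param k Seed k-mer length (default 21); must not exceed any read length.
#' @param max_mismatch Maximum substitutions tolerated (default 3).
#' @return Placements tibble: `read_id`, `contig_id`, `start`, `end`,
#'   `strand`, `mismatches`, `status` (`mapped`/`ambiguous`/`unmapped`).
#' @export
map_reads <- function(reads, contigs, k = 21, max_mismatch = 3) {
  if (nrow(reads) == 0) {
    return(tibble(read_id = character(), contig_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  mismatches = integer(), status = character()))
  }
  if (k > min(nchar(reads$seq))) {
    abort_config("seed length k exceeds the shortest read length")
  }
  res <- map_reads_cpp(reads$id, reads$seq, contigs$id, contigs$seq,
                       as.integer(k), as.integer(max_mismatch))
  out <- as_tibble(res)
  out$end <- out$start + nchar(reads$seq)
  out[, c("read_id", "contig_id", "start", "end", "strand", "mismatches",
          "status")]
}

#' Per-position read-depth profile of one contig
#'
#' `depth[p]` counts reads whose aligned span (0-based half-open) contains
#' position p. The conservation identity `sum(depth) == sum(aligned read
#' lengths)` holds by construction.
#'
#' @param placements Placements tibble ([map_reads()] or [read_sam()]); only
#'   rows with `status == "mapped"` and matching `contig_id` contribute.
#' @param contig_id Contig to profile.
#' @param contig_len Contig length in nt.
#' @return A `coverage_profile` object: `contig_id`, integer `depth` vector,
#'   `n_reads`, `contig_len`.
#' @export
depth_profile <- function(placements, contig_id, contig_len) {
  if (contig_len < 1) abort_input("contig_len must be >= 1")
  pl <- placements[!is.na(placements$contig_id) &
                     placements$contig_id == contig_id, , drop = FALSE]
  if ("status" %in% names(pl)) pl <- pl[pl$status == "mapped", , drop = FALSE]
  if (nrow(pl) > 0 && (min(pl$start) < 0 || max(pl$end) > contig_len)) {
    abort_input("a placement exceeds the contig bounds")
  }
  delta <- integer(contig_len + 1L)
  if (nrow(pl) > 0) {
    delta <- tabulate(pl$start + 1L, contig_len + 1L) -
      tabulate(pl$end + 1L, contig_len + 1L)
  }
  depth <- cumsum(delta)[seq_len(contig_len)]
  structure(list(contig_id = contig_id, depth = as.integer(depth),
                 n_reads = nrow(pl), contig_len = as.integer(contig_len)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s: %d nt, %d reads, AC %.2f, max depth %d\n",
              x$contig_id, x$contig_len, x$n_reads,
              average_coverage(x), if (x$contig_len) max(x$depth) else 0L))
  invisible(x)
}

#' @export
as_tibble.coverage_profile <- function(x, ...) {
  tibble(contig_id = x$contig_id, pos = seq_len(x$contig_len) - 1L,
         depth = x$depth)
}

#' Average coverage (AC) of a contig
#'
#' The mean number of reads covering a nucleotide, taken over the whole
#' contig.
#'
#' @param profile A `coverage_profile`.
#' @return AC (reads per nt).
#' @export
average_coverage <- function(profile) {
  mean(profile$depth)
}

#' Local coverage (LC) at the central nucleotide of the mature miRNA
#'
#' For a mature interval `[s, s + L)` in contig forward coordinates the
#' central nucleotide is `s + floor((L - 1) / 2)` (left-of-middle for even
#' L); LC is the read depth there.
#'
#' @param profile A `coverage_profile`.
#' @param mature_interval Length-2 vector `c(start, end)`, 0-based half-open,
#'   within the contig.
#' @param strand Strand of the mature annotation (recorded only; the central
#'   position is defined in forward coordinates).
#' @return A list with `lc` and `mature_center`.
#' @export
local_coverage <- function(profile, mature_interval, strand = "+") {
  s <- mature_interval[1]
  e <- mature_interval[2]
  if (s < 0 || e > profile$contig_len || e <= s) {
    abort_input("mature_interval out of contig bounds")
  }
  center <- s + floor((e - s - 1) / 2)
  list(lc = profile$depth[center + 1L], mature_center = as.integer(center),
       strand = strand)
}

#' Read count normalized per 100 nucleotides
#'
#' @param n_assigned_reads Reads assigned to the contig by the mapper.
#' @param contig_len Contig length (>= 1).
#' @return `100 * n_assigned_reads / contig_len`.
#' @export
reads_per_100nt <- function(n_assigned_reads, contig_len) {
  if (any(contig_len < 1)) abort_input("contig_len must be >= 1")
  100 * n_assigned_reads / contig_len
}

#' Build candidate records from homology hits and read placements
#'
#' One row per retained (query, contig) hit, carrying the Table-style
#' fields: alignment length and E-value from the homology screen, AC and LC
#' from the coverage profile, and the selection flag `lc > lc_threshold`
#' (strict).
#'
#' @param hits Hit tibble from [screen_contigs()].
#' @param placements Placements tibble from [map_reads()].
#' @param contigs Tibble with `id`, `seq`.
#' @param tissue Tissue label stored on every record.
#' @param lc_threshold Strict LC selection threshold (default 30).
#' @return A candidate-record tibble: `tissue`, `query_id`, `contig_id`,
#'   `contig_len`, `similarity_len`, `evalue`, `ac`, `lc`, `mature_center`,
#'   `n_assigned_reads`, `reads_per_100nt`, `selected`.
#' @export
candidate_records <- function(hits, placements, contigs, tissue,
                              lc_threshold = 30) {
  if (nrow(hits) == 0) return(empty_candidates())
  profiles <- list()
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    if (is.null(profiles[[h$contig_id]])) {
      profiles[[h$contig_id]] <<- depth_profile(placements, h$contig_id,
                                                h$contig_len)
    }
    prof <- profiles[[h$contig_id]]
    loc <- local_coverage(prof, c(h$mature_cstart, h$mature_cend), h$strand)
    tibble(tissue = tissue, query_id = h$query_id, contig_id = h$contig_id,
           contig_len = h$contig_len, similarity_len = h$similarity_len,
           evalue = h$evalue, ac = average_coverage(prof), lc = loc$lc,
           mature_center = loc$mature_center, n_assigned_reads = prof$n_reads,
           reads_per_100nt = reads_per_100nt(prof$n_reads, h$contig_len))
  })
  out <- bind_rows(rows)
  out$selected <- out$lc > lc_threshold
  out
}

empty_candidates <- function() {
  tibble(tissue = character(), query_id = character(), contig_id = character(),
         contig_len = integer(), similarity_len = integer(), evalue = numeric(),
         ac = numeric(), lc = integer(), mature_center = integer(),
         n_assigned_reads = integer(), reads_per_100nt = numeric(),
         selected = logical())
}
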