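# Sequence and placement file I/O. FASTA/FASTQ go through Biostrings; the
# SAM reader/writer is a minimal text implementation restricted to the
# ungapped records the internal mapper emits (CIGAR "<len>M"), with NM tags.

#' Read a FASTA file into a tibble
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = sub("\\s.*$", "", names(x)), seq = unname(as.character(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs A tibble with columns `id` and `seq`, or a named character
#'   vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' Qualities are ignored throughout the package and are not returned.
#'
#' @inheritParams read_fasta
#' @return A tibble with columns `id` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(id = sub("\\s.*$", "", names(x)), seq = unname(as.character(x)))
}

#' Write reads to FASTQ with constant quality
#'
#' All quality characters are "I" (Phred 40); downstream stages never use
#' base quality.
#'
#' @inheritParams write_fasta
#' @export
write_fastq <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  x <- Biostrings::DNAStringSet(seqs)
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Write read placements as SAM
#'
#' Emits a minimal valid SAM file: `@HD`/`@SQ` headers, FLAG 0/16/4, 1-based
#' POS, CIGAR `<len>M` for mapped reads, and an `NM:i:` tag with the mismatch
#' count. Unmapped and ambiguous reads are written as unmapped records.
#'
#' @param placements A placements tibble as returned by [map_reads()].
#' @param contigs Tibble with columns `id` and `seq` (used for `@SQ` lengths).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(placements, contigs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", contigs$id, nchar(contigs$seq)), con)
  mapped <- !is.na(placements$contig_id)
  flag <- ifelse(!mapped, 4L, ifelse(placements$strand == "-", 16L, 0L))
  len <- placements$end - placements$start
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*%s",
                   placements$read_id, flag,
                   ifelse(mapped, placements$contig_id, "*"),
                   ifelse(mapped, placements$start + 1L, 0L),
                   ifelse(mapped, 60L, 0L),
                   ifelse(mapped, sprintf("%dM", len), "*"),
                   ifelse(mapped, sprintf("\tNM:i:%d", placements$mismatches), ""))
  writeLines(lines, con)
  invisible(path)
}

#' Read placements from a SAM file
#'
#' Accepts the subset of SAM this package writes, plus records from external
#' aligners whose CIGAR consists of `M`/`=`/`X` (and terminal soft clips,
#' which are trimmed from the aligned span). POS is converted to 0-based
#' starts.
#'
#' @param path Path to a SAM text file.
#' @return A placements tibble (`read_id`, `contig_id`, `start`, `end`,
#'   `strand`, `mismatches`, `status`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(tibble(read_id = character(), contig_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  mismatches = integer(), status = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(get(2))
  cigar <- get(6)
  aligned_len <- vapply(cigar, function(cg) {
    if (cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    op <- substring(ops, nchar(ops))
    if (any(!op %in% c("M", "=", "X", "S", "H"))) {
      abort_input("unsupported CIGAR operation; only ungapped records are accepted")
    }
    keep <- op %in% c("M", "=", "X")
    sum(as.integer(sub(".$", "", ops[keep])))
  }, integer(1), USE.NAMES = FALSE)
  unmapped <- bitwAnd(flag, 4L) > 0L
  start <- ifelse(unmapped, NA_integer_, as.integer(get(4)) - 1L)
  nm <- vapply(f, function(x) {
    hit <- grep("^NM:i:", x, value = TRUE)
    if (length(hit)) as.integer(sub("^NM:i:", "", hit[1])) else NA_integer_
  }, integer(1))
  tibble(read_id = get(1),
         contig_id = ifelse(unmapped, NA_character_, get(3)),
         start = start,
         end = start + aligned_len,
         strand = ifelse(unmapped, NA_character_,
                         ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")),
         mismatches = nm,
         status = ifelse(unmapped, "unmapped", "mapped"))
}

#' Write intervals as BED
#'
#' @param x Tibble with columns `contig_id`, `start`, `end`, and optionally
#'   `name`, `score`, `strand` (0-based half-open, matching BED).
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  name <- if ("name" %in% names(x)) x$name else "."
  score <- if ("score" %in% names(x)) x$score else 0
  strand <- if ("strand" %in% names(x)) x$strand else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$contig_id, x$start, x$end,
                   name, format(score, trim = TRUE), strand)
  writeLines(lines, path)
  invisible(path)
}
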