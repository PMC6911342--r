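# Independent oracles used across the suite. These are deliberately naive
# implementations kept separate from the package's code paths.

# Affine-gap local alignment score by plain-matrix dynamic programming
# (gap of length g costs gap_open + g * gap_extend). Score only.
sw_score_oracle <- function(q, s, match, mismatch, gap_open, gap_extend) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  m <- length(qc)
  n <- length(sc)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  Fm <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m) + 1) {
    for (j in seq_len(n) + 1) {
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend,
                     E[i, j - 1] + gap_extend)
      Fm[i, j] <- max(H[i - 1, j] + gap_open + gap_extend,
                      Fm[i - 1, j] + gap_extend)
      sub <- H[i - 1, j - 1] +
        if (qc[i - 1] == sc[j - 1]) match else mismatch
      H[i, j] <- max(0, sub, E[i, j], Fm[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Both-strand version matching smith_waterman()'s contract.
sw_score_oracle2 <- function(q, s, sc) {
  max(sw_score_oracle(q, s, sc$match, sc$mismatch, sc$gap_open, sc$gap_extend),
      sw_score_oracle(q, revcomp(s), sc$match, sc$mismatch, sc$gap_open,
                      sc$gap_extend))
}

# Per-position depth by explicit membership counting.
depth_oracle <- function(starts, ends, contig_len) {
  vapply(seq_len(contig_len) - 1L,
         function(p) sum(starts <= p & p < ends), integer(1))
}

# Exhaustive sliding-window primer-site scan (plus strand orientation given
# by `pseq` already being the strand-appropriate sequence).
primer_sites_oracle <- function(primer, template, max_mismatch,
                                three_prime_exact) {
  tch <- strsplit(template, "", fixed = TRUE)[[1]]
  plen <- nchar(primer)
  hits <- list()
  for (strand in c("+", "-")) {
    pch <- strsplit(if (strand == "+") primer else revcomp(primer), "",
                    fixed = TRUE)[[1]]
    tail_idx <- if (strand == "+") (plen - three_prime_exact + 1):plen
                else 1:three_prime_exact
    for (o in 0:(length(tch) - plen)) {
      win <- tch[(o + 1):(o + plen)]
      if (sum(win != pch) <= max_mismatch && all(win[tail_idx] == pch[tail_idx])) {
        hits[[length(hits) + 1]] <- data.frame(position = o, strand = strand,
                                               mismatches = sum(win != pch))
      }
    }
  }
  do.call(rbind, hits)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# A small, fast scenario for pipeline-level tests.
small_scenario <- function(...) {
  args <- utils::modifyList(
    list(n_queries = 8, n_phloem_specific = 2, n_leaf_specific = 2,
         n_shared = 1, n_background = 2, n_chimeric = 1,
         contig_len_range = c(400L, 900L), n_reads_per_tissue = 8000),
    list(...))
  do.call(scenario_config, args)
}
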