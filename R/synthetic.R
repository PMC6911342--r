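# Ground-truthed synthetic data: hairpin precursor queries, two-tissue
# transcriptomes with tissue-specific / shared / background / chimeric
# contigs, and uniform short reads sampled proportionally to transcript
# abundance. Everything is deterministic for a fixed seed so downstream
# stages can be tested against exact ground truth.

#' Scenario configuration for the synthetic-data generator
#'
#' Defines a two-tissue (phloem vs leaf) simulation scenario. The defaults
#' describe the study conditions the package's end-to-end tests run under:
#' 20 precursor queries of which 6 are phloem-specific, 6 leaf-specific and
#' 2 shared; 6 precursor-free background contigs per tissue; a 50:1
#' high:low abundance ratio; 50,000 single-end 100-nt error-free reads per
#' tissue; and one chimeric contig fusing a highly expressed ORF-bearing
#' segment with a low-abundance precursor-bearing segment (the classic
#' misassembly that makes whole-contig average coverage misleading).
#'
#' @param n_queries Number of hairpin precursor queries.
#' @param hairpin_stem_len,hairpin_loop_len,mature_len Hairpin geometry in nt:
#'   stem arm length, loop length, and mature miRNA length (the mature window
#'   sits on the 5' arm).
#' @param stem_mismatches Substitutions introduced into the 3' arm relative to
#'   a perfect reverse complement of the 5' arm (imperfect plant hairpins).
#' @param contig_len_range Length range (nt) for precursor-bearing and
#'   background contigs.
#' @param n_phloem_specific,n_leaf_specific,n_shared Counts of queries
#'   embedded only in phloem, only in leaf, or in both transcriptomes.
#' @param n_background Precursor-free contigs per tissue.
#' @param n_chimeric Chimeric contigs (placed in the leaf transcriptome); each
#'   consumes one otherwise-unused query. The first chimeric contig carries
#'   its ORF on the strand opposite to the precursor.
#' @param abundance_high,abundance_low Relative transcript weights for
#'   high-abundance (embedded precursor, chimeric ORF segment) and
#'   low-abundance (background, chimeric precursor segment) sources.
#' @param n_reads_per_tissue,read_len Read count and read length.
#' @param error_rate Per-base substitution probability.
#' @param rng_seed Default seed used by [run_simulate()].
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(n_queries = 20,
                            hairpin_stem_len = 40,
                            hairpin_loop_len = 12,
                            mature_len = 21,
                            stem_mismatches = 3,
                            contig_len_range = c(400L, 2000L),
                            n_phloem_specific = 6,
                            n_leaf_specific = 6,
                            n_shared = 2,
                            n_background = 6,
                            n_chimeric = 1,
                            abundance_high = 50,
                            abundance_low = 1,
                            n_reads_per_tissue = 50000,
                            read_len = 100,
                            error_rate = 0,
                            rng_seed = 1) {
  cfg <- list(n_queries = as.integer(n_queries),
              hairpin_stem_len = as.integer(hairpin_stem_len),
              hairpin_loop_len = as.integer(hairpin_loop_len),
              mature_len = as.integer(mature_len),
              stem_mismatches = as.integer(stem_mismatches),
              contig_len_range = as.integer(contig_len_range),
              n_phloem_specific = as.integer(n_phloem_specific),
              n_leaf_specific = as.integer(n_leaf_specific),
              n_shared = as.integer(n_shared),
              n_background = as.integer(n_background),
              n_chimeric = as.integer(n_chimeric),
              abundance_high = abundance_high,
              abundance_low = abundance_low,
              n_reads_per_tissue = as.integer(n_reads_per_tissue),
              read_len = as.integer(read_len),
              error_rate = error_rate,
              rng_seed = as.integer(rng_seed))
  counts <- c(cfg$n_queries, cfg$n_phloem_specific, cfg$n_leaf_specific,
              cfg$n_shared, cfg$n_background, cfg$n_chimeric,
              cfg$n_reads_per_tissue)
  if (any(counts < 0)) abort_config("all counts must be >= 0")
  if (cfg$n_queries < 1) abort_config("n_queries must be >= 1")
  if (cfg$mature_len > cfg$hairpin_stem_len) {
    abort_config("mature_len must not exceed hairpin_stem_len")
  }
  if (cfg$stem_mismatches > cfg$hairpin_stem_len) {
    abort_config("stem_mismatches must not exceed hairpin_stem_len")
  }
  embedded <- cfg$n_phloem_specific + cfg$n_leaf_specific + cfg$n_shared
  if (embedded + cfg$n_chimeric > cfg$n_queries) {
    abort_config("tissue-specific + shared + chimeric query counts exceed n_queries")
  }
  if (length(cfg$contig_len_range) != 2 ||
      cfg$contig_len_range[1] > cfg$contig_len_range[2]) {
    abort_config("contig_len_range must be an increasing length-2 interval")
  }
  qlen <- cfg$hairpin_stem_len * 2 + cfg$hairpin_loop_len
  if (cfg$contig_len_range[1] < qlen) {
    abort_config("minimum contig length is too short to hold a precursor")
  }
  if (cfg$read_len >= cfg$contig_len_range[1]) {
    abort_config("read_len must be shorter than the minimum contig length")
  }
  if (!(cfg$abundance_high > cfg$abundance_low && cfg$abundance_low >= 0)) {
    abort_config("abundance_high must exceed abundance_low, which must be >= 0")
  }
  if (cfg$error_rate < 0 || cfg$error_rate >= 1) {
    abort_config("error_rate must lie in [0, 1)")
  }
  structure(cfg, class = "scenario_config")
}

#' Generate hairpin pre-miRNA query sequences
#'
#' Each query is `stem + loop + stem'`, where `stem'` is the reverse
#' complement of the 5' stem arm with `stem_mismatches` substitutions, so the
#' sequence folds into an imperfect hairpin. The annotated mature-miRNA
#' window (`mature_len` nt) lies on the 5' arm. Queries are pairwise
#' distinct and the output is deterministic for a fixed seed.
#'
#' @param n Number of queries (>= 1).
#' @param config A [scenario_config()].
#' @param seed Integer RNG seed (NULL to use the current RNG state).
#' @return A tibble with `query_id`, `seq`, `mature_start`, `mature_end`
#'   (0-based half-open on the query).
#' @export
generate_queries <- function(n, config = scenario_config(), seed = config$rng_seed) {
  if (n < 1) abort_config("n must be >= 1")
  sl <- config$hairpin_stem_len
  ll <- config$hairpin_loop_len
  ml <- config$mature_len
  mm <- config$stem_mismatches
  with_seed_opt(seed, {
    seqs <- character(0)
    mstart <- integer(n)
    for (i in seq_len(n)) {
      for (attempt in 1:100) {
        stem <- random_dna(sl)
        loop <- random_dna(ll)
        arm2 <- strsplit(revcomp(stem), "", fixed = TRUE)[[1]]
        if (mm > 0) {
          pos <- sample.int(sl, mm)
          for (p in pos) arm2[p] <- sample(setdiff(DNA_BASES, arm2[p]), 1)
        }
        s <- paste0(stem, loop, paste(arm2, collapse = ""))
        if (!s %in% seqs) break
      }
      if (s %in% seqs) abort_config("could not generate pairwise-distinct queries")
      seqs[i] <- s
      mstart[i] <- if (sl > ml) sample.int(sl - ml + 1, 1) - 1L else 0L
    }
    tibble(query_id = sprintf("Q%03d", seq_len(n)),
           seq = seqs, mature_start = mstart, mature_end = mstart + ml)
  })
}

# Build a random contig embedding `qseq` at a random offset.
embed_in_contig <- function(qseq, len_range, mature_start, mature_end) {
  qlen <- nchar(qseq)
  len <- sample(seq(len_range[1], len_range[2]), 1)
  if (len < qlen) abort_config("contig too short to hold the precursor")
  off <- sample.int(len - qlen + 1, 1) - 1L
  seq <- paste0(random_dna(off), qseq, random_dna(len - off - qlen))
  list(seq = seq, len = len, pstart = off, pend = off + qlen,
       mstart = off + mature_start, mend = off + mature_end)
}

# Random ORF of `len` nt (multiple of 3): ATG, non-stop codons, one stop.
random_orf <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                  collapse = "")
  codons <- setdiff(codons, STOP_CODONS)
  body <- sample(codons, len / 3 - 2, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

#' Generate leaf and phloem transcriptomes with ground truth
#'
#' Embeds each designated query once, at a random offset, in a contig of
#' random length with random flanks. Phloem-specific queries appear only in
#' the phloem contig set (and symmetrically for leaf); shared queries get an
#' independent contig in each tissue; background contigs carry no precursor.
#' Chimeric contigs (leaf tissue) concatenate a high-abundance ORF-bearing
#' segment with a low-abundance precursor-bearing segment; the first chimeric
#' contig carries its ORF on the strand opposite to the precursor.
#'
#' @param queries Tibble from [generate_queries()].
#' @param config A [scenario_config()].
#' @param seed Integer RNG seed.
#' @return A list with elements `leaf` and `phloem` (contig tibbles `id`,
#'   `seq`), `truth` (per-contig ground truth: tissue, contig_id, contig_len,
#'   query_id, role, precursor/mature intervals, abundance class, chimeric
#'   flag, fused-ORF interval and strand), `weights` (per-region sampling
#'   weights for [simulate_reads()]), and `query_roles`.
#' @export
generate_transcriptomes <- function(queries, config = scenario_config(),
                                    seed = config$rng_seed) {
  np <- config$n_phloem_specific
  nl <- config$n_leaf_specific
  ns <- config$n_shared
  nch <- config$n_chimeric
  if (np + nl + ns + nch > nrow(queries)) {
    abort_config("not enough queries for the requested class counts")
  }
  roles <- rep("unused", nrow(queries))
  roles[seq_len(np)] <- "phloem_specific"
  if (nl > 0) roles[np + seq_len(nl)] <- "leaf_specific"
  if (ns > 0) roles[np + nl + seq_len(ns)] <- "shared"
  if (nch > 0) roles[np + nl + ns + seq_len(nch)] <- "chimeric"
  query_roles <- tibble(query_id = queries$query_id, role = roles)

  with_seed_opt(seed, {
    truth <- list()
    leaf <- list()
    phloem <- list()
    weights <- list()
    counter <- c(leaf = 0L, phloem = 0L)

    add_embedded <- function(tissue, q, abundance) {
      counter[tissue] <<- counter[tissue] + 1L
      id <- sprintf("%s%04d", if (tissue == "leaf") "L" else "P", counter[tissue])
      emb <- embed_in_contig(q$seq, config$contig_len_range,
                             q$mature_start, q$mature_end)
      row <- tibble(tissue = tissue, contig_id = id, contig_len = emb$len,
                    query_id = q$query_id, role = roles[queries$query_id == q$query_id],
                    precursor_start = emb$pstart, precursor_end = emb$pend,
                    mature_start = emb$mstart, mature_end = emb$mend,
                    abundance = abundance, chimeric = FALSE,
                    orf_start = NA_integer_, orf_end = NA_integer_,
                    orf_strand = NA_character_)
      truth[[length(truth) + 1L]] <<- row
      w <- if (abundance == "high") config$abundance_high else config$abundance_low
      weights[[length(weights) + 1L]] <<-
        tibble(tissue = tissue, contig_id = id, start = 0L, end = emb$len,
               weight = w)
      if (tissue == "leaf") leaf[[id]] <<- emb$seq else phloem[[id]] <<- emb$seq
    }

    add_background <- function(tissue) {
      counter[tissue] <<- counter[tissue] + 1L
      id <- sprintf("%s%04d", if (tissue == "leaf") "L" else "P", counter[tissue])
      len <- sample(seq(config$contig_len_range[1], config$contig_len_range[2]), 1)
      seq <- random_dna(len)
      truth[[length(truth) + 1L]] <<-
        tibble(tissue = tissue, contig_id = id, contig_len = len,
               query_id = NA_character_, role = "background",
               precursor_start = NA_integer_, precursor_end = NA_integer_,
               mature_start = NA_integer_, mature_end = NA_integer_,
               abundance = "low", chimeric = FALSE,
               orf_start = NA_integer_, orf_end = NA_integer_,
               orf_strand = NA_character_)
      weights[[length(weights) + 1L]] <<-
        tibble(tissue = tissue, contig_id = id, start = 0L, end = len,
               weight = config$abundance_low)
      if (tissue == "leaf") leaf[[id]] <<- seq else phloem[[id]] <<- seq
    }

    # ORF segment 900 nt with a 300-nt embedded ORF; precursor segment 300 nt
    add_chimeric <- function(q, orf_minus) {
      counter["leaf"] <<- counter["leaf"] + 1L
      id <- sprintf("L%04d", counter["leaf"])
      orf_seg_len <- 900L
      prec_seg_len <- 300L
      qlen <- nchar(q$seq)
      if (prec_seg_len < qlen) abort_config("chimeric precursor segment too short")
      orf <- random_orf(300L)
      orf_off <- sample.int(orf_seg_len - 300L + 1L, 1) - 1L
      insert <- if (orf_minus) revcomp(orf) else orf
      orf_seg <- paste0(random_dna(orf_off), insert,
                        random_dna(orf_seg_len - orf_off - 300L))
      p_off <- sample.int(prec_seg_len - qlen + 1L, 1) - 1L
      prec_seg <- paste0(random_dna(p_off), q$seq,
                         random_dna(prec_seg_len - p_off - qlen))
      seq <- paste0(orf_seg, prec_seg)
      len <- orf_seg_len + prec_seg_len
      truth[[length(truth) + 1L]] <<-
        tibble(tissue = "leaf", contig_id = id, contig_len = len,
               query_id = q$query_id, role = "chimeric",
               precursor_start = orf_seg_len + p_off,
               precursor_end = orf_seg_len + p_off + qlen,
               mature_start = orf_seg_len + p_off + q$mature_start,
               mature_end = orf_seg_len + p_off + q$mature_end,
               abundance = "low", chimeric = TRUE,
               orf_start = orf_off, orf_end = orf_off + 300L,
               orf_strand = if (orf_minus) "-" else "+")
      weights[[length(weights) + 1L]] <<- bind_rows(
        tibble(tissue = "leaf", contig_id = id, start = 0L, end = orf_seg_len,
               weight = config$abundance_high),
        tibble(tissue = "leaf", contig_id = id, start = orf_seg_len, end = len,
               weight = config$abundance_low))
      leaf[[id]] <<- seq
    }

    for (i in seq_len(nrow(queries))) {
      q <- queries[i, ]
      switch(roles[i],
             phloem_specific = add_embedded("phloem", q, "high"),
             leaf_specific = add_embedded("leaf", q, "high"),
             shared = {
               add_embedded("leaf", q, "high")
               add_embedded("phloem", q, "high")
             },
             chimeric = add_chimeric(q, orf_minus = !any(vapply(truth, function(t)
               isTRUE(t$chimeric[1]), logical(1)))),
             NULL)
    }
    for (i in seq_len(config$n_background)) add_background("leaf")
    for (i in seq_len(config$n_background)) add_background("phloem")

    truth <- bind_rows(truth)
    # invariant: recorded intervals index the exact embedded subsequences
    list(leaf = tibble(id = names(leaf), seq = unlist(unname(leaf))),
         phloem = tibble(id = names(phloem), seq = unlist(unname(phloem))),
         truth = truth,
         weights = bind_rows(weights),
         query_roles = query_roles)
  })
}

#' Simulate uniform single-end reads from weighted contigs
#'
#' A source region is drawn with probability proportional to
#' `weight * (region_len - read_len + 1)` (so positions, not transcripts, are
#' uniform within a weight class), then a start position uniformly within the
#' region. Substitution errors are applied i.i.d. at `error_rate`. The true
#' placement of every read is returned alongside the reads.
#'
#' @param contigs Tibble with columns `id`, `seq`.
#' @param weights Named numeric vector of per-contig weights (>= 0, at least
#'   one positive). Ignored when `regions` is given.
#' @param n_reads Number of reads to draw.
#' @param read_len Read length (nt); must not exceed any positively weighted
#'   region's length.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer RNG seed (NULL for current RNG state).
#' @param regions Optional tibble (`contig_id`, `start`, `end`, `weight`)
#'   giving sub-contig source regions, e.g. the two differently expressed
#'   halves of a chimeric contig.
#' @param both_strands If TRUE, each read is reverse-complemented with
#'   probability 1/2 and its strand recorded; default FALSE (forward only).
#' @return List with `reads` (tibble `id`, `seq`) and `placements` (tibble
#'   `read_id`, `contig_id`, `start`, `end`, `strand`).
#' @export
simulate_reads <- function(contigs, weights = NULL, n_reads, read_len,
                           error_rate = 0, seed = NULL, regions = NULL,
                           both_strands = FALSE) {
  check_dna(contigs$seq, "contig sequences")
  if (is.null(regions)) {
    if (is.null(weights)) abort_input("either weights or regions is required")
    w <- weights[contigs$id]
    if (any(is.na(w))) abort_input("weights must be named by contig id")
    regions <- tibble(contig_id = contigs$id, start = 0L,
                      end = nchar(contigs$seq), weight = as.numeric(w))
  }
  if (any(regions$weight < 0)) abort_input("weights must be >= 0")
  active <- regions[regions$weight > 0, , drop = FALSE]
  if (nrow(active) == 0) abort_input("all weights are zero")
  rlen <- active$end - active$start
  if (any(rlen < read_len)) {
    abort_input("read_len exceeds the length of a positively weighted region")
  }
  seq_by_id <- setNames(contigs$seq, contigs$id)
  with_seed_opt(seed, {
    nstart <- rlen - read_len + 1L
    eff <- active$weight * nstart
    idx <- sample.int(nrow(active), n_reads, replace = TRUE, prob = eff)
    start <- active$start[idx] +
      as.integer(floor(runif(n_reads) * nstart[idx]))
    seqs <- substring(seq_by_id[active$contig_id[idx]], start + 1L,
                      start + read_len)
    strand <- rep("+", n_reads)
    if (both_strands) {
      flip <- runif(n_reads) < 0.5
      strand[flip] <- "-"
      seqs[flip] <- revcomp(seqs[flip])
    }
    if (error_rate > 0) {
      nerr <- rbinom(n_reads, read_len, error_rate)
      for (i in which(nerr > 0)) {
        chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        pos <- sample.int(read_len, nerr[i])
        for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
        seqs[i] <- paste(chars, collapse = "")
      }
    }
    ids <- sprintf("read_%06d", seq_len(n_reads))
    list(reads = tibble(id = ids, seq = unname(seqs)),
         placements = tibble(read_id = ids,
                             contig_id = active$contig_id[idx],
                             start = start, end = start + read_len,
                             strand = strand))
  })
}
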