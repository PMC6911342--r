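# End-to-end orchestration: scenario simulation to disk, and the full
# screen -> map -> coverage -> select -> compare -> diagnose (-> PCR)
# workflow over two tissues, with per-stage counts and a reproducible
# output bundle.

#' Simulate a complete two-tissue scenario to disk
#'
#' Generates queries, both transcriptomes, reads for each tissue, and all
#' ground-truth tables, writing FASTA/FASTQ/BED/TSV plus a manifest JSON
#' with the seed and per-file MD5 checksums. Identical config + seed gives
#' byte-identical outputs.
#'
#' @param config A [scenario_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; stage seeds are derived as `seed + 0..3`.
#' @return Invisibly, a list with the generated objects and `manifest`.
#' @export
run_simulate <- function(config = scenario_config(), out_dir,
                         seed = config$rng_seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort_input("could not create output directory")
  queries <- generate_queries(config$n_queries, config, seed = seed)
  tx <- generate_transcriptomes(queries, config, seed = seed + 1L)
  sim <- lapply(c(leaf = "leaf", phloem = "phloem"), function(tissue) {
    contigs <- if (tissue == "leaf") tx$leaf else tx$phloem
    regions <- tx$weights[tx$weights$tissue == tissue,
                          c("contig_id", "start", "end", "weight")]
    simulate_reads(contigs, n_reads = config$n_reads_per_tissue,
                   read_len = config$read_len, error_rate = config$error_rate,
                   seed = seed + ifelse(tissue == "leaf", 2L, 3L),
                   regions = regions)
  })
  p <- function(f) file.path(out_dir, f)
  write_fasta(rename(queries, id = "query_id"), p("queries.fasta"))
  write_bed(tibble(contig_id = queries$query_id,
                   start = queries$mature_start, end = queries$mature_end,
                   name = "mature"), p("queries_mature.bed"))
  write_fasta(tx$leaf, p("leaf_contigs.fasta"))
  write_fasta(tx$phloem, p("phloem_contigs.fasta"))
  write_fastq(sim$leaf$reads, p("leaf_reads.fastq"))
  write_fastq(sim$phloem$reads, p("phloem_reads.fastq"))
  readr::write_tsv(tx$truth, p("ground_truth.tsv"))
  readr::write_tsv(tx$weights, p("weights.tsv"))
  readr::write_tsv(sim$leaf$placements, p("leaf_read_truth.tsv"))
  readr::write_tsv(sim$phloem$placements, p("phloem_read_truth.tsv"))
  emb <- tx$truth[!is.na(tx$truth$precursor_start), ]
  write_bed(bind_rows(
    tibble(contig_id = emb$contig_id, start = emb$precursor_start,
           end = emb$precursor_end, name = paste0(emb$query_id, "_precursor")),
    tibble(contig_id = emb$contig_id, start = emb$mature_start,
           end = emb$mature_end, name = paste0(emb$query_id, "_mature"))),
    p("truth_intervals.bed"))
  files <- c("queries.fasta", "queries_mature.bed", "leaf_contigs.fasta",
             "phloem_contigs.fasta", "leaf_reads.fastq", "phloem_reads.fastq",
             "ground_truth.tsv", "weights.tsv", "leaf_read_truth.tsv",
             "phloem_read_truth.tsv", "truth_intervals.bed")
  manifest <- list(seed = seed,
                   config = unclass(config),
                   files = as.list(setNames(unname(tools::md5sum(
                     file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(queries = queries, transcriptomes = tx, reads = sim,
                 manifest = manifest, out_dir = out_dir))
}

load_scenario <- function(dir) {
  p <- function(f) file.path(dir, f)
  mature <- readr::read_tsv(p("queries_mature.bed"),
                            col_names = c("id", "mature_start", "mature_end",
                                          "name", "score", "strand"),
                            show_col_types = FALSE)
  queries <- read_fasta(p("queries.fasta")) |>
    left_join(mature[, c("id", "mature_start", "mature_end")], by = "id") |>
    rename(query_id = "id")
  list(queries = queries,
       leaf_contigs = read_fasta(p("leaf_contigs.fasta")),
       phloem_contigs = read_fasta(p("phloem_contigs.fasta")),
       leaf_reads = read_fastq(p("leaf_reads.fastq")),
       phloem_reads = read_fastq(p("phloem_reads.fastq")))
}

#' Run the full two-tissue discovery workflow
#'
#' Stages: homology screen with the strict E-value filter, read mapping,
#' coverage profiling, LC computation and selection, LC distribution
#' characterisation, paired-tissue comparison with mobility classes,
#' AC/LC-discordance diagnosis of every candidate contig, and (when primers
#' are supplied) in-silico PCR of every candidate contig. Per-stage counts
#' go into `summary`; every threshold used is recorded there and in the run
#' log.
#'
#' @param input Either a scenario directory written by [run_simulate()] or a
#'   list with `queries`, `leaf_contigs`, `phloem_contigs`, `leaf_reads`,
#'   `phloem_reads` tibbles.
#' @param out_dir Optional output directory for the TSV/JSON report bundle.
#' @param evalue_threshold Strict E-value cutoff (default 1e-15).
#' @param lc_threshold Strict LC cutoff (default 30).
#' @param discordance_ratio Minimum AC/(LC+1) for an `ac_misleading` verdict
#'   (default 5).
#' @param scoring A [scoring_model()].
#' @param K Karlin-Altschul K (default 0.41).
#' @param k,max_mismatch Mapper settings (see [map_reads()]).
#' @param min_orf_len Minimum ORF length for discordance annotation.
#' @param primers Optional primer tibble (`name`, `forward`, `reverse`).
#' @return A `phloemir_run` list: `hits`, `candidates`, `lc`, `comparison`,
#'   `discordance`, `pcr`, `summary`.
#' @export
run_all <- function(input, out_dir = NULL,
                    evalue_threshold = 1e-15, lc_threshold = 30,
                    discordance_ratio = 5, scoring = scoring_model(),
                    K = 0.41, k = 21, max_mismatch = 3, min_orf_len = 150,
                    primers = NULL) {
  if (is.character(input)) input <- load_scenario(input)
  needed <- c("queries", "leaf_contigs", "phloem_contigs", "leaf_reads",
              "phloem_reads")
  if (!all(needed %in% names(input))) {
    abort_input(paste("input must provide:", paste(needed, collapse = ", ")))
  }
  ka <- solve_lambda(scoring, K)
  stage <- function(tissue) {
    contigs <- input[[paste0(tissue, "_contigs")]]
    reads <- input[[paste0(tissue, "_reads")]]
    hits <- screen_contigs(input$queries, contigs,
                           threshold = evalue_threshold, scoring = scoring,
                           ka = ka)
    placements <- map_reads(reads, contigs, k = k, max_mismatch = max_mismatch)
    cands <- candidate_records(hits, placements, contigs, tissue,
                               lc_threshold = lc_threshold)
    diag <- lapply(seq_len(nrow(cands)), function(i) {
      cd <- cands[i, ]
      h <- hits[hits$query_id == cd$query_id & hits$contig_id == cd$contig_id, ][1, ]
      prof <- depth_profile(placements, cd$contig_id, cd$contig_len)
      if (prof$n_reads == 0) return(NULL)
      orfs <- find_orfs(contigs$seq[contigs$id == cd$contig_id],
                        min_orf_len = min_orf_len, contig_id = cd$contig_id)
      rep <- diagnose_discordance(prof, c(h$c_start, h$c_end), orfs,
                                  discordance_ratio = discordance_ratio,
                                  mature_interval = c(h$mature_cstart,
                                                      h$mature_cend))
      mutate(rep, tissue = tissue, query_id = cd$query_id, .before = 1)
    })
    list(hits = hits, candidates = cands,
         discordance = bind_rows(diag[!vapply(diag, is.null, logical(1))]),
         lc = lc_distribution(cands$lc, tissue = tissue))
  }
  leaf <- stage("leaf")
  phloem <- stage("phloem")
  comparison <- compare_tissues(leaf$candidates, phloem$candidates,
                                threshold = lc_threshold)
  pcr <- NULL
  if (!is.null(primers)) {
    all_contigs <- bind_rows(mutate(input$leaf_contigs, tissue = "leaf"),
                             mutate(input$phloem_contigs, tissue = "phloem"))
    cand_ids <- unique(c(leaf$candidates$contig_id,
                         phloem$candidates$contig_id))
    templ <- all_contigs[all_contigs$id %in% cand_ids, ]
    pcr <- bind_rows(lapply(seq_len(nrow(primers)), function(i) {
      pr <- primer_pair(primers$forward[i], primers$reverse[i])
      bind_rows(lapply(seq_len(nrow(templ)), function(j) {
        amp <- in_silico_pcr(pr, templ$seq[j])
        if (nrow(amp) == 0) return(NULL)
        mutate(amp, primer = primers$name[i], contig_id = templ$id[j],
               tissue = templ$tissue[j], .before = 1)
      }))
    }))
  }
  cmp_glance <- glance(comparison)
  summary <- list(
    thresholds = list(evalue = evalue_threshold, lc = lc_threshold,
                      discordance_ratio = discordance_ratio,
                      max_mismatch = max_mismatch, seed_k = k,
                      min_orf_len = min_orf_len,
                      scoring = unclass(scoring)[1:4], K = K,
                      lambda = ka$lambda),
    counts = list(
      n_queries = nrow(input$queries),
      n_leaf_contigs = nrow(input$leaf_contigs),
      n_phloem_contigs = nrow(input$phloem_contigs),
      n_leaf_candidates = dplyr::n_distinct(leaf$hits$contig_id),
      n_phloem_candidates = dplyr::n_distinct(phloem$hits$contig_id),
      n_leaf_selected = cmp_glance$n_leaf_selected,
      n_phloem_selected = cmp_glance$n_phloem_selected,
      n_shared = cmp_glance$n_shared,
      n_ac_misleading = n_mislead(leaf$discordance) +
        n_mislead(phloem$discordance)),
    shapiro = list(leaf = list(W = leaf$lc$W, p_value = leaf$lc$p_value),
                   phloem = list(W = phloem$lc$W, p_value = phloem$lc$p_value)),
    classes = as.list(table(comparison$class)))
  res <- structure(list(hits = bind_rows(mutate(leaf$hits, tissue = "leaf",
                                                .before = 1),
                                         mutate(phloem$hits, tissue = "phloem",
                                                .before = 1)),
                        candidates = bind_rows(leaf$candidates,
                                               phloem$candidates),
                        lc = list(leaf = leaf$lc, phloem = phloem$lc),
                        comparison = comparison,
                        discordance = bind_rows(leaf$discordance,
                                                phloem$discordance),
                        pcr = pcr, summary = summary),
                   class = "phloemir_run")
  if (!is.null(out_dir)) write_run_bundle(res, out_dir)
  res
}

n_mislead <- function(d) {
  if (!"verdict" %in% names(d)) 0L else sum(d$verdict == "ac_misleading")
}

write_run_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(res$hits, p("hits.tsv"))
  readr::write_tsv(res$candidates, p("candidates.tsv"))
  readr::write_tsv(as_tibble(res$comparison), p("comparison.tsv"))
  readr::write_tsv(res$discordance, p("discordance.tsv"))
  readr::write_tsv(tidy(res$lc$leaf), p("lc_histogram_leaf.tsv"))
  readr::write_tsv(tidy(res$lc$phloem), p("lc_histogram_phloem.tsv"))
  if (!is.null(res$pcr)) readr::write_tsv(res$pcr, p("amplicons.tsv"))
  jsonlite::write_json(res$summary, p("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  th <- res$summary$thresholds
  writeLines(c("phloemir run log",
               sprintf("evalue_threshold\t%g", th$evalue),
               sprintf("lc_threshold\t%g", th$lc),
               sprintf("discordance_ratio\t%g", th$discordance_ratio),
               sprintf("max_mismatch\t%d", th$max_mismatch),
               sprintf("seed_k\t%d", th$seed_k),
               sprintf("min_orf_len\t%g", th$min_orf_len),
               sprintf("scoring\tmatch=%g mismatch=%g gap_open=%g gap_extend=%g",
                       th$scoring$match, th$scoring$mismatch,
                       th$scoring$gap_open, th$scoring$gap_extend),
               sprintf("karlin_altschul\tlambda=%.9f K=%g", th$lambda, th$K)),
             p("run_log.txt"))
  invisible(out_dir)
}

#' @export
print.phloemir_run <- function(x, ...) {
  ct <- x$summary$counts
  cat("<phloemir_run>\n")
  cat(sprintf("  queries: %d | contigs: leaf %d, phloem %d\n",
              ct$n_queries, ct$n_leaf_contigs, ct$n_phloem_contigs))
  cat(sprintf("  candidates (E < %g): leaf %d, phloem %d\n",
              x$summary$thresholds$evalue, ct$n_leaf_candidates,
              ct$n_phloem_candidates))
  cat(sprintf("  selected (LC > %g): leaf %d, phloem %d, shared %d\n",
              x$summary$thresholds$lc, ct$n_leaf_selected,
              ct$n_phloem_selected, ct$n_shared))
  cat(sprintf("  ac_misleading contigs: %d\n", ct$n_ac_misleading))
  invisible(x)
}

#' @rdname run_all
#' @param x A `phloemir_run`.
#' @param ... Unused.
#' @export
glance.phloemir_run <- function(x, ...) {
  as_tibble(x$summary$counts)
}
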