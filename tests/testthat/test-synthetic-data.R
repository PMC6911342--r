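test_that("hairpin queries follow the stem-loop-stem' construction", {
  cfg <- scenario_config()
  q <- generate_queries(120, cfg, seed = 1)
  expect_equal(nrow(q), 120)
  expect_true(all(nchar(q$seq) == 92))
  expect_equal(anyDuplicated(q$seq), 0L)
  # 3' arm reverse-complement-matches the 5' arm at >= 37/40 positions
  arm5 <- substr(q$seq, 1, 40)
  arm3 <- substr(q$seq, 53, 92)
  agree <- mapply(function(a, b) {
    sum(strsplit(revcomp(a), "")[[1]] == strsplit(b, "")[[1]])
  }, arm5, arm3)
  expect_true(all(agree >= 37))
  # mature window on the 5' arm
  expect_true(all(q$mature_start >= 0 & q$mature_end <= 40))
  expect_true(all(q$mature_end - q$mature_start == 21))
  # deterministic for a fixed seed
  expect_identical(q, generate_queries(120, cfg, seed = 1))
})

test_that("zero-mismatch hairpins are exact reverse-complement palindromic arms", {
  cfg <- scenario_config(hairpin_stem_len = 5, hairpin_loop_len = 4,
                         mature_len = 5, stem_mismatches = 0)
  q <- generate_queries(1, cfg, seed = 7)
  expect_equal(nchar(q$seq), 14L)
  expect_identical(substr(q$seq, 10, 14), revcomp(substr(q$seq, 1, 5)))
})

test_that("invalid query requests raise configuration errors", {
  expect_error(generate_queries(0, scenario_config()),
               class = "phloemir_config_error")
  expect_error(scenario_config(mature_len = 50, hairpin_stem_len = 40),
               class = "phloemir_config_error")
  expect_error(scenario_config(contig_len_range = c(50, 100)),
               class = "phloemir_config_error")
  expect_error(scenario_config(abundance_high = 1, abundance_low = 1),
               class = "phloemir_config_error")
})

test_that("transcriptome ground truth round-trips embedded intervals", {
  cfg <- small_scenario()
  q <- generate_queries(cfg$n_queries, cfg, seed = 11)
  tx <- generate_transcriptomes(q, cfg, seed = 12)
  emb <- tx$truth[!is.na(tx$truth$query_id), ]
  expect_gt(nrow(emb), 0)
  for (i in seq_len(nrow(emb))) {
    r <- emb[i, ]
    contigs <- if (r$tissue == "leaf") tx$leaf else tx$phloem
    s <- contigs$seq[contigs$id == r$contig_id]
    expect_identical(substr(s, r$precursor_start + 1, r$precursor_end),
                     q$seq[q$query_id == r$query_id])
    qq <- q[q$query_id == r$query_id, ]
    expect_identical(substr(s, r$mature_start + 1, r$mature_end),
                     substr(qq$seq, qq$mature_start + 1, qq$mature_end))
    expect_true(r$mature_start >= r$precursor_start &&
                  r$mature_end <= r$precursor_end)
  }
})

test_that("tissue-specific queries are absent from the other tissue", {
  cfg <- scenario_config(n_queries = 1, n_phloem_specific = 1,
                         n_leaf_specific = 0, n_shared = 0, n_background = 2,
                         n_chimeric = 0, n_reads_per_tissue = 100)
  q <- generate_queries(1, cfg, seed = 3)
  tx <- generate_transcriptomes(q, cfg, seed = 4)
  leaf_truth <- tx$truth[tx$truth$tissue == "leaf", ]
  expect_true(all(leaf_truth$role == "background"))
  phloem_truth <- tx$truth[tx$truth$tissue == "phloem", ]
  expect_equal(sum(!is.na(phloem_truth$query_id)), 1L)
})

test_that("the first chimeric contig records an opposite-strand fused ORF", {
  cfg <- small_scenario()
  q <- generate_queries(cfg$n_queries, cfg, seed = 21)
  tx <- generate_transcriptomes(q, cfg, seed = 22)
  chim <- tx$truth[tx$truth$chimeric, ]
  expect_equal(nrow(chim), 1L)
  expect_identical(chim$orf_strand, "-")
  expect_identical(chim$tissue, "leaf")
  # the fused ORF really is an ORF on the minus strand
  contig <- tx$leaf$seq[tx$leaf$id == chim$contig_id]
  orfs <- find_orfs(contig, min_orf_len = 150)
  minus <- orfs[orfs$strand == "-", ]
  expect_true(any(minus$start <= chim$orf_start & minus$end >= chim$orf_end))
  # segment-level weights: ORF segment high, precursor segment low
  w <- tx$weights[tx$weights$contig_id == chim$contig_id, ]
  expect_equal(nrow(w), 2L)
  expect_gt(w$weight[1], w$weight[2])
})

test_that("generation is byte-identical across repeated runs with one seed", {
  cfg <- small_scenario()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- run_simulate(cfg, d1, seed = 5)$manifest
  m2 <- run_simulate(cfg, d2, seed = 5)$manifest
  expect_identical(unname(unlist(m1$files)), unname(unlist(m2$files)))
  # and checksums move when the seed moves (collision check across seeds)
  sums <- vapply(1:3, function(s) {
    d <- file.path(withr::local_tempdir(), paste0("s", s))
    paste(unlist(run_simulate(cfg, d, seed = s)$manifest$files), collapse = "")
  }, character(1))
  expect_equal(anyDuplicated(sums), 0L)
})

test_that("error-free reads are exact substrings at their recorded origins", {
  contig <- tibble::tibble(id = "c1", seq = random_seq(400))
  sim <- simulate_reads(contig, c(c1 = 1), n_reads = 100, read_len = 50,
                        seed = 9)
  expect_identical(sim$reads$seq,
                   substr(rep(contig$seq, 100), sim$placements$start + 1,
                          sim$placements$end))
})

test_that("read counts split by weight within binomial sampling error", {
  set.seed(2)
  contigs <- tibble::tibble(id = c("a", "b"),
                            seq = c(random_seq(600), random_seq(600)))
  sim <- simulate_reads(contigs, c(a = 9, b = 1), n_reads = 10000,
                        read_len = 100, seed = 13)
  n_a <- sum(sim$placements$contig_id == "a")
  sd3 <- 3 * sqrt(10000 * 0.9 * 0.1)
  expect_lt(abs(n_a - 9000), sd3)
})

test_that("zero-weight contigs yield no reads and all-zero weights error", {
  contigs <- tibble::tibble(id = c("a", "b"),
                            seq = c(random_seq(300), random_seq(300)))
  sim <- simulate_reads(contigs, c(a = 0, b = 1), n_reads = 500,
                        read_len = 50, seed = 1)
  expect_false(any(sim$placements$contig_id == "a"))
  expect_error(simulate_reads(contigs, c(a = 0, b = 0), n_reads = 10,
                              read_len = 50),
               class = "phloemir_input_error")
})

test_that("interior read depth is binomial around R * l / (G - l + 1)", {
  G <- 500L
  l <- 50L
  R <- 2000L
  contig <- tibble::tibble(id = "c", seq = random_seq(G))
  p <- l / (G - l + 1)
  mu <- R * p
  sd4 <- 4 * sqrt(R * p * (1 - p))
  probe <- c(60L, 150L, 250L, 350L, 440L) # fixed interior positions (0-based)
  for (seed in 1:5) {
    sim <- simulate_reads(contig, c(c = 1), n_reads = R, read_len = l,
                          seed = seed)
    depth <- depth_oracle(sim$placements$start, sim$placements$end, G)
    expect_true(all(abs(depth[probe + 1L] - mu) <= sd4))
    # whole-profile envelope: no interior position strays grossly
    interior <- depth[(l):(G - l)]
    expect_true(all(abs(interior - mu) <= 1.5 * sd4))
  }
})
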