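test_that("error-free simulated reads map back to their true origins", {
  cfg <- small_scenario()
  q <- generate_queries(cfg$n_queries, cfg, seed = 41)
  tx <- generate_transcriptomes(q, cfg, seed = 42)
  sim <- simulate_reads(tx$phloem,
                        regions = tx$weights[tx$weights$tissue == "phloem",
                                             -1],
                        n_reads = 500, read_len = 100, seed = 43)
  pl <- map_reads(sim$reads, tx$phloem)
  mapped <- pl[pl$status == "mapped", ]
  truth <- sim$placements[match(mapped$read_id, sim$placements$read_id), ]
  expect_identical(mapped$contig_id, truth$contig_id)
  expect_identical(mapped$start, truth$start)
  expect_true(all(mapped$mismatches == 0))
  expect_gt(nrow(mapped) / nrow(pl), 0.99)
})

test_that("reads present identically in two contigs are discarded ambiguous", {
  shared <- random_seq(120)
  contigs <- tibble::tibble(id = c("a", "b"),
                            seq = paste0(c(random_seq(100), random_seq(100)),
                                         shared,
                                         c(random_seq(100), random_seq(100))))
  reads <- tibble::tibble(id = "r1", seq = substr(shared, 11, 110))
  pl <- map_reads(reads, contigs)
  expect_identical(pl$status, "ambiguous")
})

test_that("noisy reads map to their true origin at the expected rate", {
  set.seed(5)
  contigs <- tibble::tibble(id = c("x", "y"),
                            seq = c(random_seq(1500), random_seq(1500)))
  sim <- simulate_reads(contigs, c(x = 1, y = 1), n_reads = 3000,
                        read_len = 100, error_rate = 0.01, seed = 44)
  pl <- map_reads(sim$reads, contigs, max_mismatch = 3)
  mapped <- pl[pl$status == "mapped", ]
  truth <- sim$placements[match(mapped$read_id, sim$placements$read_id), ]
  correct <- sum(mapped$contig_id == truth$contig_id &
                   mapped$start == truth$start)
  # P(>3 errors in 100 nt at 1%) ~ 1.8%; seeding needs one intact end k-mer
  expect_gt(nrow(mapped) / nrow(pl), 0.95)
  expect_gt(correct / nrow(mapped), 0.99)
  expect_error(map_reads(sim$reads, contigs, k = 200),
               class = "phloemir_config_error")
})

test_that("depth profiles count covering reads and conserve read mass", {
  pl <- tibble::tibble(read_id = c("r1", "r2"), contig_id = "c",
                       start = c(0L, 2L), end = c(5L, 7L),
                       strand = "+", mismatches = 0L, status = "mapped")
  prof <- depth_profile(pl, "c", 10L)
  expect_identical(prof$depth, c(1L, 1L, 2L, 2L, 2L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(average_coverage(prof), 1.0)
  # no reads: all-zero profile, AC 0
  prof0 <- depth_profile(pl[0, ], "c", 10L)
  expect_identical(prof0$depth, rep(0L, 10))
  expect_equal(average_coverage(prof0), 0)
  # out-of-bounds placements are an input error
  bad <- tibble::tibble(read_id = "r", contig_id = "c", start = 8L, end = 30L,
                        strand = "+", mismatches = 0L, status = "mapped")
  expect_error(depth_profile(bad, "c", 10L), class = "phloemir_input_error")
})

test_that("random profiles equal brute-force membership counts", {
  set.seed(6)
  G <- 800L
  starts <- sample.int(G - 60L, 1000, replace = TRUE) - 1L
  ends <- starts + sample(30:60, 1000, replace = TRUE)
  pl <- tibble::tibble(read_id = sprintf("r%04d", 1:1000), contig_id = "c",
                       start = starts, end = ends, strand = "+",
                       mismatches = 0L, status = "mapped")
  prof <- depth_profile(pl, "c", G)
  expect_identical(prof$depth, depth_oracle(starts, ends, G))
  # conservation: sum of depth equals summed aligned lengths
  expect_equal(sum(prof$depth), sum(ends - starts))
  expect_equal(average_coverage(prof), sum(ends - starts) / G)
  expect_lte(max(prof$depth), nrow(pl))
})

test_that("local coverage reads the depth at the mature-center position", {
  pl <- tibble::tibble(read_id = c("r1", "r2"), contig_id = "c",
                       start = c(0L, 2L), end = c(5L, 7L),
                       strand = "+", mismatches = 0L, status = "mapped")
  prof <- depth_profile(pl, "c", 10L)
  loc <- local_coverage(prof, c(2, 7))
  expect_equal(loc$mature_center, 4L)
  expect_equal(loc$lc, 2L)
  # even length resolves left-of-middle: L = 22 starting at 100 -> 110
  prof2 <- depth_profile(pl[0, ], "c2", 200L)
  expect_equal(local_coverage(prof2, c(100, 122))$mature_center, 110L)
  expect_error(local_coverage(prof, c(8, 30)), class = "phloemir_input_error")
  expect_true(local_coverage(prof, c(0, 10))$lc <= max(prof$depth))
})

test_that("per-100-nt normalisation is scale invariant", {
  expect_equal(reads_per_100nt(500, 1000), 50)
  expect_equal(reads_per_100nt(0, 1000), 0)
  expect_equal(reads_per_100nt(1000, 2000), reads_per_100nt(500, 1000))
})

test_that("chimeric contigs have AC far above LC at the precursor", {
  cfg <- small_scenario()
  q <- generate_queries(cfg$n_queries, cfg, seed = 51)
  tx <- generate_transcriptomes(q, cfg, seed = 52)
  chim <- tx$truth[tx$truth$chimeric, ]
  sim <- simulate_reads(tx$leaf,
                        regions = tx$weights[tx$weights$tissue == "leaf", -1],
                        n_reads = 20000, read_len = 100, seed = 53)
  pl <- map_reads(sim$reads, tx$leaf)
  prof <- depth_profile(pl, chim$contig_id, chim$contig_len)
  ac <- average_coverage(prof)
  lc <- local_coverage(prof, c(chim$mature_start, chim$mature_end))$lc
  expect_gte(ac / max(lc, 1), 5)
})

test_that("SAM output round-trips through the reader", {
  contigs <- tibble::tibble(id = "c1", seq = random_seq(300))
  sim <- simulate_reads(contigs, c(c1 = 1), n_reads = 50, read_len = 60,
                        seed = 3)
  pl <- map_reads(sim$reads, contigs)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(pl, contigs, path)
  back <- read_sam(path)
  keep <- pl$status == "mapped"
  expect_identical(back$start[keep], pl$start[keep])
  expect_identical(back$end[keep], pl$end[keep])
  expect_identical(back$contig_id[keep], pl$contig_id[keep])
  expect_identical(back$mismatches[keep], pl$mismatches[keep])
})
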