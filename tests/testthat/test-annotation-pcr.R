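test_that("ORF finding handles the minimal ORF and both strands", {
  orfs <- find_orfs("ATGAAATAA", min_orf_len = 9)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$start, 0L)
  expect_equal(orfs$end, 9L)
  expect_equal(orfs$strand, "+")
  rc <- find_orfs(revcomp("ATGAAATAA"), min_orf_len = 9)
  expect_equal(nrow(rc), 1L)
  expect_equal(rc$start, 0L)
  expect_equal(rc$end, 9L)
  expect_equal(rc$strand, "-")
  expect_equal(nrow(find_orfs(strrep("C", 300))), 0L)
})

test_that("ORF calls are strand-symmetric in forward coordinates", {
  set.seed(15)
  for (i in 1:10) {
    s <- random_seq(600)
    fwd <- find_orfs(s, min_orf_len = 60)
    rev <- find_orfs(revcomp(s), min_orf_len = 60)
    flip <- c("+" = "-", "-" = "+")
    key <- function(x) paste(x$start, x$end, x$strand, sep = ":")
    rev_mapped <- tibble::tibble(start = 600L - rev$end, end = 600L - rev$start,
                                 strand = unname(flip[rev$strand]))
    expect_setequal(key(fwd), key(rev_mapped))
  }
})

test_that("coverage peaks and discordance reproduce the chimeric diagnosis", {
  # constructed chimera: high ORF-segment coverage, scarce precursor coverage
  cfg <- small_scenario()
  q <- generate_queries(cfg$n_queries, cfg, seed = 61)
  tx <- generate_transcriptomes(q, cfg, seed = 62)
  chim <- tx$truth[tx$truth$chimeric, ]
  sim <- simulate_reads(tx$leaf,
                        regions = tx$weights[tx$weights$tissue == "leaf", -1],
                        n_reads = 20000, read_len = 100, seed = 63)
  pl <- map_reads(sim$reads, tx$leaf)
  prof <- depth_profile(pl, chim$contig_id, chim$contig_len)
  orfs <- find_orfs(tx$leaf$seq[tx$leaf$id == chim$contig_id])
  rep <- diagnose_discordance(prof,
                              c(chim$precursor_start, chim$precursor_end),
                              orfs,
                              mature_interval = c(chim$mature_start,
                                                  chim$mature_end))
  expect_equal(rep$verdict, "ac_misleading")
  expect_true(rep$peak_overlaps_orf)
  expect_false(rep$peak_overlaps_precursor)
  # a contig whose only expressed region is the precursor is concordant
  emb <- tx$truth[tx$truth$tissue == "leaf" & !is.na(tx$truth$query_id) &
                    !tx$truth$chimeric, ][1, ]
  prof2 <- depth_profile(pl, emb$contig_id, emb$contig_len)
  rep2 <- diagnose_discordance(prof2, c(emb$precursor_start, emb$precursor_end),
                               mature_interval = c(emb$mature_start,
                                                   emb$mature_end))
  expect_equal(rep2$verdict, "concordant")
  expect_error(diagnose_discordance(depth_profile(pl[0, ], "x", 10L), c(0, 5)),
               class = "phloemir_input_error")
})

test_that("published-style AC/LC values with a disjoint peak are flagged", {
  # profile shaped like the leaf miR393a contig: AC 80.8, LC 5 over 1718 nt
  G <- 1718L
  depth <- rep(5L, G)
  peak_span <- 200:900
  depth[peak_span] <- as.integer(round((80.8 * G - 5 * (G - length(peak_span))) /
                                         length(peak_span)))
  prof <- structure(list(contig_id = "L11031", depth = depth,
                         n_reads = 1L, contig_len = G),
                    class = "coverage_profile")
  rep <- diagnose_discordance(prof, precursor_interval = c(1400, 1600))
  expect_equal(rep$verdict, "ac_misleading")
  expect_gte(rep$ratio, 5)
  expect_equal(rep$lc, 5L)
  expect_equal(round(rep$ac, 1), 80.8, tolerance = 0.05)
})

test_that("primer sites respect mismatch budget and the 3'-exact rule", {
  set.seed(16)
  template <- random_seq(400)
  primer <- substr(template, 101, 120)
  sites <- find_primer_sites(primer, template, 2, 3)
  plus <- sites[sites$strand == "+", ]
  expect_true(any(plus$position == 100 & plus$mismatches == 0))
  # a single 3'-terminal mismatch kills the site
  bad <- primer
  last <- substr(bad, 20, 20)
  substr(bad, 20, 20) <- setdiff(c("A", "C", "G", "T"), last)[1]
  sites_bad <- find_primer_sites(bad, template, 2, 3)
  expect_false(any(sites_bad$strand == "+" & sites_bad$position == 100))
})

test_that("primer scanning equals the exhaustive sliding-window oracle", {
  set.seed(17)
  for (i in 1:5) {
    template <- random_seq(1000)
    primer <- random_seq(20)
    got <- find_primer_sites(primer, template, 6, 2)
    want <- primer_sites_oracle(primer, template, 6, 2)
    key <- function(x) if (is.null(x) || nrow(x) == 0) character(0) else
      paste(x$position, x$strand, x$mismatches, sep = ":")
    expect_setequal(key(got), key(want))
  }
})

test_that("in-silico PCR amplifies the constructed 140-bp product", {
  set.seed(18)
  f <- random_seq(20)
  r <- random_seq(20)
  template <- paste0(random_seq(50), f, random_seq(100), revcomp(r),
                     random_seq(50))
  amp <- in_silico_pcr(primer_pair(f, r), template)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, 140L)
  expect_equal(amp$end - amp$start, amp$length)
  # primers in the same orientation only: no product
  template_same <- paste0(random_seq(50), f, random_seq(100), r,
                          random_seq(50))
  expect_equal(nrow(in_silico_pcr(primer_pair(f, r), template_same)), 0L)
})

test_that("species-discriminating primers amplify only the matching template", {
  set.seed(19)
  f <- random_seq(20)
  r <- random_seq(20)
  template_a <- paste0(random_seq(60), f, random_seq(80), revcomp(r),
                       random_seq(60))
  # template B carries >= 3 mismatches at the forward primer's 3' terminus
  f_broken <- paste0(substr(f, 1, 17), chartr("ACGT", "GTAC", substr(f, 18, 20)))
  template_b <- paste0(random_seq(60), f_broken, random_seq(80), revcomp(r),
                       random_seq(60))
  pr <- primer_pair(f, r, max_mismatch = 2, three_prime_exact = 3)
  expect_gt(nrow(in_silico_pcr(pr, template_a)), 0L)
  expect_equal(nrow(in_silico_pcr(pr, template_b)), 0L)
})

test_that("the synthetic stand-in contig yields 162 and 276 bp products", {
  fasta <- system.file("extdata", "synthetic_pri_mir319a.fasta",
                       package = "phloemir")
  primers <- read_primers(system.file("extdata", "synthetic_primers.tsv",
                                      package = "phloemir"))
  template <- read_fasta(fasta)$seq
  lens <- vapply(seq_len(nrow(primers)), function(i) {
    amp <- in_silico_pcr(primer_pair(primers$forward[i], primers$reverse[i]),
                         template)
    expect_equal(nrow(amp), 1L)
    amp$length
  }, integer(1))
  expect_equal(sort(lens), c(162L, 276L))
})

test_that("primer pairs validate length and 3'-exact bounds", {
  expect_error(primer_pair("ACGT", strrep("A", 20)),
               class = "phloemir_config_error")
  expect_error(primer_pair(strrep("AC", 10), strrep("GT", 10),
                           three_prime_exact = 25),
               class = "phloemir_config_error")
})
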