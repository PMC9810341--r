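test_that("SNP overlap counting distinguishes distinct SNPs from pairs", {
  peaks <- peak_set(c("c", "c"), c(0, 5), c(10, 15))
  snp_in <- snps_from_positions("c", 0, base = 0)    # at a peak start
  snp_out <- snps_from_positions("c", 15, base = 0)  # at exclusive end
  expect_equal(count_snp_overlaps(snp_in, peaks)$O, 1)
  expect_equal(count_snp_overlaps(snp_out, peaks)$O, 0)
  # one SNP inside two overlapping peaks: one distinct hit, two pairs
  snp_mid <- snps_from_positions("c", 7, base = 0)
  res <- count_snp_overlaps(snp_mid, peaks)
  expect_equal(res$O, 1)
  expect_equal(nrow(res$hits), 2)
  expect_equal(count_snp_overlaps(snp_mid, peaks, count = "pairs")$O, 2)
  expect_error(count_snp_overlaps(peak_set("c", 0, 5), peaks), "1-bp")
})

test_that("overlap counts equal quadratic brute force on random fixtures", {
  set.seed(40)
  for (i in 1:100) {
    genome <- c(chrA = 4000, chrB = 2000)
    peaks <- random_peaks(sample(5:40, 1), genome = genome)
    pos <- sample.int(4000, sample(5:50, 1)) - 1
    chrom <- sample(names(genome), length(pos), replace = TRUE)
    keep <- pos < genome[chrom]
    snps <- peak_set(chrom[keep], pos[keep], pos[keep] + 1,
                     genome = genome)
    bf <- brute_force_pairs(snps, peaks)
    res <- count_snp_overlaps(snps, peaks)
    expect_equal(res$O, length(unique(bf$a_index)))
    expect_equal(nrow(res$hits), nrow(bf))
    # the shuffle-loop fast path agrees with the overlap engine
    fast <- chromprime:::count_points_in_union(
      split(snps$start, snps$chrom), peaks$chrom, peaks$start, peaks$end)
    expect_equal(fast, res$O)
  }
})

test_that("enrichment p hits its floor when the signal dominates every null", {
  sc <- generate_snp_scenario(enrichment_fold = 50, seed = 3)
  r <- enrichment_test(sc$snps, sc$peak_sets$ct1,
                       genome = attr(sc$snps, "genome"), B = 99, seed = 4)
  expect_equal(r$p, 1 / 100)
  expect_gt(r$fold, 5)
})

test_that("null expectation tracks the peak coverage fraction", {
  # one peak covering half the chromosome: per-SNP hit probability under
  # a uniform shuffle is exactly computable, and mean coverage is 1/2
  G <- 2e5; w <- 1e5
  genome <- c(chr1 = G)
  peaks <- peak_set("chr1", 0, w, genome = genome)
  set.seed(17)
  pos <- sample.int(G, 400) - 1
  snps <- peak_set("chr1", pos, pos + 1, genome = genome)
  r <- enrichment_test(snps, peaks, genome = genome, B = 2000, seed = 6)
  p_hit <- (pmin(pos, G - w) - pmax(0, pos - w + 1) + 1) / (G - w + 1)
  expected <- sum(p_hit)
  null_counts <- attr(r, "null")
  se <- sd(null_counts) / sqrt(length(null_counts))
  expect_lt(abs(r$E - expected), 3 * se)
  expect_equal(expected / 400, 0.5, tolerance = 0.05)
})

test_that("expected counts scale linearly with the number of SNPs", {
  sc <- generate_snp_scenario(n_snps = 200, enrichment_fold = 1, seed = 8)
  genome <- attr(sc$snps, "genome")
  snps2 <- peak_set(rep(sc$snps$chrom, 2), rep(sc$snps$start, 2),
                    rep(sc$snps$end, 2), genome = genome)
  r1 <- enrichment_test(sc$snps, sc$peak_sets$ct1, genome, B = 300, seed = 5)
  r2 <- enrichment_test(snps2, sc$peak_sets$ct1, genome, B = 300, seed = 5)
  expect_equal(r2$E / r1$E, 2, tolerance = 0.02)
})

test_that("empirical p is invariant under chromosome relabeling", {
  sc <- generate_snp_scenario(enrichment_fold = 3, seed = 12)
  genome <- attr(sc$snps, "genome")
  relabel <- c(chr1 = "k9", chr2 = "k1")
  genome2 <- stats::setNames(genome, relabel[names(genome)])
  snps2 <- peak_set(relabel[sc$snps$chrom], sc$snps$start, sc$snps$end,
                    genome = genome2)
  peaks <- sc$peak_sets$ct1
  peaks2 <- peak_set(relabel[peaks$chrom], peaks$start, peaks$end,
                     genome = genome2)
  r1 <- enrichment_test(sc$snps, peaks, genome, B = 199, seed = 21)
  r2 <- enrichment_test(snps2, peaks2, genome2, B = 199, seed = 21)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$O, r2$O)
})

test_that("multi-set report ranks the planted cell type first with BH", {
  sc <- generate_snp_scenario(enrichment_fold = 8, seed = 19)
  res <- multi_set_report(sc$snps, sc$peak_sets,
                          genome = attr(sc$snps, "genome"), B = 199,
                          seed = 19)
  expect_equal(res$set[1], sc$truth$enriched_celltype)
  expect_equal(res$q, bh_adjust(res$p), tolerance = 1e-12)
  expect_true(all(res$p >= 1 / 200))
  single <- multi_set_report(sc$snps, sc$peak_sets["ct2"],
                             genome = attr(sc$snps, "genome"), B = 99,
                             seed = 3)
  expect_equal(single$q, single$p)
})

test_that("enrichment_test validates its inputs", {
  sc <- generate_snp_scenario(seed = 1)
  expect_error(enrichment_test(sc$snps, sc$peak_sets$ct1,
                               genome = c(chr1 = 1e6), B = 9, seed = 1),
               "missing chromosome")
  expect_error(enrichment_test(sc$snps, sc$peak_sets$ct1, B = 0,
                               genome = attr(sc$snps, "genome")),
               "B must be >= 1")
})
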