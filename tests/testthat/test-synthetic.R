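test_that("config validation rejects inconsistent settings before sampling", {
  expect_error(synth_config(n_genes = 50), "exceeds n_genes")
  expect_error(synth_config(fold_change_expr = 0.5), ">= 1")
  expect_error(synth_config(baseline_low_mu = 10, baseline_high_mu = 5),
               "below baseline_high_mu")
  expect_error(synth_config(genes_per_type = c(TypeX = 5)), "names")
})

test_that("the generator is deterministic for a fixed seed", {
  a <- small_multiome(seed = 33)
  b <- small_multiome(seed = 33)
  expect_identical(a$expression$counts, b$expression$counts)
  expect_identical(a$atac$counts, b$atac$counts)
  expect_identical(a$truth, b$truth)
  c2 <- small_multiome(seed = 34)
  expect_false(identical(a$expression$counts, c2$expression$counts))
})

test_that("counts are integer, non-negative, with observed totals = colsums", {
  mo <- small_multiome(seed = 2, totals_mode = "observed")
  expect_true(all(mo$expression$counts >= 0))
  expect_true(all(mo$expression$counts == round(mo$expression$counts)))
  expect_equal(unname(mo$expression$totals),
               unname(colSums(mo$expression$counts)))
})

test_that("negative-binomial draws match their planted moments", {
  # replicate draws of one Type2a gene's accessibility across seeds:
  # mean stays at baseline_high_mu in both conditions, variance exceeds
  # the mean (overdispersion)
  cfg0 <- synth_config(n_genes = 40,
                       genes_per_type = c(Type2a = 10),
                       n_replicates = 1, seed = 1)
  gene <- "g0001"
  draws <- vapply(1:500, function(s) {
    mo <- generate_multiome(synth_config(n_genes = 40,
                                         genes_per_type = c(Type2a = 10),
                                         n_replicates = 1, seed = s))
    mo$atac$counts[gene, ]
  }, numeric(2))
  mu <- cfg0$baseline_high_mu
  sigma <- sqrt(mu + mu^2 / cfg0$nb_dispersion)
  for (cond in 1:2) {
    m <- mean(draws[cond, ])
    expect_lt(abs(m - mu), 3 * sigma / sqrt(ncol(draws)))
  }
  expect_gt(var(as.numeric(draws)), mean(draws)) # overdispersed
})

test_that("unit fold changes degenerate every gene to null", {
  mo <- generate_multiome(synth_config(n_genes = 100,
                                       genes_per_type = c(Type1a = 10,
                                                          Type3 = 10),
                                       fold_change_expr = 1,
                                       fold_change_ca = 1, seed = 9))
  expect_true(all(mo$truth$true_type == "null"))
  expect_true(all(mo$means$expr_ctrl == mo$means$expr_dis))
})

test_that("truth labels are consistent with the generating means", {
  mo <- small_multiome(seed = 4)
  ev <- analytic_evidence(mo)
  ta <- classify_genes(ev$expr, ev$ca, ev$baseline)
  m <- merge(mo$truth, ta[c("gene_id", "label")], by = "gene_id")
  expect_identical(m$label,
                   ifelse(m$true_type == "null", "unclassified",
                          m$true_type))
})

test_that("window counts reproduce, dilute, or thin the signal by length", {
  mo <- small_multiome(seed = 10)
  win <- simulate_window_counts(mo, c(2000, 1000, 500, 250), seed = 3)
  expect_identical(win[["500"]]$counts, mo$atac$counts)
  expect_true(all(win[["1000"]]$counts >= mo$atac$counts))
  expect_true(all(win[["250"]]$counts <= mo$atac$counts))
  # deterministic given the seed
  win2 <- simulate_window_counts(mo, c(2000, 1000, 500, 250), seed = 3)
  expect_identical(win[["2000"]]$counts, win2[["2000"]]$counts)
})

test_that("uniform SNP scenario matches the coverage-fraction expectation", {
  genome <- c(chr1 = 1e6, chr2 = 1e6)
  hits <- vapply(1:200, function(s) {
    sc <- generate_snp_scenario(n_snps = 200, n_peaks = 100,
                                genome = genome, enrichment_fold = 1,
                                peak_width = 1000, seed = s)
    ct <- sc$truth$enriched_celltype
    c(count_snp_overlaps(sc$snps, sc$peak_sets[[ct]])$O,
      sc$truth$coverage)
  }, numeric(2))
  # E[O] = n_snps * coverage; aggregate over 200 scenarios
  expected <- 200 * mean(hits[2, ])
  observed <- mean(hits[1, ])
  se <- sd(hits[1, ]) / sqrt(ncol(hits))
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("extreme enrichment folds drive nearly all SNPs into target peaks", {
  sc <- generate_snp_scenario(n_snps = 300, enrichment_fold = 1e6, seed = 2)
  O <- count_snp_overlaps(sc$snps,
                          sc$peak_sets[[sc$truth$enriched_celltype]])$O
  expect_gt(O / 300, 0.99)
  sc2 <- generate_snp_scenario(seed = 5, enrichment_fold = 5)
  sc3 <- generate_snp_scenario(seed = 5, enrichment_fold = 5)
  expect_identical(as.data.frame(sc2$snps), as.data.frame(sc3$snps))
  expect_error(generate_snp_scenario(n_peaks = 0), "at least one bp")
})

test_that("ABC scenario plants top-ranked links and validates ids", {
  sc <- generate_abc_scenario(seed = 11)
  el <- abc_condition_elements(sc, "disease")
  A <- stats::setNames(element_activity(el$atac, el$k27ac), el$element_id)
  # the rank-1 planted element carries its gene's maximal activity*contact
  for (g in unique(sc$truth$gene_id)) {
    rows <- sc$contacts[sc$contacts$gene_id == g, ]
    prods <- A[rows$element_id] *
      (rows$contact / max(rows$contact))
    top <- sc$truth$element_id[sc$truth$gene_id == g &
                                 sc$truth$true_score_rank == 1]
    expect_equal(unname(rows$element_id[which.max(prods)]), top)
  }
  expect_error(generate_abc_scenario(
    planted_links = data.frame(element_id = "nope", gene_id = "gene001"),
    seed = 1), "unknown element")
  s1 <- generate_abc_scenario(seed = 3)
  s2 <- generate_abc_scenario(seed = 3)
  expect_identical(s1$activities, s2$activities)
})
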