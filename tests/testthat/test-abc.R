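test_that("element activity is the geometric mean with absorbing zero", {
  expect_equal(element_activity(4, 9), 6)
  expect_equal(element_activity(0, 123), 0)
  x <- runif(20, 0, 50)
  expect_equal(element_activity(x, x), x)
  expect_error(element_activity(-1, 4), "non-negative")
})

test_that("contact frequency uses table rows and distance fallback", {
  # fallback boundary cases
  expect_equal(contact_frequency(10000, 5000), 1)        # d = d0
  expect_equal(contact_frequency(15000, 5000), 0.5)      # d = 2 d0
  expect_equal(contact_frequency(3000, 3000), 1)         # element at TSS
  expect_equal(contact_frequency(4000, 3000), 1)         # d < d0 capped
  # monotone non-increasing in distance
  d <- seq(0, 1e6, by = 5e4)
  C <- contact_frequency(d, 0)
  expect_true(all(diff(C) <= 0))
  # table lookup normalised by the gene row maximum
  tab <- data.frame(element_id = c("e1", "e2"), gene_id = c("g", "g"),
                    contact = c(50, 200))
  C2 <- contact_frequency(c(1e6, 2e6), 0, element_id = c("e1", "e2"),
                          gene_id = c("g", "g"), contact_table = tab)
  expect_equal(C2, c(0.25, 1))
})

test_that("ABC scores normalise to one and match direct summation", {
  set.seed(50)
  for (i in 1:20) {
    n <- 20
    gt <- gene_table("g", "chr1", "+", 5e5, genome = c(chr1 = 1e6))
    start <- sort(sample.int(9e5, n))
    el <- data.frame(element_id = sprintf("e%02d", 1:n), chrom = "chr1",
                     start = start, end = start + 200,
                     atac = rlnorm(n), k27ac = rlnorm(n))
    links <- abc_scores(gt, el)
    expect_equal(sum(links$score), 1, tolerance = 1e-9)
    # independent direct recomputation
    A <- sqrt(el$atac * el$k27ac)
    d <- abs((el$start + el$end) / 2 - 5e5)
    C <- pmin(1, 5000 / d); C[d == 0] <- 1
    S <- (A * C) / sum(A * C)
    expect_equal(links$score[match(el$element_id, links$element_id)], S,
                 tolerance = 1e-12)
  }
})

test_that("single, symmetric, and all-zero candidate sets behave as defined", {
  gt <- gene_table("g", "chr1", "+", 1000, genome = c(chr1 = 1e6))
  one <- data.frame(element_id = "e1", chrom = "chr1", start = 5000,
                    end = 5200, atac = 4, k27ac = 4)
  l1 <- abc_scores(gt, one)
  expect_equal(l1$score, 1)
  expect_true(l1$retained)
  two <- rbind(one, data.frame(element_id = "e2", chrom = "chr1",
                               start = 8000, end = 8200, atac = 4,
                               k27ac = 4))
  # equalise contact via a table so both candidates tie
  tab <- data.frame(element_id = c("e1", "e2"), gene_id = "g",
                    contact = c(7, 7))
  l2 <- abc_scores(gt, two, contact_table = tab)
  expect_equal(l2$score, c(0.5, 0.5))
  zero <- transform(two, atac = 0, k27ac = 0)
  l0 <- abc_scores(gt, zero, contact_table = tab)
  expect_true(all(is.na(l0$score)))
  expect_false(any(l0$retained))
  # empty candidate set: nothing within the window
  l_none <- abc_scores(gt, two, window_bp = 1000)
  expect_equal(nrow(l_none), 0L)
})

test_that("score increases with own activity, all else fixed", {
  gt <- gene_table("g", "chr1", "+", 5e5, genome = c(chr1 = 1e6))
  set.seed(51)
  start <- sort(sample.int(9e5, 10))
  el <- data.frame(element_id = sprintf("e%02d", 1:10), chrom = "chr1",
                   start = start, end = start + 200,
                   atac = rlnorm(10), k27ac = rlnorm(10))
  s0 <- abc_scores(gt, el)
  el2 <- el; el2$atac[4] <- el2$atac[4] * 2
  s1 <- abc_scores(gt, el2)
  expect_gt(s1$score[s1$element_id == "e04"],
            s0$score[s0$element_id == "e04"])
})

test_that("link histogram counts genes at n = 0 and rescales invariantly", {
  links <- data.frame(
    gene_id = c("g1", "g2", "g2", "g3"),
    retained = c(FALSE, TRUE, FALSE, TRUE),
    condition = "ctrl")
  h <- count_links_per_gene(links, gene_ids = c("g1", "g2", "g3", "g4"))
  expect_equal(h$n_genes[h$n_links == 0], 2) # g1 and absent g4
  expect_equal(h$n_genes[h$n_links == 1], 2)

  sc <- generate_abc_scenario(seed = 14)
  el <- abc_condition_elements(sc, "disease")
  l1 <- abc_scores(sc$genes, el, contact_table = sc$contacts)
  el10 <- transform(el, atac = atac * 10, k27ac = k27ac * 10)
  l10 <- abc_scores(sc$genes, el10, contact_table = sc$contacts)
  l1$condition <- l10$condition <- "disease"
  expect_identical(count_links_per_gene(l1, sc$genes$gene_id),
                   count_links_per_gene(l10, sc$genes$gene_id))
})

test_that("planted links are retained and shift genes to more links in disease", {
  sc <- generate_abc_scenario(seed = 23)
  ld <- abc_scores(sc$genes, abc_condition_elements(sc, "disease"),
                   contact_table = sc$contacts)
  lc <- abc_scores(sc$genes, abc_condition_elements(sc, "ctrl"),
                   contact_table = sc$contacts)
  planted <- merge(sc$truth, ld, by = c("element_id", "gene_id"))
  expect_true(all(planted$retained))
  pg <- unique(sc$truth$gene_id)
  nd <- tapply(ld$retained, ld$gene_id, sum)[pg]
  nc <- tapply(lc$retained, lc$gene_id, sum)[pg]
  expect_gt(mean(nd), mean(nc))
})
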