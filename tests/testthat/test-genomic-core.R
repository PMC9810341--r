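test_that("BED parsing follows the 0-based half-open contract", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10\tp1"), tmp)
  ps <- read_bed(tmp)
  expect_equal(ps$chrom, "chr1")
  expect_equal(ps$start, 0)
  expect_equal(ps$end, 10)
  expect_equal(ps$name, "p1")

  writeLines(c("chr1\t10\t10"), tmp)
  expect_error(read_bed(tmp), "end.*<=.*start|line 1")

  writeLines(c("chr2\t5\t9", "chr1\t7\t20", "chr1\t0\t3"), tmp)
  ps <- read_bed(tmp)
  expect_equal(ps$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(ps$start, c(0, 7, 5))

  writeLines(c("chr1\t0"), tmp)
  expect_error(read_bed(tmp), "line 1")
  writeLines(c("chr1\tzero\t10"), tmp)
  expect_error(read_bed(tmp), "line 1")
})

test_that("BED round-trip reproduces sorted coordinates byte-identically", {
  set.seed(11)
  ps <- random_peaks(40)
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(ps, f1)
  write_bed(read_bed(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("peak_set enforces its invariants", {
  expect_error(peak_set("chr1", 5, 5), "end must exceed start")
  expect_error(peak_set("chr1", -1, 5), "start must be >= 0")
  expect_error(peak_set("chr1", 0, 200, genome = c(chr1 = 100)),
               "exceeds chromosome length")
  expect_error(peak_set("chrX", 0, 10, genome = c(chr1 = 100)),
               "absent from genome")
  # duplicates retained, not dropped
  ps <- peak_set(c("c", "c"), c(1, 1), c(5, 5))
  expect_equal(nrow(ps), 2L)
})

test_that("promoter derivation mirrors strand and clips at boundaries", {
  gt <- gene_table(c("gp", "gm", "gt"), c("chr1", "chr1", "chr1"),
                   c("+", "-", "+"), c(1000, 1000, 200),
                   genome = c(chr1 = 2000))
  pr <- derive_promoters(gt, 500)
  d <- as.data.frame(pr)
  expect_equal(d[d$name == "gp", c("start", "end")],
               data.frame(start = 500, end = 1000),
               ignore_attr = TRUE)
  expect_equal(d[d$name == "gm", c("start", "end")],
               data.frame(start = 1001, end = 1501),
               ignore_attr = TRUE)
  expect_equal(d[d$name == "gt", c("start", "end")],
               data.frame(start = 0, end = 200),
               ignore_attr = TRUE)
  expect_identical(attr(pr, "truncated"), pr$name == "gt")
  # minus-strand window clipped at the chromosome end
  gt2 <- gene_table("ge", "chr1", "-", 1800, genome = c(chr1 = 2000))
  d2 <- as.data.frame(derive_promoters(gt2, 500))
  expect_equal(d2$end, 2000)
})

test_that("intersect_pairs equals the quadratic brute-force oracle", {
  set.seed(7)
  for (rep in 1:4) {
    a <- random_peaks(50 * rep)
    b <- random_peaks(30 * rep)
    got <- intersect_pairs(a, b)
    exp <- brute_force_pairs(a, b)
    expect_equal(got[c("a_index", "b_index", "overlap_bp")], exp,
                 ignore_attr = TRUE)
    # symmetry of overlap widths
    rev <- intersect_pairs(b, a)
    expect_equal(sort(rev$overlap_bp), sort(got$overlap_bp))
  }
  # half-open: touching intervals do not overlap
  expect_equal(nrow(intersect_pairs(peak_set("c", 0, 10),
                                    peak_set("c", 10, 20))), 0L)
  expect_equal(intersect_pairs(peak_set("c", 0, 10),
                               peak_set("c", 5, 15))$overlap_bp, 5)
  expect_equal(nrow(intersect_pairs(peak_set(character(), numeric(),
                                             numeric()),
                                    random_peaks(5))), 0L)
})

test_that("merge_regions merges strict overlaps but not bookends", {
  ps <- peak_set(rep("c", 3), c(0, 5, 20), c(10, 15, 30))
  m <- as.data.frame(merge_regions(ps))
  expect_equal(m$start, c(0, 20))
  expect_equal(m$end, c(15, 30))
  bk <- merge_regions(peak_set(c("c", "c"), c(0, 10), c(10, 20)))
  expect_equal(nrow(bk), 2L)
})

test_that("shuffling preserves widths and is seed-deterministic", {
  set.seed(3)
  ps <- random_peaks(60)
  s1 <- shuffle_regions(ps, seed = 5)
  s2 <- shuffle_regions(ps, seed = 5)
  s3 <- shuffle_regions(ps, seed = 6)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_false(identical(as.data.frame(s1), as.data.frame(s3)))
  expect_equal(sort(widths(s1)), sort(widths(ps)))
  # within-chromosome: per-chromosome width multisets preserved
  for (cn in unique(ps$chrom))
    expect_equal(sort(widths(s1)[s1$chrom == cn]),
                 sort(widths(ps)[ps$chrom == cn]))
  expect_error(shuffle_regions(peak_set("c", 0, 50, genome = c(c = 100)),
                               seed = 1, genome = c(c = 20)),
               "wider than")
})

test_that("shuffle placement is uniform over valid starts", {
  ps <- peak_set("c", 0, 100, genome = c(c = 1000))
  starts <- vapply(1:10000, function(b)
    shuffle_regions(ps, seed = b)$start, 0)
  # uniform over {0..900}: mean 450, sd 900/sqrt(12)
  se <- (900 / sqrt(12)) / sqrt(length(starts))
  expect_lt(abs(mean(starts) - 450), 3 * se)
  expect_true(all(starts >= 0 & starts <= 900))
})

test_that("cross-chromosome shuffling weights chromosomes by valid placements", {
  ps <- peak_set(rep("a", 400), rep(0, 400), rep(10, 400),
                 genome = c(a = 1000, b = 3000))
  sh <- shuffle_regions(ps, seed = 9, within_chrom = FALSE)
  # valid starts: 991 vs 2991 -> P(b) ~ 0.751
  p_b <- mean(sh$chrom == "b")
  se <- sqrt(0.751 * 0.249 / 400)
  expect_lt(abs(p_b - 0.751), 4 * se)
})

test_that("genome and count-matrix file formats round-trip", {
  gf <- withr::local_tempfile()
  writeLines(c("chr1\t1000", "chr2\t500"), gf)
  expect_equal(read_genome(gf), c(chr1 = 1000, chr2 = 500))

  m <- matrix(c(0, 5, 10, 2), 2, 2,
              dimnames = list(c("r1", "r2"), c("s1", "s2")))
  rc <- region_counts(m, lengths = c(r1 = 100, r2 = 400), totals = c(50, 60))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(rc, tf, header = "demo")
  rc2 <- read_counts_tsv(tf, totals = c(50, 60))
  expect_equal(rc2$counts, rc$counts)
  expect_equal(rc2$lengths, rc$lengths)

  # MTX triplet with sidecar labels
  mf <- withr::local_tempfile(fileext = ".mtx")
  rf <- withr::local_tempfile(); sf <- withr::local_tempfile()
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), mf)
  writeLines(rownames(m), rf); writeLines(colnames(m), sf)
  rc3 <- read_counts_mtx(mf, rf, sf, lengths = c(r1 = 100, r2 = 400),
                         totals = c(50, 60))
  expect_equal(rc3$counts, rc$counts)
})

test_that("region_counts rejects invariant violations", {
  m <- matrix(c(10, 5), 1, 2, dimnames = list("r", c("a", "b")))
  expect_error(region_counts(m, 100, totals = c(5, 5)),
               "exceed library totals")
  expect_error(region_counts(m, 0), "lengths must be > 0")
  expect_error(region_counts(m - 20, 100), "non-negative")
  expect_error(region_counts(matrix(1.5, 1, 1,
                                    dimnames = list("r", "s")), 100),
               "integers")
})

test_that("SNP coordinate base must be declared and converts correctly", {
  expect_error(snps_from_positions("c", 10), "declare the coordinate base")
  s0 <- snps_from_positions("c", 10, base = 0)
  s1 <- snps_from_positions("c", 10, base = 1)
  expect_equal(s0$start, 10)
  expect_equal(s1$start, 9)
  expect_equal(widths(s0), 1)
})
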