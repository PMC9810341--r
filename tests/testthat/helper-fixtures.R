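# Shared fixture builders and independent oracles used across test files.

# Random interval set on a small genome.
random_peaks <- function(n, genome = c(chrA = 10000, chrB = 5000),
                         max_width = 300) {
  chrom <- sample(names(genome), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  start <- floor(runif(n) * (genome[chrom] - w))
  peak_set(chrom, start, start + w,
           name = sprintf("r%03d", seq_len(n)), genome = genome)
}

# Quadratic all-pairs overlap oracle (half-open semantics).
brute_force_pairs <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= 1)
      out[[length(out) + 1L]] <- data.frame(a_index = i, b_index = j,
                                            overlap_bp = ov)
  }
  if (!length(out))
    return(data.frame(a_index = integer(), b_index = integer(),
                      overlap_bp = numeric()))
  d <- do.call(rbind, out)
  d[order(d$a_index, d$b_index), ]
}

# Literal step-up BH oracle: q_(i) = min_{j >= i} (n/j) p_(j), capped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n))
    q_sorted[i] <- min(1, min((n / (i:n)) * p[o][i:n]))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Exact two-sided binomial oracle by explicit outcome enumeration.
exact_test_oracle <- function(c_a, N_a, c_b, N_b) {
  n <- c_a + c_b
  if (n == 0) return(1)
  p0 <- N_a / (N_a + N_b)
  d_obs <- dbinom(c_a, n, p0)
  total <- 0
  for (k in 0:n) {
    dk <- dbinom(k, n, p0)
    if (dk <= d_obs * (1 + 1e-7)) total <- total + dk
  }
  min(1, total)
}

# Small multiome for fast end-to-end tests.
small_multiome <- function(seed = 1, ...) {
  generate_multiome(synth_config(
    n_genes = 200,
    genes_per_type = c(Type1a = 15, Type1b = 15, Type2a = 15,
                       Type2b = 15, Type3 = 15, Type4 = 15),
    seed = seed, ...))
}

run_typing_differential <- function(mo, ...) {
  de <- differential_counts(mo$expression, mo$groups, "disease", "ctrl", ...)
  da <- differential_counts(mo$atac, mo$groups, "disease", "ctrl", ...)
  list(expr = de, ca = da,
       baseline = stats::setNames(da$A_den, da$feature))
}
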