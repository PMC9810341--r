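#' Pseudocount log2 fold change
#'
#' `M = log2((a + pseudocount) / (b + pseudocount))` on aligned feature
#' vectors (typically RPKM activity columns, numerator = disease/treated).
#'
#' @param a,b Named numeric vectors of non-negative activities with
#'   identical feature keys.
#' @param pseudocount Positive stabiliser added to both sides (default 1
#'   on the RPKM scale).
#' @return Named numeric vector of log2 fold changes.
#' @export
pseudocount_lfc <- function(a, b, pseudocount = 1) {
  stop_if_not_scalar_number(pseudocount, "pseudocount", positive = TRUE)
  if (!is.null(names(a)) || !is.null(names(b))) {
    if (is.null(names(a)) || is.null(names(b)) ||
        !identical(names(a), names(b)))
      stop("feature keys of 'a' and 'b' are misaligned", call. = FALSE)
  } else if (length(a) != length(b)) {
    stop("'a' and 'b' differ in length", call. = FALSE)
  }
  log2((a + pseudocount) / (b + pseudocount))
}

# Core of the exact two-sided binomial test. Two-sided p sums the
# probabilities of all outcomes no more likely than the observed one; the
# (1 + 1e-7) relative tolerance guards floating-point ties at symmetric
# null proportions.
exact_binom_p <- function(k, n, p0) {
  if (n == 0) return(1)
  ld <- stats::dbinom(0:n, n, p0, log = TRUE)
  keep <- ld <= ld[k + 1L] + log1p(1e-7)
  m <- max(ld[keep])
  p <- min(1, exp(m + log(sum(exp(ld[keep] - m)))))
  # extreme outcomes underflow double precision; keep p in (0, 1]
  max(p, .Machine$double.xmin)
}

#' Exact two-sided count test for two pooled libraries
#'
#' Conditions on the total `c_a + c_b` and tests `c_a` against
#' `Binomial(c_a + c_b, N_a / (N_a + N_b))`; the two-sided p-value sums
#' the probabilities of all outcomes whose probability does not exceed the
#' observed outcome's. A feature with `c_a + c_b = 0` is untestable and
#' returns p = 1 (flagged via the `untestable` attribute).
#'
#' @param c_a,c_b Non-negative integer counts (vectors allowed).
#' @param N_a,N_b Positive library totals.
#' @return Numeric vector of p-values in `(0, 1]` with an `untestable`
#'   logical attribute.
#' @examples
#' exact_count_test(10, 1e6, 0, 1e6)  # 2 * (1/2)^10
#' @export
exact_count_test <- function(c_a, N_a, c_b, N_b) {
  stop_if_not_scalar_number(N_a, "N_a", positive = TRUE)
  stop_if_not_scalar_number(N_b, "N_b", positive = TRUE)
  if (length(c_a) != length(c_b))
    stop("count vectors differ in length", call. = FALSE)
  if (any(c_a < 0) || any(c_b < 0) || any(c_a != round(c_a)) ||
      any(c_b != round(c_b)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(c_a > N_a) || any(c_b > N_b))
    stop("counts cannot exceed library totals", call. = FALSE)
  p0 <- N_a / (N_a + N_b)
  n <- c_a + c_b
  p <- vapply(seq_along(c_a), function(i)
    exact_binom_p(c_a[i], n[i], p0), 0)
  structure(p, untestable = n == 0)
}

#' Z-score enrichment p-values for a fold-change vector
#'
#' Standardises M against the all-features distribution,
#' `z = (M - mean(M)) / sd(M)`, and converts to two-sided normal
#' p-values `p = 2 * pnorm(-abs(z))`.
#'
#' @param M Numeric vector of log2 fold changes (>= 3 finite values with
#'   nonzero spread).
#' @return A list with components `z` and `p` (named as `M`).
#' @export
zscore_enrichment <- function(M) {
  if (sum(is.finite(M)) < 3L)
    stop("need at least 3 finite fold changes", call. = FALSE)
  s <- stats::sd(M[is.finite(M)])
  if (!is.finite(s) || s == 0)
    stop("sd(M) is zero: no enrichment signal to standardise against",
         call. = FALSE)
  z <- (M - mean(M[is.finite(M)])) / s
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR control: `q_(i) = min_{j >= i} (n * p_(j) / j)`, capped at
#' 1, returned in input order.
#'
#' @param p Numeric vector of raw p-values in `(0, 1]`.
#' @return Numeric vector of adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Differential test on pooled pseudobulk counts
#'
#' Sums counts within each condition, computes the pseudocount log2 fold
#' change on the RPKM scale (numerator vs denominator), an exact binomial
#' p-value per feature (or a seeded label-permutation p-value), and BH
#' adjustment.
#'
#' @param x A `region_counts` whose columns are replicate samples.
#' @param groups Character vector assigning each column to a condition.
#' @param numerator,denominator Condition labels; `numerator` is the
#'   disease/treated side of the fold change.
#' @param pseudocount Pseudocount on the RPKM scale (default 1).
#' @param alpha Adjusted-p cutoff used only to set the `direction` column.
#' @param method `"exact"` (default) or `"permutation"` (label
#'   permutation of replicate columns; requires `n_perm` and `seed`).
#' @param n_perm Number of permutations for `method = "permutation"`.
#' @param seed Seed for the permutation draw.
#' @return A `differential_result`: data.frame with columns `feature`,
#'   `M`, `p`, `q`, `direction`, `untestable`, plus per-condition pooled
#'   activity columns `A_num` and `A_den`.
#' @export
differential_counts <- function(x, groups, numerator, denominator,
                                pseudocount = 1, alpha = 0.05,
                                method = c("exact", "permutation"),
                                n_perm = 1000, seed = 1) {
  stopifnot(inherits(x, "region_counts"))
  method <- match.arg(method)
  if (length(groups) != ncol(x$counts))
    stop("'groups' must label every sample column", call. = FALSE)
  for (g in c(numerator, denominator))
    if (!g %in% groups)
      stop("condition label not present in groups: ", g, call. = FALSE)
  ia <- groups == numerator; ib <- groups == denominator
  c_a <- rowSums(x$counts[, ia, drop = FALSE])
  c_b <- rowSums(x$counts[, ib, drop = FALSE])
  N_a <- sum(x$totals[ia]); N_b <- sum(x$totals[ib])
  A_a <- c_a / ((x$lengths / 1000) * (N_a / 1e6))
  A_b <- c_b / ((x$lengths / 1000) * (N_b / 1e6))
  M <- pseudocount_lfc(A_a, A_b, pseudocount)
  if (method == "exact") {
    p <- exact_count_test(c_a, N_a, c_b, N_b)
    untestable <- attr(p, "untestable")
  } else {
    obs <- abs(M)
    hits <- integer(length(M))
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        perm <- sample(seq_along(groups))
        pa <- perm[ia]; pb <- perm[ib]
        ca <- rowSums(x$counts[, pa, drop = FALSE])
        cb <- rowSums(x$counts[, pb, drop = FALSE])
        Na <- sum(x$totals[pa]); Nb <- sum(x$totals[pb])
        Mb <- pseudocount_lfc(ca / ((x$lengths / 1000) * (Na / 1e6)),
                              cb / ((x$lengths / 1000) * (Nb / 1e6)),
                              pseudocount)
        hits <- hits + (abs(Mb) >= obs)
      }
    })
    p <- (1 + hits) / (n_perm + 1)
    untestable <- (c_a + c_b) == 0
  }
  q <- bh_adjust(as.numeric(p))
  direction <- ifelse(q < alpha & M > 0, "up",
                      ifelse(q < alpha & M < 0, "down", "unchanged"))
  structure(data.frame(feature = rownames(x$counts), M = M,
                       p = as.numeric(p), q = q, direction = direction,
                       untestable = untestable,
                       A_num = A_a, A_den = A_b,
                       row.names = NULL, stringsAsFactors = FALSE),
            alpha = alpha, class = c("differential_result", "data.frame"))
}

#' Promoter-mark enrichment between two conditions
#'
#' The z-score route used for histone-mark comparisons at promoters:
#' pseudocount log2 fold change of the two activity columns, z-scores
#' against the all-promoter distribution, two-sided normal p-values, BH.
#'
#' @param a,b Aligned named activity vectors (treated, control).
#' @param pseudocount Pseudocount for the fold change.
#' @param alpha Adjusted-p cutoff for the `direction` column.
#' @return A `differential_result` with an extra `z` column.
#' @export
mark_enrichment <- function(a, b, pseudocount = 1, alpha = 0.05) {
  M <- pseudocount_lfc(a, b, pseudocount)
  zp <- zscore_enrichment(M)
  q <- bh_adjust(zp$p)
  direction <- ifelse(q < alpha & M > 0, "up",
                      ifelse(q < alpha & M < 0, "down", "unchanged"))
  structure(data.frame(feature = if (is.null(names(a)))
                         as.character(seq_along(a)) else names(a),
                       M = unname(M), z = unname(zp$z), p = unname(zp$p),
                       q = q, direction = direction,
                       untestable = FALSE,
                       row.names = NULL, stringsAsFactors = FALSE),
            alpha = alpha, class = c("differential_result", "data.frame"))
}

#' @export
print.differential_result <- function(x, ...) {
  alpha <- attr(x, "alpha")
  cat(sprintf("differential_result: %d feature(s); %d up, %d down at q < %g\n",
              nrow(x), sum(x$direction == "up"), sum(x$direction == "down"),
              alpha))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat(sprintf("  ... and %d more\n", nrow(x) - 10L))
  invisible(x)
}
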