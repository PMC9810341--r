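#' RPKM activity scores for regions
#'
#' Normalises counts by region length and library size:
#' `A[r, g] = counts[r, g] / ((L_r / 1000) * (N_g / 1e6))`, i.e. reads per
#' kilobase of region per million mapped reads. A score is zero exactly
#' when its count is zero, and the matrix is invariant under joint
#' rescaling of all counts and totals by the same constant.
#'
#' @param x A `region_counts`.
#' @return An `activity_matrix`: a numeric matrix of scores with `lengths`
#'   and `totals` attributes carried along.
#' @examples
#' rc <- region_counts(matrix(100, 1, 1, dimnames = list("p", "s")),
#'                     lengths = 500, totals = 1e6)
#' score_regions(rc)  # 200 RPKM
#' @export
score_regions <- function(x) {
  stopifnot(inherits(x, "region_counts"))
  if (any(x$lengths <= 0)) stop("zero-length region", call. = FALSE)
  A <- sweep(x$counts, 1, x$lengths / 1000, "/")
  A <- sweep(A, 2, x$totals / 1e6, "/")
  structure(A, lengths = x$lengths, totals = x$totals,
            class = c("activity_matrix", class(A)))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks). Constant
#' input has no defined rank correlation and yields `NA` with a warning
#' rather than a number.
#'
#' @param x,y Numeric vectors of equal length (>= 3 after removing pairs
#'   with missing values).
#' @return Spearman's rho in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: rank correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Select a promoter length by accessibility-expression correlation
#'
#' For each candidate promoter length, the gene-wise promoter
#' accessibility score is correlated (Spearman) with the matched gene
#' expression score within every pseudobulk group. The selected length
#' maximises the mean rho across groups; ties resolve to the smallest
#' length.
#'
#' @param atac_by_length Named list (names = candidate lengths in bp) of
#'   `region_counts` with gene-id rownames: promoter accessibility counted
#'   over each candidate window.
#' @param expression An `activity_matrix` (or `region_counts`, scored
#'   internally) of gene expression with the same group columns.
#' @return A `length_selection` object: data.frame of (length, group, rho)
#'   plus `selected` and `mean_rho` attributes.
#' @export
select_promoter_length <- function(atac_by_length, expression) {
  if (is.null(names(atac_by_length)) ||
      anyNA(suppressWarnings(as.numeric(names(atac_by_length)))))
    stop("atac_by_length must be named by candidate length in bp",
         call. = FALSE)
  if (inherits(expression, "region_counts"))
    expression <- score_regions(expression)
  lens <- as.numeric(names(atac_by_length))
  rows <- list()
  for (i in seq_along(atac_by_length)) {
    A <- score_regions(atac_by_length[[i]])
    common <- intersect(rownames(A), rownames(expression))
    groups <- intersect(colnames(A), colnames(expression))
    if (!length(groups))
      stop("no shared pseudobulk groups between ATAC and expression",
           call. = FALSE)
    for (g in groups) {
      a <- A[common, g]; e <- expression[common, g]
      keep <- is.finite(a) & is.finite(e)
      if (sum(keep) < 3L)
        stop(sprintf(
          "fewer than 3 genes with complete values in group '%s'", g),
          call. = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(length = lens[i], group = g,
                   rho = rank_correlation(a, e))
    }
  }
  report <- do.call(rbind, rows)
  mean_rho <- tapply(report$rho, report$length, mean)
  best <- max(mean_rho, na.rm = TRUE)
  cand <- as.numeric(names(mean_rho))[mean_rho >= best - 1e-12]
  structure(report, selected = min(cand),
            mean_rho = stats::setNames(as.numeric(mean_rho),
                                       names(mean_rho)),
            class = c("length_selection", "data.frame"))
}

#' @export
print.length_selection <- function(x, ...) {
  mr <- attr(x, "mean_rho")
  cat("Promoter-length selection (Spearman rho, mean over groups):\n")
  for (l in names(mr)) cat(sprintf("  %6s bp: rho = %.4f\n", l, mr[[l]]))
  cat(sprintf("selected: %g bp\n", attr(x, "selected")))
  invisible(x)
}

#' Mean activity of region sets
#'
#' Scores every region (RPKM) and averages within each named set; an empty
#' set yields `NA`, never zero.
#'
#' @param sets Named list of character vectors of region ids.
#' @param x A `region_counts` covering those regions.
#' @return Matrix of mean activity, sets x groups.
#' @export
aggregate_set_signal <- function(sets, x) {
  stopifnot(inherits(x, "region_counts"))
  if (is.null(names(sets))) stop("sets must be named", call. = FALSE)
  A <- score_regions(x)
  out <- matrix(NA_real_, length(sets), ncol(A),
                dimnames = list(names(sets), colnames(A)))
  for (s in names(sets)) {
    ids <- intersect(sets[[s]], rownames(A))
    if (length(ids))
      out[s, ] <- colMeans(A[ids, , drop = FALSE])
  }
  out
}
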