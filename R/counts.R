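#' Region-by-sample count matrices
#'
#' A `region_counts` object couples a non-negative integer count matrix
#' (regions x samples) with per-region lengths in bp and per-sample library
#' totals N. It is the input to all activity scoring.
#'
#' @param counts Numeric matrix of non-negative counts with rownames
#'   (region or gene ids) and colnames (sample/group labels).
#' @param lengths Numeric vector of region lengths in bp (recycled if
#'   scalar), or named and matched to rownames.
#' @param totals Per-sample total mapped reads; `"observed"` uses column
#'   sums. Must satisfy `counts[r, s] <= totals[s]` and `totals[s] > 0`.
#' @return An object of class `region_counts`.
#' @export
region_counts <- function(counts, lengths, totals = "observed") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have rownames (regions) and colnames (samples)",
         call. = FALSE)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative", call. = FALSE)
  if (any(counts != round(counts)))
    stop("counts must be integers", call. = FALSE)
  if (length(lengths) == 1L) lengths <- rep(lengths, nrow(counts))
  if (!is.null(names(lengths))) {
    if (!all(rownames(counts) %in% names(lengths)))
      stop("lengths missing for some regions", call. = FALSE)
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts))
    stop("lengths must match the number of regions", call. = FALSE)
  if (any(lengths <= 0)) stop("region lengths must be > 0", call. = FALSE)
  if (identical(totals, "observed")) totals <- colSums(counts)
  if (length(totals) == 1L) totals <- rep(totals, ncol(counts))
  if (length(totals) != ncol(counts))
    stop("totals must match the number of samples", call. = FALSE)
  totals <- stats::setNames(as.numeric(totals), colnames(counts))
  if (any(totals <= 0)) stop("library totals must be > 0", call. = FALSE)
  if (any(sweep(counts, 2, totals) > 0))
    stop("counts cannot exceed library totals", call. = FALSE)
  structure(list(counts = counts,
                 lengths = stats::setNames(as.numeric(lengths),
                                           rownames(counts)),
                 totals = totals),
            class = "region_counts")
}

#' @export
print.region_counts <- function(x, ...) {
  cat(sprintf("region_counts: %d region(s) x %d sample(s)\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  samples:", paste(colnames(x$counts), collapse = ", "), "\n")
  cat(sprintf("  library totals: %s\n",
              paste(format(x$totals, big.mark = ","), collapse = ", ")))
  invisible(x)
}

#' @export
dim.region_counts <- function(x) dim(x$counts)

#' Read a count matrix TSV
#'
#' Tab-separated with header; first column `region_id`, remaining columns
#' one per sample. Region lengths come from a `length` column if present,
#' otherwise from the `lengths` argument.
#'
#' @param path Path to the TSV.
#' @param lengths Region lengths in bp (scalar, vector, or named), used
#'   when the file has no `length` column.
#' @param totals Library totals, or `"observed"` for column sums.
#' @return A `region_counts`.
#' @export
read_counts_tsv <- function(path, lengths = NULL, totals = "observed") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (names(df)[1L] != "region_id")
    stop("first column must be 'region_id'", call. = FALSE)
  if ("length" %in% names(df)) {
    lengths <- stats::setNames(df$length, df$region_id)
    df$length <- NULL
  }
  if (is.null(lengths))
    stop("region lengths required (no 'length' column in file)", call. = FALSE)
  m <- as.matrix(df[-1L])
  rownames(m) <- df$region_id
  region_counts(m, lengths, totals)
}

#' Write a count matrix TSV
#'
#' @param x A `region_counts`.
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed metadata lines.
#' @return Invisibly, `path`.
#' @export
write_counts_tsv <- function(x, path, header = NULL) {
  stopifnot(inherits(x, "region_counts"))
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("region_id", "length", colnames(x$counts)),
                   collapse = "\t"), con)
  body <- cbind(rownames(x$counts), format(x$lengths, trim = TRUE,
                                           scientific = FALSE),
                apply(x$counts, 2, format, trim = TRUE, scientific = FALSE))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a MatrixMarket triplet count matrix with label sidecars
#'
#' @param mtx_path Path to the MTX triplet file.
#' @param regions_path Text file, one region id per line (rows).
#' @param samples_path Text file, one sample label per line (columns).
#' @param lengths Region lengths in bp.
#' @param totals Library totals, or `"observed"`.
#' @return A `region_counts`.
#' @export
read_counts_mtx <- function(mtx_path, regions_path, samples_path,
                            lengths, totals = "observed") {
  m <- as.matrix(Matrix::readMM(mtx_path))
  rn <- readLines(regions_path); cn <- readLines(samples_path)
  if (nrow(m) != length(rn) || ncol(m) != length(cn))
    stop("sidecar label files do not match matrix dimensions", call. = FALSE)
  rownames(m) <- rn; colnames(m) <- cn
  region_counts(m, lengths, totals)
}
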