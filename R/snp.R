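#' Count SNPs overlapping open-chromatin peaks
#'
#' SNPs are 1-bp intervals `[pos, pos + 1)`; a SNP at a peak's start
#' overlaps, a SNP at its (exclusive) end does not. The observed statistic
#' O counts distinct SNPs with at least one overlapping peak; with
#' `count = "pairs"` it counts SNP-peak pairs instead.
#'
#' @param snps `peak_set` of 1-bp intervals.
#' @param peaks `peak_set` of peaks.
#' @param count `"distinct"` (default) or `"pairs"`.
#' @return List with `O` (the count) and `hits` (the SNP-peak pair table
#'   from [intersect_pairs()]).
#' @export
count_snp_overlaps <- function(snps, peaks, count = c("distinct", "pairs")) {
  stopifnot(inherits(snps, "peak_set"), inherits(peaks, "peak_set"))
  count <- match.arg(count)
  if (nrow(snps) && any(widths(snps) != 1))
    stop("snps must be 1-bp intervals [pos, pos+1)", call. = FALSE)
  hits <- intersect_pairs(snps, peaks)
  O <- if (count == "distinct") length(unique(hits$a_index)) else nrow(hits)
  list(O = O, hits = hits)
}

# Fast point-in-union counter. pos_by_chrom: named list of SNP positions;
# starts/ends: parallel vectors of peak coordinates; chrom: their
# chromosomes. Counts distinct SNPs falling in the union of peaks.
count_points_in_union <- function(pos_by_chrom, chrom, starts, ends) {
  total <- 0L
  for (cn in names(pos_by_chrom)) {
    i <- chrom == cn
    if (!any(i)) next
    s <- starts[i]; e <- ends[i]
    o <- order(s, e)
    s <- s[o]; e <- e[o]
    cme <- cummax(e)
    n <- length(s)
    grp <- cumsum(c(TRUE, s[-1L] > cme[-n]))
    us <- s[!duplicated(grp)]
    ue <- cme[c(which(!duplicated(grp))[-1L] - 1L, n)]
    idx <- findInterval(pos_by_chrom[[cn]], as.numeric(rbind(us, ue)))
    total <- total + sum(idx %% 2L == 1L)
  }
  total
}

#' SNP-in-peaks enrichment against a shuffle null
#'
#' Computes the observed number of distinct SNPs overlapping the peak set,
#' then builds an empirical null by shuffling the peaks B times
#' (width-preserving, uniform within each chromosome) and recounting. The
#' expected count E is the mean over shuffles, fold is O/E, and the
#' empirical p-value uses the add-one estimator
#' `(1 + #\{null >= O\}) / (B + 1)`.
#'
#' @param snps `peak_set` of 1-bp SNP intervals.
#' @param peaks `peak_set` of peaks.
#' @param genome Named chromosome-length vector (defaults to the peaks'
#'   genome attribute); must cover every peak chromosome.
#' @param B Number of shuffles (>= 1).
#' @param seed Integer seed.
#' @param set Label for the peak set.
#' @return One-row data.frame: `set`, `O`, `E`, `fold`, `p`, `B`,
#'   `n_snps`, plus a `null` attribute holding the null counts.
#' @export
enrichment_test <- function(snps, peaks, genome = NULL, B = 199, seed = 1,
                            set = "peaks") {
  stopifnot(inherits(snps, "peak_set"), inherits(peaks, "peak_set"))
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  genome <- validate_genome(if (is.null(genome)) attr(peaks, "genome")
                            else genome)
  if (is.null(genome)) stop("genome lengths required", call. = FALSE)
  missing_chr <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_chr))
    stop("genome missing chromosome(s): ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  obs <- count_snp_overlaps(snps, peaks)$O
  pos_by_chrom <- split(snps$start, snps$chrom)
  w <- widths(peaks)
  nvalid <- genome[peaks$chrom] - w + 1
  if (any(nvalid < 1))
    stop("peak wider than its chromosome", call. = FALSE)
  null_counts <- integer(B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      start <- floor(stats::runif(nrow(peaks)) * nvalid)
      null_counts[b] <- count_points_in_union(pos_by_chrom, peaks$chrom,
                                              start, start + w)
    }
  })
  E <- mean(null_counts)
  structure(data.frame(set = set, O = obs, E = E,
                       fold = if (E > 0) obs / E else NA_real_,
                       p = (1 + sum(null_counts >= obs)) / (B + 1),
                       B = B, n_snps = nrow(snps),
                       stringsAsFactors = FALSE),
            null = null_counts)
}

#' Enrichment across several peak sets with BH correction
#'
#' Runs [enrichment_test()] for every peak set (deterministic per-set
#' seeds derived from the global one) and adjusts the empirical p-values
#' across sets with Benjamini-Hochberg.
#'
#' @param snps `peak_set` of 1-bp SNP intervals.
#' @param peak_sets Named list of `peak_set` objects.
#' @param genome Named chromosome-length vector.
#' @param B Shuffles per set.
#' @param seed Global seed.
#' @return An `enrichment_result` data.frame (set, O, E, fold, p, q, B,
#'   n_snps), sorted by q then p.
#' @export
multi_set_report <- function(snps, peak_sets, genome = NULL, B = 199,
                             seed = 1) {
  if (!length(peak_sets) || is.null(names(peak_sets)))
    stop("peak_sets must be a non-empty named list", call. = FALSE)
  rows <- lapply(seq_along(peak_sets), function(i)
    enrichment_test(snps, peak_sets[[i]], genome = genome, B = B,
                    seed = stage_seed(seed, i * 1000L),
                    set = names(peak_sets)[i]))
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out$q <- bh_adjust(out$p)
  out <- out[order(out$q, out$p, out$set), ]
  rownames(out) <- NULL
  structure(out[c("set", "O", "E", "fold", "p", "q", "B", "n_snps")],
            class = c("enrichment_result", "data.frame"))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result over %d peak set(s), B = %d shuffle(s)\n",
              nrow(x), x$B[1L]))
  print.data.frame(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Convert SNP coordinates to internal 0-based 1-bp intervals
#'
#' Callers must declare whether the incoming positions are 0- or 1-based;
#' there is no default, because variant tables ship in both conventions.
#'
#' @param chrom Chromosome names.
#' @param pos Positions.
#' @param base Declared coordinate base: 0 or 1.
#' @param name Optional SNP identifiers.
#' @param genome Optional chromosome lengths.
#' @return `peak_set` of 1-bp intervals.
#' @export
snps_from_positions <- function(chrom, pos, base, name = NULL,
                                genome = NULL) {
  if (missing(base) || !base %in% c(0, 1))
    stop("declare the coordinate base of SNP positions: 0 or 1",
         call. = FALSE)
  start <- as.numeric(pos) - base
  peak_set(chrom, start, start + 1, name = name, genome = genome)
}
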