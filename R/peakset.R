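#' Genomic interval sets
#'
#' A `peak_set` stores genomic intervals in the BED convention: 0-based,
#' half-open `[start, end)`. Intervals are kept sorted by
#' (chromosome lexicographic, start, end); duplicate intervals are retained
#' but flagged. An optional genome (named vector of chromosome lengths in
#' bp) enables bounds checking and shuffling.
#'
#' @param chrom Character vector of chromosome names (opaque strings; no
#'   "chr" normalisation is attempted).
#' @param start,end Integer vectors, 0-based half-open; `end > start >= 0`.
#' @param name Optional character vector of interval names.
#' @param strand Optional character vector in `+`, `-`, `.`.
#' @param genome Optional named numeric vector mapping chromosome to length
#'   (bp); when supplied every interval must lie within its chromosome.
#' @return An object of class `peak_set`: a data.frame with columns
#'   `chrom`, `start`, `end`, `name`, `strand` plus a `genome` attribute.
#' @examples
#' ps <- peak_set(c("chr1", "chr1"), c(0, 100), c(50, 200))
#' ps
#' @export
peak_set <- function(chrom, start, end, name = NULL, strand = NULL,
                     genome = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  n <- length(start)
  if (length(chrom) == 1L && n > 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(end) != n)
    stop("chrom, start and end must have equal length", call. = FALSE)
  if (n > 0L) {
    if (any(!is.finite(start)) || any(!is.finite(end)))
      stop("non-finite coordinates", call. = FALSE)
    if (any(start < 0)) stop("start must be >= 0", call. = FALSE)
    bad <- which(end <= start)
    if (length(bad))
      stop(sprintf("end must exceed start (interval %d: %s:%g-%g)",
                   bad[1L], chrom[bad[1L]], start[bad[1L]], end[bad[1L]]),
           call. = FALSE)
  }
  if (is.null(name)) name <- rep(NA_character_, n)
  if (is.null(strand)) strand <- rep(".", n)
  strand[is.na(strand)] <- "."
  if (n > 0L && !all(strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = as.character(name), strand = strand,
                   stringsAsFactors = FALSE)
  ord <- order(df$chrom, df$start, df$end, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(genome)) {
    genome <- validate_genome(genome)
    unknown <- setdiff(unique(df$chrom), names(genome))
    if (length(unknown))
      stop("chromosome(s) absent from genome: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    over <- df$end > genome[df$chrom]
    if (any(over))
      stop(sprintf("interval %s:%g-%g exceeds chromosome length %g",
                   df$chrom[over][1L], df$start[over][1L], df$end[over][1L],
                   unname(genome[df$chrom[over][1L]])), call. = FALSE)
  }
  structure(df, genome = genome,
            class = c("peak_set", "data.frame"))
}

validate_genome <- function(genome) {
  if (is.null(names(genome)) || any(names(genome) == "") ||
      anyDuplicated(names(genome)))
    stop("genome must be a named vector with unique chromosome names",
         call. = FALSE)
  genome <- stats::setNames(as.numeric(genome), names(genome))
  if (any(!is.finite(genome)) || any(genome <= 0))
    stop("chromosome lengths must be positive", call. = FALSE)
  genome
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set with %d interval(s) on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (ndup <- sum(duplicated(x[c("chrom", "start", "end")])))
    cat(sprintf("  (%d duplicate interval(s) retained)\n", ndup))
  if (!is.null(attr(x, "genome")))
    cat(sprintf("  genome: %d chromosome(s), %.0f bp total\n",
                length(attr(x, "genome")), sum(attr(x, "genome"))))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Interval widths of a peak set
#' @param x A `peak_set`.
#' @return Numeric vector of widths in bp.
#' @export
widths <- function(x) {
  stopifnot(inherits(x, "peak_set"))
  x$end - x$start
}

#' Read a BED file into a peak_set
#'
#' Accepts BED3/BED4/BED6 (tab-separated, no header). Coordinates are
#' loaded verbatim as 0-based half-open.
#'
#' @param path Path to a BED file.
#' @param genome Optional named vector of chromosome lengths for bounds
#'   checking.
#' @return A `peak_set`, sorted by (chrom, start, end).
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(peak_set(character(), numeric(), numeric(), genome = genome))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("malformed BED line %d: fewer than 3 tab-separated fields",
                 which(nf < 3L)[1L]), call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop(sprintf("malformed BED line %d: coordinates do not parse as integers",
                 which(is.na(start) | is.na(end))[1L]), call. = FALSE)
  bad <- which(end <= start)
  if (length(bad))
    stop(sprintf("invalid interval at line %d: end (%g) <= start (%g)",
                 bad[1L], end[bad[1L]], start[bad[1L]]), call. = FALSE)
  name <- ifelse(nf >= 4L, vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else NA_character_, ""), NA_character_)
  strand <- ifelse(nf >= 6L, vapply(fields, function(f)
    if (length(f) >= 6L) f[[6L]] else ".", ""), ".")
  peak_set(chrom, start, end, name = name, strand = strand, genome = genome)
}

#' Write a peak_set as BED
#'
#' Emits BED3 when no interval is named, BED4 when names are present but no
#' strand, BED6 when any strand is set. Round-trips coordinates exactly.
#'
#' @param x A `peak_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "peak_set"))
  has_name <- any(!is.na(x$name))
  has_strand <- any(x$strand != ".")
  nm <- ifelse(is.na(x$name), ".", x$name)
  lines <- if (has_strand) {
    sprintf("%s\t%.0f\t%.0f\t%s\t0\t%s", x$chrom, x$start, x$end, nm, x$strand)
  } else if (has_name) {
    sprintf("%s\t%.0f\t%.0f\t%s", x$chrom, x$start, x$end, nm)
  } else {
    sprintf("%s\t%.0f\t%.0f", x$chrom, x$start, x$end)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome file (chromosome sizes)
#'
#' Two-column TSV: chromosome name, length in bp.
#'
#' @param path Path to the genome file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_genome <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  validate_genome(stats::setNames(df$length, df$chrom))
}

#' Merge overlapping intervals into non-overlapping meta intervals
#'
#' Strictly overlapping intervals (shared bp under half-open semantics) are
#' merged; bookended intervals (`end == start`) are NOT merged.
#'
#' @param x A `peak_set`.
#' @return A `peak_set` of disjoint intervals.
#' @export
merge_regions <- function(x) {
  stopifnot(inherits(x, "peak_set"))
  if (!nrow(x)) return(x)
  out <- lapply(split(x[c("start", "end")], x$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    s <- d$start; e <- d$end
    ks <- s[1L]; ke <- e[1L]; rs <- numeric(0); re <- numeric(0)
    for (i in seq_along(s)[-1L]) {
      if (s[i] < ke) ke <- max(ke, e[i])
      else { rs <- c(rs, ks); re <- c(re, ke); ks <- s[i]; ke <- e[i] }
    }
    data.frame(start = c(rs, ks), end = c(re, ke))
  })
  chrom <- rep(names(out), vapply(out, nrow, 0L))
  d <- do.call(rbind, out)
  peak_set(chrom, d$start, d$end, genome = attr(x, "genome"))
}

# Convert a peak_set to GRanges (1-based closed) for overlap machinery.
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end))
}

#' Report all overlapping interval pairs between two peak sets
#'
#' Every pair with at least 1 bp of shared sequence under half-open
#' semantics is reported exactly once; intervals touching end-to-start do
#' not overlap.
#'
#' @param a,b `peak_set` objects on the same coordinate system.
#' @return A data.frame with one row per overlapping pair: `a_index`,
#'   `b_index` (row indices into the sorted inputs), `a_name`, `b_name`,
#'   and `overlap_bp`.
#' @export
intersect_pairs <- function(a, b) {
  stopifnot(inherits(a, "peak_set"), inherits(b, "peak_set"))
  empty <- data.frame(a_index = integer(), b_index = integer(),
                      a_name = character(), b_name = character(),
                      overlap_bp = numeric())
  if (!nrow(a) || !nrow(b)) return(empty)
  hits <- GenomicRanges::findOverlaps(as_granges0(a), as_granges0(b),
                                      minoverlap = 1L)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (!length(qi)) return(empty)
  ov <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
  ord <- order(qi, si)
  data.frame(a_index = qi[ord], b_index = si[ord],
             a_name = a$name[qi][ord], b_name = b$name[si][ord],
             overlap_bp = ov[ord])
}

#' Shuffle intervals to random positions, preserving widths
#'
#' Each interval is repositioned uniformly over its valid start positions.
#' With `within_chrom = TRUE` the chromosome label is preserved; otherwise
#' the target chromosome is drawn with probability proportional to the
#' number of valid placements it offers for that width. Deterministic for
#' a fixed seed.
#'
#' @param x A `peak_set` with a genome attribute (or supply `genome`).
#' @param seed Integer seed.
#' @param within_chrom Keep each interval on its own chromosome?
#' @param genome Optional named chromosome-length vector overriding the
#'   set's own genome.
#' @return A `peak_set` of equal size with identical widths.
#' @export
shuffle_regions <- function(x, seed, within_chrom = TRUE, genome = NULL) {
  stopifnot(inherits(x, "peak_set"))
  genome <- validate_genome(if (is.null(genome)) attr(x, "genome") else genome)
  if (is.null(genome)) stop("genome lengths required to shuffle", call. = FALSE)
  if (!nrow(x)) return(x)
  w <- widths(x)
  if (any(w > max(genome)))
    stop("interval wider than every chromosome", call. = FALSE)
  with_seed(seed, {
    if (within_chrom) {
      unknown <- setdiff(unique(x$chrom), names(genome))
      if (length(unknown))
        stop("genome missing chromosome(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      nvalid <- genome[x$chrom] - w + 1
      if (any(nvalid < 1))
        stop("interval wider than its chromosome", call. = FALSE)
      start <- floor(stats::runif(nrow(x)) * nvalid)
      peak_set(x$chrom, start, start + w, name = x$name, genome = genome)
    } else {
      # per interval, chromosome probability proportional to valid starts
      chrom <- character(nrow(x)); start <- numeric(nrow(x))
      for (i in seq_len(nrow(x))) {
        nvalid <- pmax(genome - w[i] + 1, 0)
        if (sum(nvalid) == 0)
          stop("interval wider than every chromosome", call. = FALSE)
        ci <- sample.int(length(genome), 1L, prob = nvalid)
        chrom[i] <- names(genome)[ci]
        start[i] <- floor(stats::runif(1L) * nvalid[ci])
      }
      peak_set(chrom, start, start + w, name = x$name, genome = genome)
    }
  })
}
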