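#' Gene annotation tables
#'
#' A `gene_table` records, per gene, its chromosome, strand, and the
#' 0-based coordinate of the transcription start base (TSS).
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chrom Character vector of chromosome names.
#' @param strand Character vector in `+` / `-`.
#' @param tss Non-negative integer vector, 0-based TSS positions.
#' @param genome Optional named chromosome-length vector; when supplied,
#'   every TSS must lie within its chromosome.
#' @return A data.frame of class `gene_table`.
#' @export
gene_table <- function(gene_id, chrom, strand, tss, genome = NULL) {
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) stop("gene_id must be unique", call. = FALSE)
  if (length(chrom) != n || length(strand) != n || length(tss) != n)
    stop("all columns must have equal length", call. = FALSE)
  if (n > 0L && !all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  tss <- as.numeric(tss)
  if (any(tss < 0) || any(!is.finite(tss)))
    stop("tss must be non-negative and finite", call. = FALSE)
  if (!is.null(genome)) {
    genome <- validate_genome(genome)
    unknown <- setdiff(unique(chrom), names(genome))
    if (length(unknown))
      stop("gene(s) on chromosome(s) absent from genome: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (any(tss >= genome[chrom]))
      stop("tss beyond chromosome end", call. = FALSE)
  }
  structure(data.frame(gene_id = as.character(gene_id),
                       chrom = as.character(chrom),
                       strand = strand, tss = tss,
                       stringsAsFactors = FALSE),
            genome = genome, class = c("gene_table", "data.frame"))
}

#' Read a gene annotation TSV
#'
#' Four tab-separated columns with header: `gene_id`, `chrom`, `strand`,
#' `tss` (0-based TSS coordinate).
#'
#' @param path Path to the TSV file.
#' @param genome Optional chromosome-length vector for bounds checking.
#' @return A `gene_table`.
#' @export
read_gene_table <- function(path, genome = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(df)))
    stop("gene table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  gene_table(df$gene_id, df$chrom, df$strand, df$tss, genome = genome)
}

#' Derive promoter windows upstream of each TSS
#'
#' For a `+` strand gene the promoter is `[max(0, tss - length_bp), tss)`;
#' for a `-` strand gene it is the mirrored window downstream in genome
#' space, `[tss + 1, tss + 1 + length_bp)`, clipped to the chromosome end
#' when a genome is available. Windows truncated by a chromosome boundary
#' are flagged in the `truncated` attribute.
#'
#' @param genes A `gene_table`.
#' @param length_bp Promoter length in bp (> 0).
#' @return A `peak_set` with one interval per gene, named by `gene_id`,
#'   carrying a logical `truncated` attribute aligned with its rows.
#' @examples
#' gt <- gene_table("g1", "chr1", "+", 1000)
#' derive_promoters(gt, 500)   # chr1:[500,1000)
#' @export
derive_promoters <- function(genes, length_bp) {
  stopifnot(inherits(genes, "gene_table"))
  stop_if_not_scalar_number(length_bp, "length_bp", positive = TRUE)
  genome <- attr(genes, "genome")
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0, genes$tss - length_bp), genes$tss + 1)
  end <- ifelse(plus, genes$tss, genes$tss + 1 + length_bp)
  if (!is.null(genome)) {
    unknown <- setdiff(unique(genes$chrom), names(genome))
    if (length(unknown))
      stop("gene(s) on unknown chromosome(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    end <- pmin(end, genome[genes$chrom])
  }
  if (any(end <= start))
    stop("promoter window collapsed to zero width (TSS at chromosome edge)",
         call. = FALSE)
  truncated <- (end - start) < length_bp
  ps <- peak_set(genes$chrom, start, end, name = genes$gene_id,
                 strand = genes$strand, genome = genome)
  # peak_set sorts; realign the flag with the sorted rows
  attr(ps, "truncated") <- truncated[match(ps$name, genes$gene_id)]
  ps
}
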