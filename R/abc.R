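#' Enhancer element activity
#'
#' Geometric mean of ATAC and H3K27ac signal (both RPKM-scale,
#' non-negative): `A = sqrt(atac * k27ac)`.
#'
#' @param atac,k27ac Non-negative numeric vectors.
#' @return Numeric vector of activities.
#' @export
element_activity <- function(atac, k27ac) {
  if (any(atac < 0) || any(k27ac < 0))
    stop("activities must be non-negative", call. = FALSE)
  sqrt(atac * k27ac)
}

#' Element-promoter contact frequency
#'
#' For pairs covered by a contact table the raw value is normalised to
#' (0, 1] by the maximum over that gene's table entries; otherwise a
#' power-law distance fallback `C = min(1, (d0 / d)^gamma)` is used with
#' `d` the element midpoint-to-TSS distance (an element at the TSS has
#' `C = 1`).
#'
#' @param element_mid Element midpoint positions (bp).
#' @param gene_tss Matched TSS positions (bp).
#' @param element_id,gene_id Matched identifier vectors (required when a
#'   contact table is supplied).
#' @param contact_table Optional data.frame with `element_id`, `gene_id`,
#'   `contact` (raw positive values).
#' @param d0 Reference distance (bp) at which the fallback reaches 1.
#' @param gamma Power-law exponent (> 0).
#' @return Numeric vector of contact frequencies in (0, 1].
#' @export
contact_frequency <- function(element_mid, gene_tss, element_id = NULL,
                              gene_id = NULL, contact_table = NULL,
                              d0 = 5000, gamma = 1) {
  stop_if_not_scalar_number(d0, "d0", positive = TRUE)
  stop_if_not_scalar_number(gamma, "gamma", positive = TRUE)
  d <- abs(element_mid - gene_tss)
  C <- ifelse(d == 0, 1, pmin(1, (d0 / d)^gamma))
  if (!is.null(contact_table) && nrow(contact_table)) {
    if (is.null(element_id) || is.null(gene_id))
      stop("element_id and gene_id required with a contact table",
           call. = FALSE)
    if (any(contact_table$contact <= 0))
      stop("raw contacts must be positive", call. = FALSE)
    rowmax <- tapply(contact_table$contact, contact_table$gene_id, max)
    key <- paste(contact_table$element_id, contact_table$gene_id, sep = "\r")
    val <- contact_table$contact / rowmax[contact_table$gene_id]
    hit <- match(paste(element_id, gene_id, sep = "\r"), key)
    C[!is.na(hit)] <- val[hit[!is.na(hit)]]
  }
  unname(C)
}

#' Activity-by-contact enhancer-gene scores
#'
#' For each gene, candidate elements within the window around the TSS are
#' scored `S = A * C / sum(A * C)` over the candidates, so scores for a
#' gene sum to 1; links with `S > cutoff` are retained. When every
#' candidate product is zero the scores are undefined (`NA`) and nothing
#' is retained.
#'
#' @param genes A `gene_table`.
#' @param elements Data.frame with `element_id`, `chrom`, `start`, `end`,
#'   `atac`, `k27ac` (activities on the RPKM scale).
#' @param contact_table Optional raw contact table (see
#'   [contact_frequency()]).
#' @param window_bp Candidate window span centred on the TSS (default
#'   5 Mb; elements within `window_bp / 2` of the TSS compete).
#' @param cutoff Retention cutoff on S (default 0.05).
#' @param d0,gamma Fallback contact parameters.
#' @return An `abc_links` data.frame: `element_id`, `gene_id`, `activity`,
#'   `contact`, `score`, `retained`.
#' @export
abc_scores <- function(genes, elements, contact_table = NULL,
                       window_bp = 5e6, cutoff = 0.05,
                       d0 = 5000, gamma = 1) {
  stopifnot(inherits(genes, "gene_table"))
  need <- c("element_id", "chrom", "start", "end", "atac", "k27ac")
  if (!all(need %in% names(elements)))
    stop("elements must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  stop_if_not_scalar_number(window_bp, "window_bp", positive = TRUE)
  A <- element_activity(elements$atac, elements$k27ac)
  mid <- (elements$start + elements$end) / 2
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    cand <- which(elements$chrom == genes$chrom[i] &
                    abs(mid - genes$tss[i]) <= window_bp / 2)
    if (!length(cand)) next
    C <- contact_frequency(mid[cand], genes$tss[i],
                           element_id = elements$element_id[cand],
                           gene_id = rep(genes$gene_id[i], length(cand)),
                           contact_table = contact_table,
                           d0 = d0, gamma = gamma)
    prod <- A[cand] * C
    tot <- sum(prod)
    S <- if (tot > 0) prod / tot else rep(NA_real_, length(cand))
    out[[i]] <- data.frame(element_id = elements$element_id[cand],
                           gene_id = genes$gene_id[i],
                           activity = A[cand], contact = C, score = S,
                           retained = !is.na(S) & S > cutoff,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(element_id = character(), gene_id = character(),
                      activity = numeric(), contact = numeric(),
                      score = numeric(), retained = logical(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, cutoff = cutoff,
            class = c("abc_links", "data.frame"))
}

#' Assemble the element table for one condition of an ABC scenario
#'
#' Joins element coordinates with that condition's ATAC/H3K27ac
#' activities, in the layout [abc_scores()] expects.
#'
#' @param scenario Output of [generate_abc_scenario()].
#' @param condition `"ctrl"` or `"disease"`.
#' @return Data.frame with `element_id`, `chrom`, `start`, `end`, `atac`,
#'   `k27ac`.
#' @export
abc_condition_elements <- function(scenario, condition) {
  a <- scenario$activities[scenario$activities$condition == condition, ]
  if (!nrow(a)) stop("unknown condition: ", condition, call. = FALSE)
  i <- match(scenario$elements$name, a$element_id)
  data.frame(element_id = scenario$elements$name,
             chrom = scenario$elements$chrom,
             start = scenario$elements$start,
             end = scenario$elements$end,
             atac = a$atac[i], k27ac = a$k27ac[i],
             stringsAsFactors = FALSE)
}

#' Histogram of retained links per gene
#'
#' Counts, for each condition, how many genes carry n retained links;
#' genes with no retained links are included at n = 0.
#'
#' @param links A data.frame of links with `gene_id`, `retained`, and a
#'   `condition` column (e.g. row-bound condition-specific [abc_scores()]
#'   outputs).
#' @param gene_ids Gene universe; genes absent from `links` count at
#'   n = 0.
#' @return Data.frame: `condition`, `n_links`, `n_genes`.
#' @export
count_links_per_gene <- function(links, gene_ids) {
  if (!"condition" %in% names(links))
    stop("links must carry a 'condition' column", call. = FALSE)
  conds <- unique(links$condition)
  out <- do.call(rbind, lapply(conds, function(cn) {
    d <- links[links$condition == cn, ]
    per_gene <- tapply(d$retained, d$gene_id, sum)
    n <- stats::setNames(rep(0L, length(gene_ids)), gene_ids)
    n[names(per_gene)] <- as.integer(per_gene)
    tab <- table(n)
    data.frame(condition = cn, n_links = as.integer(names(tab)),
               n_genes = as.integer(tab), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
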