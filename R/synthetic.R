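#' Configuration for the synthetic multi-ome generator
#'
#' Defines the study conditions emulated by [generate_multiome()]: a
#' control and a disease condition, negative-binomial pseudobulk counts
#' for expression and promoter accessibility, and planted gene classes
#' matching the priming-type definitions used by [classify_genes()].
#'
#' Type-level generating means (per replicate): low and high baselines are
#' `baseline_low_mu` and `baseline_high_mu`; the intermediate level is
#' their geometric mean. Type1a: expression and accessibility both low in
#' control, both multiplied by their fold change in disease. Type1b: as
#' Type1a but accessibility starts at the intermediate level. Type2a:
#' expression induced, accessibility high and unchanged. Type2b:
#' expression induced, accessibility low and unchanged. Type3: expression
#' reduced, accessibility unchanged (intermediate). Type4: expression
#' reduced and accessibility reduced (intermediate to intermediate/fold).
#' Null genes share a lognormal baseline between expression and
#' accessibility (with lognormal jitter), planting a cross-gene
#' accessibility-expression correlation, and are unchanged across
#' conditions.
#'
#' @param n_genes Total genes (planted types + null remainder).
#' @param genes_per_type Named integer vector over
#'   `Type1a, Type1b, Type2a, Type2b, Type3, Type4`.
#' @param n_celltypes Number of cell types (each gets its own pseudobulk
#'   columns with the same planted structure).
#' @param n_replicates Pseudo-replicates per condition.
#' @param fold_change_expr,fold_change_ca Multiplicative disease effects
#'   (>= 1; exactly 1 degenerates every gene to null).
#' @param baseline_low_mu,baseline_high_mu Expected counts per replicate
#'   for lowly/highly active features.
#' @param nb_dispersion Negative-binomial size parameter.
#' @param library_size Nominal per-sample total mapped reads.
#' @param promoter_length_true Width (bp) of the window that actually
#'   carries the accessibility signal.
#' @param expr_length Effective transcript length (bp) used for
#'   expression RPKM.
#' @param bg_rate_per_bp Median background accessibility rate (reads per
#'   bp per replicate) scattered beyond the true promoter window;
#'   per-gene rates are lognormal around this median.
#' @param null_mu_meanlog,null_mu_sdlog Lognormal parameters for null-gene
#'   baselines.
#' @param null_ca_jitter_sdlog Lognormal jitter decoupling null-gene
#'   accessibility from expression.
#' @param totals_mode `"nominal"` (library_size per sample) or
#'   `"observed"` (column sums).
#' @param seed Integer seed.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 2000,
                         genes_per_type = c(Type1a = 100, Type1b = 100,
                                            Type2a = 100, Type2b = 100,
                                            Type3 = 100, Type4 = 100),
                         n_celltypes = 1,
                         n_replicates = 2,
                         fold_change_expr = 4,
                         fold_change_ca = 4,
                         baseline_low_mu = 20,
                         baseline_high_mu = 2000,
                         nb_dispersion = 10,
                         library_size = 1e6,
                         promoter_length_true = 500,
                         expr_length = 1000,
                         bg_rate_per_bp = 0.5,
                         null_mu_meanlog = log(200),
                         null_mu_sdlog = 1,
                         null_ca_jitter_sdlog = 0.5,
                         totals_mode = c("nominal", "observed"),
                         seed = 1) {
  cfg <- list(n_genes = n_genes, genes_per_type = genes_per_type,
              n_celltypes = n_celltypes, n_replicates = n_replicates,
              conditions = c("ctrl", "disease"),
              fold_change_expr = fold_change_expr,
              fold_change_ca = fold_change_ca,
              baseline_low_mu = baseline_low_mu,
              baseline_high_mu = baseline_high_mu,
              nb_dispersion = nb_dispersion,
              library_size = library_size,
              promoter_length_true = promoter_length_true,
              expr_length = expr_length,
              bg_rate_per_bp = bg_rate_per_bp,
              null_mu_meanlog = null_mu_meanlog,
              null_mu_sdlog = null_mu_sdlog,
              null_ca_jitter_sdlog = null_ca_jitter_sdlog,
              totals_mode = match.arg(totals_mode),
              seed = seed)
  type_names <- c("Type1a", "Type1b", "Type2a", "Type2b", "Type3", "Type4")
  if (!all(names(cfg$genes_per_type) %in% type_names))
    stop("genes_per_type names must be among: ",
         paste(type_names, collapse = ", "), call. = FALSE)
  if (sum(cfg$genes_per_type) > cfg$n_genes)
    stop("sum(genes_per_type) exceeds n_genes", call. = FALSE)
  if (cfg$fold_change_expr < 1 || cfg$fold_change_ca < 1)
    stop("fold changes must be >= 1", call. = FALSE)
  for (f in c("n_genes", "n_celltypes", "n_replicates", "baseline_low_mu",
              "baseline_high_mu", "nb_dispersion", "library_size",
              "promoter_length_true", "expr_length", "bg_rate_per_bp"))
    stop_if_not_scalar_number(cfg[[f]], f, positive = TRUE)
  if (cfg$baseline_low_mu >= cfg$baseline_high_mu)
    stop("baseline_low_mu must be below baseline_high_mu", call. = FALSE)
  structure(cfg, class = "synth_config")
}

# Per-gene generating means for both assays and conditions.
type_means <- function(cfg) {
  low <- cfg$baseline_low_mu; high <- cfg$baseline_high_mu
  mid <- sqrt(low * high)
  fe <- cfg$fold_change_expr; fa <- cfg$fold_change_ca
  counts <- cfg$genes_per_type
  planted <- rep(names(counts), counts)
  n_null <- cfg$n_genes - length(planted)
  true_type <- c(planted, rep("null", n_null))
  gene_id <- sprintf("g%04d", seq_len(cfg$n_genes))
  m <- data.frame(gene_id = gene_id, true_type = true_type,
                  expr_ctrl = NA_real_, expr_dis = NA_real_,
                  ca_ctrl = NA_real_, ca_dis = NA_real_,
                  stringsAsFactors = FALSE)
  set_type <- function(m, type, ec, ed, ac, ad) {
    i <- m$true_type == type
    m$expr_ctrl[i] <- ec; m$expr_dis[i] <- ed
    m$ca_ctrl[i] <- ac; m$ca_dis[i] <- ad
    m
  }
  m <- set_type(m, "Type1a", low, low * fe, low, low * fa)
  m <- set_type(m, "Type1b", low, low * fe, mid, mid * fa)
  m <- set_type(m, "Type2a", low, low * fe, high, high)
  m <- set_type(m, "Type2b", low, low * fe, low, low)
  m <- set_type(m, "Type3", low * fe, low, mid, mid)
  m <- set_type(m, "Type4", low * fe, low, mid, mid / fa)
  # null genes: shared lognormal baseline with accessibility jitter,
  # filled in under the generator's RNG (generate_multiome)
  m
}

#' Generate a synthetic pseudobulk multi-ome with planted gene classes
#'
#' Draws negative-binomial expression and promoter-accessibility counts
#' for `n_celltypes` cell types under control and disease conditions, with
#' generating means determined by each gene's planted priming type (see
#' [synth_config()]). The accessibility signal sits entirely inside the
#' true promoter window; [simulate_window_counts()] adds per-gene
#' background beyond it so that widening the window dilutes the
#' accessibility-expression correlation. Deterministic for a fixed seed.
#' When both fold changes equal 1 every gene's means are unchanged and
#' the truth table reports all genes as null.
#'
#' @param cfg A `synth_config`.
#' @return A list of class `synthetic_multiome` with components
#'   `expression` and `atac` (`region_counts`), `genes` (`gene_table`),
#'   `truth` (data.frame: gene_id, true_type), `means` (per-gene
#'   generating means), `groups` (condition label per sample column),
#'   `bg_rate` (per-gene background rates), and `config`.
#' @export
generate_multiome <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  m <- type_means(cfg)
  with_seed(cfg$seed, {
    i_null <- m$true_type == "null"
    base <- stats::rlnorm(sum(i_null), cfg$null_mu_meanlog, cfg$null_mu_sdlog)
    jit <- stats::rlnorm(sum(i_null), 0, cfg$null_ca_jitter_sdlog)
    m$expr_ctrl[i_null] <- base; m$expr_dis[i_null] <- base
    m$ca_ctrl[i_null] <- base * jit; m$ca_dis[i_null] <- base * jit
    if (cfg$fold_change_expr == 1 && cfg$fold_change_ca == 1)
      m$true_type <- "null"
    n <- cfg$n_genes
    # annotation: genes spaced along one chromosome, alternating strand,
    # TSS far enough from the edge that no candidate window truncates
    spacing <- 10000
    tss <- 10000 + (seq_len(n) - 1) * spacing
    genome <- c(chr1 = max(tss) + 20000)
    genes <- gene_table(m$gene_id, rep("chr1", n),
                        rep(c("+", "-"), length.out = n), tss,
                        genome = genome)
    grid <- expand.grid(r = seq_len(cfg$n_replicates),
                        cond = cfg$conditions,
                        ct = seq_len(cfg$n_celltypes),
                        stringsAsFactors = FALSE)
    samples <- sprintf("ct%d_%s_r%d", grid$ct, grid$cond, grid$r)
    cond_of <- grid$cond
    draw <- function(mu_ctrl, mu_dis) {
      out <- matrix(0, n, length(samples),
                    dimnames = list(m$gene_id, samples))
      for (j in seq_along(samples)) {
        mu <- if (cond_of[j] == "disease") mu_dis else mu_ctrl
        out[, j] <- stats::rnbinom(n, size = cfg$nb_dispersion, mu = mu)
      }
      out
    }
    expr_counts <- draw(m$expr_ctrl, m$expr_dis)
    atac_counts <- draw(m$ca_ctrl, m$ca_dis)
    bg_rate <- stats::rlnorm(n, log(cfg$bg_rate_per_bp), 1)
    names(bg_rate) <- m$gene_id
    totals <- if (cfg$totals_mode == "nominal")
      rep(cfg$library_size, length(samples))
    else "observed"
    promoters <- derive_promoters(genes, cfg$promoter_length_true)
    plen <- stats::setNames(widths(promoters), promoters$name)[m$gene_id]
    structure(list(
      expression = region_counts(expr_counts, cfg$expr_length, totals),
      atac = region_counts(atac_counts, plen, totals),
      genes = genes,
      truth = m[c("gene_id", "true_type")],
      means = m,
      groups = cond_of,
      samples = samples,
      bg_rate = bg_rate,
      config = cfg), class = "synthetic_multiome")
  })
}

#' @export
print.synthetic_multiome <- function(x, ...) {
  cat(sprintf("synthetic_multiome: %d gene(s), %d sample(s) (%s)\n",
              nrow(x$expression$counts), length(x$samples),
              paste(x$samples, collapse = ", ")))
  print(table(x$truth$true_type))
  invisible(x)
}

#' Promoter accessibility counts for candidate window lengths
#'
#' Rebuilds the accessibility count matrix as it would look when counted
#' over windows of each candidate length. Windows at the true signal
#' length reproduce the generated counts; longer windows add per-gene
#' Poisson background (rate `bg_rate` per extra bp), shorter windows thin
#' the signal binomially by the width ratio (signal reads uniform within
#' the true window).
#'
#' @param mo A `synthetic_multiome`.
#' @param lengths_bp Candidate window lengths in bp.
#' @param seed Seed for the background/thinning draws.
#' @return Named list of `region_counts`, one per candidate length, ready
#'   for [select_promoter_length()].
#' @export
simulate_window_counts <- function(mo, lengths_bp = c(2000, 1000, 500),
                                   seed = mo$config$seed + 1) {
  stopifnot(inherits(mo, "synthetic_multiome"))
  true_len <- mo$config$promoter_length_true
  counts <- mo$atac$counts
  n <- nrow(counts); k <- ncol(counts)
  with_seed(seed, {
    out <- lapply(lengths_bp, function(L) {
      cm <- if (L == true_len) {
        counts
      } else if (L > true_len) {
        extra <- matrix(stats::rpois(n * k, mo$bg_rate * (L - true_len)),
                        n, k)
        counts + extra
      } else {
        matrix(stats::rbinom(n * k, as.vector(counts), L / true_len),
               n, k)
      }
      dimnames(cm) <- dimnames(counts)
      region_counts(cm, L, mo$atac$totals)
    })
    names(out) <- as.character(lengths_bp)
    out
  })
}

#' Analytic differential evidence from generating means
#'
#' Applies the pipeline's fold-change definition to the generator's
#' noise-free means (pooled over replicates, RPKM-normalised), with
#' p = q = 1 for genes whose means are equal across conditions and an
#' arbitrarily small p otherwise. Feeding the result to
#' [classify_genes()] must reproduce the planted labels exactly.
#'
#' @param mo A `synthetic_multiome`.
#' @param pseudocount Pseudocount matching the downstream analysis.
#' @return List with `expr` and `ca` (`differential_result`) and
#'   `baseline` (named control accessibility activity vector).
#' @export
analytic_evidence <- function(mo, pseudocount = 1) {
  stopifnot(inherits(mo, "synthetic_multiome"))
  cfg <- mo$config
  nrep <- sum(mo$groups == "ctrl") # per condition, all cell types pooled
  N <- unname(mo$expression$totals[1]) * nrep
  mk <- function(mu_ctrl, mu_dis, L) {
    A_c <- (mu_ctrl * nrep) / ((L / 1000) * (N / 1e6))
    A_d <- (mu_dis * nrep) / ((L / 1000) * (N / 1e6))
    M <- log2((A_d + pseudocount) / (A_c + pseudocount))
    changed <- abs(mu_ctrl - mu_dis) > 1e-12
    p <- ifelse(changed, 1e-300, 1)
    q <- bh_adjust(p)
    structure(data.frame(feature = mo$means$gene_id, M = M, p = p, q = q,
                         direction = ifelse(!changed, "unchanged",
                                            ifelse(M > 0, "up", "down")),
                         untestable = FALSE, A_num = A_d, A_den = A_c,
                         stringsAsFactors = FALSE),
              alpha = 0.05, class = c("differential_result", "data.frame"))
  }
  Lca <- mo$atac$lengths[mo$means$gene_id]
  list(expr = mk(mo$means$expr_ctrl, mo$means$expr_dis, cfg$expr_length),
       ca = mk(mo$means$ca_ctrl, mo$means$ca_dis, Lca),
       baseline = stats::setNames(
         (mo$means$ca_ctrl * nrep) / ((Lca / 1000) * (N / 1e6)),
         mo$means$gene_id))
}

#' Generate a SNP/open-chromatin scenario with planted enrichment
#'
#' Builds per-cell-type peak sets placed uniformly on a toy genome and a
#' set of single-base variant positions of which an excess fraction is
#' planted inside the target cell type's peaks. A SNP is planted inside
#' the target peak union with probability
#' `min(1, (enrichment_fold - 1) * coverage)` and placed uniformly over
#' the genome otherwise, so `enrichment_fold = 1` gives exactly uniform
#' placement and large folds drive nearly all SNPs into target peaks.
#'
#' @param n_snps Number of SNPs.
#' @param n_peaks Peaks per cell-type set.
#' @param genome Named chromosome-length vector.
#' @param enrichment_fold Target fold enrichment (>= 1).
#' @param target_celltype Name of the enriched set.
#' @param celltypes Character vector of set names (must include the
#'   target).
#' @param peak_width Peak width in bp.
#' @param seed Integer seed.
#' @return List with `snps` (1-bp `peak_set`), `peak_sets` (named list of
#'   `peak_set`), and `truth` (enriched set, planted probability, target
#'   coverage fraction).
#' @export
generate_snp_scenario <- function(n_snps = 500, n_peaks = 200,
                                  genome = c(chr1 = 1e6, chr2 = 1e6),
                                  enrichment_fold = 1,
                                  target_celltype = "ct1",
                                  celltypes = paste0("ct", 1:4),
                                  peak_width = 1000, seed = 1) {
  genome <- validate_genome(genome)
  if (!target_celltype %in% celltypes)
    stop("target_celltype must be among celltypes", call. = FALSE)
  if (n_peaks < 1 || peak_width < 1)
    stop("peak sets must cover at least one bp", call. = FALSE)
  if (enrichment_fold < 1)
    stop("enrichment_fold must be >= 1", call. = FALSE)
  with_seed(seed, {
    gsize <- sum(genome)
    place_uniform <- function(n, width) {
      nvalid <- pmax(genome - width + 1, 0)
      ci <- sample.int(length(genome), n, replace = TRUE, prob = nvalid)
      start <- floor(stats::runif(n) * nvalid[ci])
      peak_set(names(genome)[ci], start, start + width, genome = genome)
    }
    peak_sets <- lapply(celltypes, function(ct)
      place_uniform(n_peaks, peak_width))
    names(peak_sets) <- celltypes
    target_union <- merge_regions(peak_sets[[target_celltype]])
    cov_bp <- sum(widths(target_union))
    coverage <- cov_bp / gsize
    p_extra <- min(1, (enrichment_fold - 1) * coverage)
    planted <- stats::runif(n_snps) < p_extra
    pos <- numeric(n_snps); chrom <- character(n_snps)
    if (any(planted)) {
      # uniform over the bp of the target union
      w <- widths(target_union)
      pick <- sample.int(nrow(target_union), sum(planted),
                         replace = TRUE, prob = w)
      off <- floor(stats::runif(sum(planted)) * w[pick])
      pos[planted] <- target_union$start[pick] + off
      chrom[planted] <- target_union$chrom[pick]
    }
    if (any(!planted)) {
      ci <- sample.int(length(genome), sum(!planted), replace = TRUE,
                       prob = genome)
      pos[!planted] <- floor(stats::runif(sum(!planted)) * genome[ci])
      chrom[!planted] <- names(genome)[ci]
    }
    snps <- peak_set(chrom, pos, pos + 1,
                     name = sprintf("rs%05d", seq_len(n_snps)),
                     genome = genome)
    list(snps = snps, peak_sets = peak_sets,
         truth = list(enriched_celltype = target_celltype,
                      p_extra = p_extra, coverage = coverage))
  })
}

#' Generate an activity-by-contact scenario with planted links
#'
#' Places genes and candidate enhancer elements on one chromosome and
#' assigns ATAC/H3K27ac activities per condition. Planted links (several
#' elements per planted gene) receive jointly high activity in the
#' disease condition and high raw contact, while decoy elements keep low
#' activities in both conditions; planted genes therefore gain retained
#' links in disease. The truth table records the intended links and their
#' within-gene activity-contact rank.
#'
#' @param n_genes Number of genes.
#' @param n_elements Number of candidate elements.
#' @param n_planted_genes Genes that receive planted links (ignored when
#'   `planted_links` is given).
#' @param links_per_gene Planted elements per planted gene.
#' @param planted_links Optional data.frame with columns `element_id`,
#'   `gene_id` overriding the automatic planting; unknown ids error.
#' @param decoy_mu,planted_mu Median activity (RPKM) of decoy and planted
#'   elements.
#' @param seed Integer seed.
#' @return List with `elements` (`peak_set` of element intervals),
#'   `activities` (long data.frame: element_id, condition, atac, k27ac),
#'   `contacts` (data.frame: element_id, gene_id, contact), `genes`
#'   (`gene_table`), and `truth` (data.frame: element_id, gene_id,
#'   true_score_rank).
#' @export
generate_abc_scenario <- function(n_genes = 20, n_elements = 80,
                                  n_planted_genes = 5, links_per_gene = 6,
                                  planted_links = NULL,
                                  decoy_mu = 1, planted_mu = 100,
                                  seed = 1) {
  with_seed(seed, {
    gene_id <- sprintf("gene%03d", seq_len(n_genes))
    element_id <- sprintf("e%03d", seq_len(n_elements))
    glen <- 100000 * (n_genes + 1)
    genome <- c(chr1 = glen)
    tss <- sort(sample.int(glen - 20000, n_genes)) + 10000
    genes <- gene_table(gene_id, rep("chr1", n_genes),
                        rep(c("+", "-"), length.out = n_genes),
                        tss, genome = genome)
    estart <- sort(sample.int(glen - 1000, n_elements))
    elements <- peak_set("chr1", estart, estart + 500,
                         name = element_id, genome = genome)
    element_id <- elements$name
    if (is.null(planted_links)) {
      pg <- gene_id[seq_len(min(n_planted_genes, n_genes))]
      pe <- split(element_id[seq_len(length(pg) * links_per_gene)],
                  rep(seq_along(pg), each = links_per_gene))
      planted_links <- data.frame(
        element_id = unlist(pe),
        gene_id = rep(pg, each = links_per_gene),
        stringsAsFactors = FALSE)
    }
    if (!all(planted_links$element_id %in% element_id))
      stop("planted link references unknown element id", call. = FALSE)
    if (!all(planted_links$gene_id %in% gene_id))
      stop("planted link references unknown gene id", call. = FALSE)
    is_planted <- element_id %in% planted_links$element_id
    # decoys span orders of magnitude (wide lognormal) so a gene's score
    # mass concentrates on few elements; planted elements are uniformly
    # strong, so planted genes gain retained links in disease
    decoy <- function(n) stats::rlnorm(n, log(decoy_mu), 1.5)
    strong <- function(n) stats::rlnorm(n, log(planted_mu), 0.2)
    activities <- rbind(
      data.frame(element_id = element_id, condition = "ctrl",
                 atac = decoy(n_elements), k27ac = decoy(n_elements),
                 stringsAsFactors = FALSE),
      data.frame(element_id = element_id, condition = "disease",
                 atac = ifelse(is_planted, strong(n_elements),
                               decoy(n_elements)),
                 k27ac = ifelse(is_planted, strong(n_elements),
                                decoy(n_elements)),
                 stringsAsFactors = FALSE))
    contacts <- data.frame(element_id = planted_links$element_id,
                           gene_id = planted_links$gene_id,
                           contact = stats::rlnorm(nrow(planted_links),
                                                   log(100), 0.2),
                           stringsAsFactors = FALSE)
    # truth: rank planted elements within each gene by disease A * C
    dis <- activities[activities$condition == "disease", ]
    A <- stats::setNames(sqrt(dis$atac * dis$k27ac), dis$element_id)
    truth <- do.call(rbind, lapply(split(contacts, contacts$gene_id),
      function(d) {
        d <- d[order(-A[d$element_id] * d$contact), ]
        d$true_score_rank <- seq_len(nrow(d))
        d[c("element_id", "gene_id", "true_score_rank")]
      }))
    rownames(truth) <- NULL
    list(elements = elements, activities = activities, contacts = contacts,
         genes = genes, truth = truth)
  })
}
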