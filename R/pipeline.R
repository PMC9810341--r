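#' Read a pipeline configuration file
#'
#' YAML key-value file; see [run_typing()] and [run_snp()] for the keys
#' each pipeline expects. Relative paths are resolved against the config
#' file's directory.
#'
#' @param path Path to a YAML config.
#' @return A named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg$.dir <- dirname(normalizePath(path))
  structure(cfg, class = "pipeline_config")
}

cfg_path <- function(cfg, x) {
  if (is.null(cfg$.dir) || grepl("^/", x)) x else file.path(cfg$.dir, x)
}

cfg_hash <- function(cfg) {
  cfg$.dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}

pkg_version <- function() {
  tryCatch(as.character(utils::packageVersion("chromprime")),
           error = function(e) "0.0.0")
}

output_header <- function(cfg, seed) {
  c(sprintf("chromprime %s", pkg_version()),
    sprintf("seed=%s", format(seed)),
    sprintf("config=%s", cfg_hash(cfg)))
}

write_tsv_out <- function(df, path, header) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(format(df, trim = TRUE, scientific = FALSE,
                            digits = 10),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

open_log <- function(outdir) {
  logpath <- file.path(outdir, "pipeline.log")
  unlink(logpath)
  t0 <- Sys.time()
  function(stage, rows) {
    el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    cat(sprintf("[%s] stage=%s elapsed_s=%.2f\n[%s] stage=%s rows=%d\n",
                format(Sys.time()), stage, el,
                format(Sys.time()), stage, rows),
        file = logpath, append = TRUE)
  }
}

need_keys <- function(cfg, keys, pipeline) {
  miss <- setdiff(keys, names(cfg))
  if (length(miss))
    stop(sprintf("config_error pipeline=%s missing_keys=%s", pipeline,
                 paste(miss, collapse = ",")), call. = FALSE)
}

need_file <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config_error missing_path=%s", path), call. = FALSE)
  path
}

#' Run the priming-typing pipeline over files on disk
#'
#' Reads a gene annotation, expression counts, and promoter accessibility
#' counts (one matrix per candidate promoter length when
#' `promoter_length: auto`), computes RPKM activities, differential
#' expression and accessibility (pooled exact test), classifies genes
#' into priming types, and writes every result as headered TSV into the
#' output directory. Deterministic given the seed; every output carries
#' the package version, seed, and a config hash in `#` header lines.
#'
#' Config keys: `annotation`, `expression_counts`, `atac_counts` (path,
#' or map length -> path), `groups` (condition per sample column),
#' `numerator`, `denominator`, `promoter_length` (bp or `"auto"`),
#' optional `alpha`, `tau_expr`, `tau_ca`, `pseudocount`, `seed`,
#' `truth` (planted-type TSV for a recovery report), `outdir`.
#'
#' @param config A `pipeline_config` (or path to one).
#' @param outdir Output directory (default from the config).
#' @return Invisibly, a list with the in-memory results (`assignment`,
#'   `expr`, `ca`, `selection`, `recovery`).
#' @export
run_typing <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  need_keys(config, c("annotation", "expression_counts", "atac_counts",
                      "groups", "numerator", "denominator",
                      "promoter_length"), "typing")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outdir <- if (is.null(outdir)) cfg_path(config, config$outdir) else outdir
  if (is.null(outdir)) stop("config_error missing_keys=outdir", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- open_log(outdir)
  hdr <- output_header(config, seed)
  genes <- read_gene_table(need_file(cfg_path(config, config$annotation)))
  log("annotation", nrow(genes))
  expr <- read_counts_tsv(need_file(cfg_path(config,
                                             config$expression_counts)))
  log("expression_counts", nrow(expr$counts))
  groups <- as.character(unlist(config$groups))
  pseudo <- if (is.null(config$pseudocount)) 1 else config$pseudocount
  thr <- typing_thresholds(
    alpha = if (is.null(config$alpha)) 0.05 else config$alpha,
    tau_expr = if (is.null(config$tau_expr)) 1 else config$tau_expr,
    tau_ca = if (is.null(config$tau_ca)) 1 else config$tau_ca)
  selection <- NULL
  if (identical(config$promoter_length, "auto")) {
    if (is.null(names(config$atac_counts)))
      stop("config_error reason=auto_promoter_length_needs_length_keyed_atac_counts",
           call. = FALSE)
    by_len <- lapply(config$atac_counts, function(p)
      read_counts_tsv(need_file(cfg_path(config, p))))
    selection <- select_promoter_length(by_len, score_regions(expr))
    sel <- attr(selection, "selected")
    atac <- by_len[[as.character(sel)]]
    write_tsv_out(as.data.frame(selection),
                  file.path(outdir, "length_selection.tsv"),
                  c(hdr, sprintf("selected=%g", sel)))
    log("length_selection", nrow(selection))
  } else {
    atac <- read_counts_tsv(need_file(cfg_path(config,
                                               config$atac_counts)))
  }
  log("atac_counts", nrow(atac$counts))
  de <- differential_counts(expr, groups, config$numerator,
                            config$denominator, pseudocount = pseudo,
                            alpha = thr$alpha)
  da <- differential_counts(atac, groups, config$numerator,
                            config$denominator, pseudocount = pseudo,
                            alpha = thr$alpha)
  log("differential", nrow(de) + nrow(da))
  baseline <- stats::setNames(da$A_den, da$feature)
  assignment <- classify_genes(de, da, baseline, thr)
  log("classification", nrow(assignment))
  write_tsv_out(as.data.frame(score_regions(expr)) |>
                  (\(d) cbind(region_id = rownames(d), d))(),
                file.path(outdir, "activity_expression.tsv"), hdr)
  write_tsv_out(as.data.frame(score_regions(atac)) |>
                  (\(d) cbind(region_id = rownames(d), d))(),
                file.path(outdir, "activity_atac.tsv"), hdr)
  write_tsv_out(as.data.frame(de),
                file.path(outdir, "differential_expression.tsv"), hdr)
  write_tsv_out(as.data.frame(da),
                file.path(outdir, "differential_accessibility.tsv"), hdr)
  write_tsv_out(as.data.frame(assignment),
                file.path(outdir, "type_assignment.tsv"), hdr)
  tally <- summary(assignment)
  write_tsv_out(data.frame(label = names(tally$subtype_counts),
                           n_genes = as.integer(tally$subtype_counts)),
                file.path(outdir, "type_counts.tsv"), hdr)
  recovery <- NULL
  if (!is.null(config$truth)) {
    truth <- utils::read.table(need_file(cfg_path(config, config$truth)),
                               sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    recovery <- recovery_report(assignment, truth)
    cm <- as.data.frame.matrix(recovery$confusion)
    write_tsv_out(cbind(true_type = rownames(cm), cm),
                  file.path(outdir, "confusion.tsv"),
                  c(hdr, sprintf("macro_recall=%.6f", recovery$macro_recall),
                    sprintf("null_false_rate=%.6f",
                            recovery$null_false_rate)))
    log("recovery", nrow(cm))
  }
  invisible(list(assignment = assignment, expr = de, ca = da,
                 selection = selection, recovery = recovery))
}

#' Run the SNP/open-chromatin enrichment pipeline
#'
#' Reads SNP positions (with a declared coordinate base), one BED per
#' peak set and a genome file, and writes the observed-vs-expected
#' enrichment table built from width-preserving within-chromosome shuffle
#' nulls, BH-adjusted across sets.
#'
#' Config keys: `snps` (TSV with `chrom`, `pos` or a BED file),
#' `snp_base` (0 or 1; required), `peaks` (map set name -> BED path),
#' `genome` (two-column TSV), `B`, `seed`, `outdir`.
#'
#' @param config A `pipeline_config` (or path to one).
#' @param outdir Output directory (default from the config).
#' @return Invisibly, the `enrichment_result` table.
#' @export
run_snp <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  need_keys(config, c("snps", "snp_base", "peaks", "genome"), "snp")
  if (!config$snp_base %in% c(0, 1))
    stop("config_error reason=snp_base_must_be_0_or_1", call. = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  B <- if (is.null(config$B)) 199L else as.integer(config$B)
  outdir <- if (is.null(outdir)) cfg_path(config, config$outdir) else outdir
  if (is.null(outdir)) stop("config_error missing_keys=outdir", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- open_log(outdir)
  genome <- read_genome(need_file(cfg_path(config, config$genome)))
  snp_path <- need_file(cfg_path(config, config$snps))
  if (grepl("\\.bed$", snp_path)) {
    if (config$snp_base != 0)
      stop("config_error reason=bed_snps_are_0_based", call. = FALSE)
    snps <- read_bed(snp_path, genome = genome)
  } else {
    df <- utils::read.table(snp_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    snps <- snps_from_positions(df$chrom, df$pos, base = config$snp_base,
                                name = df$name, genome = genome)
  }
  log("snps", nrow(snps))
  peak_sets <- lapply(config$peaks, function(p)
    read_bed(need_file(cfg_path(config, p)), genome = genome))
  log("peaks", sum(vapply(peak_sets, nrow, 0L)))
  res <- multi_set_report(snps, peak_sets, genome = genome, B = B,
                          seed = seed)
  log("enrichment", nrow(res))
  write_tsv_out(as.data.frame(res), file.path(outdir, "enrichment.tsv"),
                c(output_header(config, seed), sprintf("B=%d", B)))
  invisible(res)
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Generates the multi-ome, SNP, and activity-by-contact scenarios and
#' writes them in the pipeline's interchange formats, together with
#' ready-to-run `typing_config.yaml` and `snp_config.yaml` files.
#'
#' @param outdir Output directory.
#' @param seed Integer seed.
#' @param cfg A `synth_config` for the multi-ome.
#' @param snp_fold Planted SNP enrichment fold.
#' @return Invisibly, `outdir`.
#' @export
write_fixtures <- function(outdir, seed = 1,
                           cfg = synth_config(seed = seed),
                           snp_fold = 5) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  mo <- generate_multiome(cfg)
  win <- simulate_window_counts(mo, c(2000, 1000, 500))
  gt <- as.data.frame(mo$genes)
  utils::write.table(gt, file.path(outdir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_counts_tsv(mo$expression,
                   file.path(outdir, "expression_counts.tsv"))
  for (L in names(win))
    write_counts_tsv(win[[L]],
                     file.path(outdir, sprintf("atac_counts_%s.tsv", L)))
  utils::write.table(mo$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sc <- generate_snp_scenario(enrichment_fold = snp_fold,
                              seed = stage_seed(seed, 71L))
  gn <- attr(sc$snps, "genome")
  utils::write.table(data.frame(chrom = names(gn), length = gn),
                     file.path(outdir, "genome.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_bed(sc$snps, file.path(outdir, "snps.bed"))
  for (ct in names(sc$peak_sets))
    write_bed(sc$peak_sets[[ct]],
              file.path(outdir, sprintf("peaks_%s.bed", ct)))
  abc <- generate_abc_scenario(seed = stage_seed(seed, 137L))
  write_bed(abc$elements, file.path(outdir, "abc_elements.bed"))
  utils::write.table(abc$activities,
                     file.path(outdir, "abc_activities.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(abc$contacts, file.path(outdir, "abc_contacts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(abc$genes),
                     file.path(outdir, "abc_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  typing_cfg <- list(
    annotation = "annotation.tsv",
    expression_counts = "expression_counts.tsv",
    atac_counts = list(`2000` = "atac_counts_2000.tsv",
                       `1000` = "atac_counts_1000.tsv",
                       `500` = "atac_counts_500.tsv"),
    groups = mo$groups, numerator = "disease", denominator = "ctrl",
    promoter_length = "auto", truth = "truth.tsv", seed = seed,
    outdir = "typing_out")
  yaml::write_yaml(typing_cfg, file.path(outdir, "typing_config.yaml"))
  snp_cfg <- list(snps = "snps.bed", snp_base = 0,
                  peaks = as.list(stats::setNames(
                    sprintf("peaks_%s.bed", names(sc$peak_sets)),
                    names(sc$peak_sets))),
                  genome = "genome.tsv", B = 199, seed = seed,
                  outdir = "snp_out")
  yaml::write_yaml(snp_cfg, file.path(outdir, "snp_config.yaml"))
  invisible(outdir)
}
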