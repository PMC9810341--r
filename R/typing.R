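#' Thresholds for priming-type classification
#'
#' @param alpha Adjusted-p cutoff (default 0.05, the conventional FDR
#'   level).
#' @param tau_expr Expression |log2 fold change| cutoff. Default 1
#'   (two-fold), the conventional effect-size filter; configurable
#'   because published analyses vary between `log2(1.5)` and 1.5 on the
#'   log2 scale.
#' @param tau_ca Accessibility |log2 fold change| cutoff (default 1).
#' @param subtype_quantile Quantile of within-type baseline accessibility
#'   at which subtypes split (default 0.5, the median).
#' @return A list of class `typing_thresholds`.
#' @export
typing_thresholds <- function(alpha = 0.05, tau_expr = 1, tau_ca = 1,
                              subtype_quantile = 0.5) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (tau_expr < 0 || tau_ca < 0)
    stop("fold-change cutoffs must be >= 0", call. = FALSE)
  if (subtype_quantile <= 0 || subtype_quantile >= 1)
    stop("subtype_quantile must be in (0,1)", call. = FALSE)
  structure(list(alpha = alpha, tau_expr = tau_expr, tau_ca = tau_ca,
                 subtype_quantile = subtype_quantile),
            class = "typing_thresholds")
}

#' Classify genes into chromatin priming types
#'
#' Joint classification from differential expression, differential
#' accessibility, and baseline (control-condition) accessibility:
#' \describe{
#'   \item{Type1}{expression up and accessibility up; split into 1a (low
#'     baseline accessibility) / 1b (high) at the within-type median.}
#'   \item{Type2}{expression up, accessibility unchanged; split into 2a
#'     (high baseline) / 2b (low).}
#'   \item{Type3}{expression down, accessibility unchanged.}
#'   \item{Type4}{expression down and accessibility down.}
#' }
#' "Up"/"down" require `q < alpha` and `|M|` beyond the corresponding
#' cutoff; "unchanged" is failure of that conjunction. Genes matching no
#' row (including discordant patterns such as expression up with
#' accessibility down) are `unclassified`. Genes missing from any input
#' are excluded and listed in the `reconciliation` attribute.
#'
#' @param expr `differential_result` for expression (disease vs control).
#' @param ca `differential_result` for promoter accessibility.
#' @param baseline Named numeric vector: control-condition promoter
#'   activity (RPKM) per gene.
#' @param thresholds A [typing_thresholds()].
#' @return A `type_assignment`: data.frame with `gene_id`, `label`, and
#'   the evidence columns `M_expr`, `q_expr`, `M_ca`, `q_ca`,
#'   `baseline_A`.
#' @export
classify_genes <- function(expr, ca, baseline,
                           thresholds = typing_thresholds()) {
  stopifnot(inherits(expr, "differential_result"),
            inherits(ca, "differential_result"),
            inherits(thresholds, "typing_thresholds"))
  if (is.null(names(baseline)))
    stop("baseline must be named by gene id", call. = FALSE)
  universe <- union(union(expr$feature, ca$feature), names(baseline))
  shared <- Reduce(intersect, list(expr$feature, ca$feature,
                                   names(baseline)))
  dropped <- setdiff(universe, shared)
  e <- expr[match(shared, expr$feature), ]
  a <- ca[match(shared, ca$feature), ]
  b <- baseline[shared]
  al <- thresholds$alpha
  expr_up <- e$q < al & e$M > thresholds$tau_expr
  expr_down <- e$q < al & e$M < -thresholds$tau_expr
  ca_up <- a$q < al & a$M > thresholds$tau_ca
  ca_down <- a$q < al & a$M < -thresholds$tau_ca
  ca_changed <- a$q < al & abs(a$M) > thresholds$tau_ca
  main <- rep("unclassified", length(shared))
  main[expr_up & ca_up] <- "Type1"
  main[expr_up & !ca_changed] <- "Type2"
  main[expr_down & !ca_changed] <- "Type3"
  main[expr_down & ca_down] <- "Type4"
  label <- main
  for (ty in c("Type1", "Type2")) {
    i <- which(main == ty)
    label[i] <- split_subtypes(ty, b[i], global_baseline = b,
                               quantile = thresholds$subtype_quantile)
  }
  structure(data.frame(gene_id = shared, label = label,
                       M_expr = e$M, q_expr = e$q,
                       M_ca = a$M, q_ca = a$q, baseline_A = unname(b),
                       row.names = NULL, stringsAsFactors = FALSE),
            thresholds = thresholds, reconciliation = dropped,
            class = c("type_assignment", "data.frame"))
}

#' Split a main type into a/b subtypes by baseline accessibility
#'
#' Members are ranked by baseline control-condition activity and split at
#' the within-type quantile (default median). For Type1, below the split
#' is 1a (low accessibility in control) and at/above is 1b; for Type2,
#' at/above is 2a (high) and below is 2b. Exact-median ties go to the
#' "high" subtype. A singleton type is split against the global baseline
#' median and flagged with a warning.
#'
#' @param type `"Type1"` or `"Type2"`.
#' @param baseline Baseline activities of the type's members.
#' @param global_baseline All genes' baseline activities (used for
#'   singleton types).
#' @param quantile Split quantile in (0,1).
#' @return Character vector of subtype labels.
#' @export
split_subtypes <- function(type, baseline, global_baseline = baseline,
                           quantile = 0.5) {
  if (!type %in% c("Type1", "Type2"))
    stop("subtypes are defined for Type1 and Type2 only", call. = FALSE)
  if (!length(baseline)) return(character(0))
  if (length(baseline) < 2L) {
    warning(sprintf(
      "%s has a single member; splitting against the global baseline", type))
    cut <- stats::quantile(global_baseline, quantile, na.rm = TRUE,
                           names = FALSE)
  } else {
    cut <- stats::quantile(baseline, quantile, na.rm = TRUE, names = FALSE)
  }
  high <- baseline >= cut
  if (type == "Type1") ifelse(high, "Type1b", "Type1a")
  else ifelse(high, "Type2a", "Type2b")
}

#' @export
print.type_assignment <- function(x, ...) {
  cat(sprintf("type_assignment: %d gene(s)\n", nrow(x)))
  print(table(x$label))
  if (length(attr(x, "reconciliation")))
    cat(sprintf("  %d gene(s) excluded (missing from an input)\n",
                length(attr(x, "reconciliation"))))
  invisible(x)
}

#' @export
summary.type_assignment <- function(object, ...) {
  tab <- table(factor(object$label,
                      levels = c("Type1a", "Type1b", "Type2a", "Type2b",
                                 "Type3", "Type4", "unclassified")))
  main <- c(Type1 = sum(tab[c("Type1a", "Type1b")]),
            Type2 = sum(tab[c("Type2a", "Type2b")]),
            Type3 = unname(tab["Type3"]), Type4 = unname(tab["Type4"]))
  structure(list(subtype_counts = tab, type_counts = main,
                 n = nrow(object)), class = "summary.type_assignment")
}

#' @export
print.summary.type_assignment <- function(x, ...) {
  cat("Priming-type tally:\n")
  for (ty in names(x$type_counts))
    cat(sprintf("  %d %s\n", x$type_counts[[ty]], ty))
  cat("Subtypes:\n")
  print(x$subtype_counts)
  invisible(x)
}

#' Compare assigned labels with planted truth
#'
#' @param assigned A `type_assignment`.
#' @param truth Data.frame with `gene_id` and `true_type` (planted label
#'   or `"null"`).
#' @return A `recovery_report`: confusion matrix (true x assigned),
#'   per-type recall, macro recall over planted types, and the null-gene
#'   false-classification rate.
#' @export
recovery_report <- function(assigned, truth) {
  stopifnot(inherits(assigned, "type_assignment"))
  m <- merge(truth, as.data.frame(assigned)[c("gene_id", "label")],
             by = "gene_id")
  levs <- c("Type1a", "Type1b", "Type2a", "Type2b", "Type3", "Type4")
  confusion <- table(true = factor(m$true_type, levels = c(levs, "null")),
                     assigned = factor(m$label,
                                       levels = c(levs, "unclassified")))
  planted <- intersect(levs, unique(m$true_type))
  recall <- vapply(planted, function(ty) {
    i <- m$true_type == ty
    if (!any(i)) return(NA_real_)
    mean(m$label[i] == ty)
  }, 0)
  nulls <- m$true_type == "null"
  null_rate <- if (any(nulls)) mean(m$label[nulls] != "unclassified")
               else NA_real_
  structure(list(confusion = confusion, recall = recall,
                 macro_recall = mean(recall),
                 null_false_rate = null_rate,
                 n = nrow(m)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_report over %d gene(s)\n", x$n))
  cat(sprintf("  macro recall: %.3f\n", x$macro_recall))
  if (is.finite(x$null_false_rate))
    cat(sprintf("  null false-classification rate: %.3f\n",
                x$null_false_rate))
  cat("  per-type recall:\n")
  for (ty in names(x$recall))
    cat(sprintf("    %s: %.3f\n", ty, x$recall[[ty]]))
  invisible(x)
}
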