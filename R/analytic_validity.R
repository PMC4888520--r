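# Deterministic expected confusion matrix and analytic performance metrics.

#' Expected confusion matrix for one gene
#'
#' Computes the expected 2x2 classification table for detecting pathogenic
#' mutations in one gene across the screened population. The expected number
#' of true positives is
#'
#' `prevalence * size * (p_indel*sens_indel + p_snv*sens_snv + p_cnv*sens_cnv) * coverage`
#'
#' i.e. carriers, times the spectrum-weighted platform sensitivity, times the
#' probability the gene region is horizontally covered. False negatives are
#' the remaining carriers. False positives default to 0 on the assumption
#' that every positive call is confirmed by an orthogonal assay; a
#' non-zero `fp_count` can be supplied (the sensitivity analysis does).
#' True negatives absorb everyone else, including carriers of variants of
#' uncertain significance, which are assumed not to be reported.
#'
#' @param gene a [gene_model()].
#' @param platform a [platform_performance()].
#' @param pop a [population_config()].
#' @param fp_count expected number of false-positive calls (default 0).
#' @return an object of class `confusion_counts` with continuous cells
#'   `tp`, `fp`, `fn`, `tn` and a `rounded` integer view (half away from
#'   zero) of each.
#' @examples
#' cfg <- brca_preset()
#' expected_confusion(cfg$genes$BRCA1, cfg$platform, cfg$population)
#' @export
expected_confusion <- function(gene, platform, pop, fp_count = 0) {
  stopifnot(inherits(gene, "gene_model"), inherits(platform, "platform_performance"),
            inherits(pop, "population_config"))
  fp_count <- check_nonneg(fp_count, "fp_count")
  carriers <- gene$prevalence * pop$size
  weighted_sens <- gene$spectrum$p_indel * platform$sens_indel +
    gene$spectrum$p_snv * platform$sens_snv +
    gene$spectrum$p_cnv * platform$sens_cnv
  tp <- carriers * weighted_sens * gene$coverage
  fn <- carriers - tp
  fp <- fp_count
  tn <- pop$size - carriers - fp
  confusion_counts(gene$name, tp = tp, fp = fp, fn = fn, tn = tn,
                   size = pop$size)
}

#' Construct a confusion-counts object
#'
#' Usually produced by [expected_confusion()] or [simulate_cohort()]; exposed
#' so externally tabulated cells can reuse the metric and reporting code.
#'
#' @param gene gene name the counts belong to.
#' @param tp,fp,fn,tn cell values (continuous non-negative reals).
#' @param size population size the cells must sum to.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(gene, tp, fp, fn, tn, size = tp + fp + fn + tn) {
  tp <- check_nonneg(tp, "tp")
  fp <- check_nonneg(fp, "fp")
  fn <- check_nonneg(fn, "fn")
  tn <- check_nonneg(tn, "tn")
  size <- as.numeric(size)
  if (abs(tp + fp + fn + tn - size) > 1e-9 * max(1, size)) {
    validation_error("tp+fp+fn+tn", "cells must sum to the population size")
  }
  structure(list(
    gene = gene,
    tp = tp, fp = fp, fn = fn, tn = tn,
    size = size,
    rounded = c(tp = round_half_away(tp), fp = round_half_away(fp),
                fn = round_half_away(fn), tn = round_half_away(tn))
  ), class = "confusion_counts")
}

#' Analytic performance metrics from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`. By default
#' metrics are computed from the rounded integer cells, matching how
#' whole-cohort tables are reported (93 of 120 carriers detected gives
#' 77.5 %, where the continuous 93.19 of 120 would give 77.7 %); set
#' `use = "continuous"` for the unrounded cells. A metric whose denominator
#' is zero is returned as `NA` and flagged in `defined`, never silently 0.
#'
#' @param counts a [confusion_counts()] object.
#' @param use `"rounded"` (default) or `"continuous"` cells.
#' @return an object of class `test_performance`: proportions `sensitivity`,
#'   `specificity`, `ppv`, `npv` plus a named logical vector `defined`.
#' @examples
#' cfg <- brca_preset()
#' performance_metrics(expected_confusion(cfg$genes$BRCA1, cfg$platform, cfg$population))
#' @export
performance_metrics <- function(counts, use = c("rounded", "continuous")) {
  stopifnot(inherits(counts, "confusion_counts"))
  use <- match.arg(use)
  cells <- if (use == "rounded") as.list(counts$rounded) else counts[c("tp", "fp", "fn", "tn")]
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  metrics <- c(
    sensitivity = ratio(cells$tp, cells$tp + cells$fn),
    specificity = ratio(cells$tn, cells$tn + cells$fp),
    ppv = ratio(cells$tp, cells$tp + cells$fp),
    npv = ratio(cells$tn, cells$tn + cells$fn)
  )
  structure(list(
    gene = counts$gene,
    sensitivity = metrics[["sensitivity"]],
    specificity = metrics[["specificity"]],
    ppv = metrics[["ppv"]],
    npv = metrics[["npv"]],
    defined = !is.na(metrics),
    cells_used = use
  ), class = "test_performance")
}

#' Main-model analytic validity for every gene in a configuration
#'
#' Runs [expected_confusion()] and [performance_metrics()] for each gene.
#'
#' @param config a [screen_config()].
#' @param fp_count expected false positives per gene (default 0).
#' @return a named list (one element per gene) of
#'   `list(counts = confusion_counts, metrics = test_performance)`,
#'   classed `analytic_validity`.
#' @export
analytic_validity <- function(config, fp_count = 0) {
  stopifnot(inherits(config, "screen_config"))
  res <- lapply(config$genes, function(g) {
    counts <- expected_confusion(g, config$platform, config$population, fp_count)
    list(counts = counts, metrics = performance_metrics(counts))
  })
  structure(res, class = "analytic_validity")
}

#' @export
print.confusion_counts <- function(x, ...) {
  r <- x$rounded
  cat(sprintf("%s expected classification of %s women\n", x$gene,
              format(x$size, big.mark = ",")))
  m <- matrix(c(r["tp"], r["fp"], r["tp"] + r["fp"],
                r["fn"], r["tn"], r["fn"] + r["tn"],
                r["tp"] + r["fn"], r["fp"] + r["tn"], sum(r)),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("Detected: yes", "Detected: no", "Total"),
                              c("Carrier", "Non-carrier", "Total")))
  print(format(m, big.mark = ","), quote = FALSE)
  cat(sprintf("continuous: tp %.4f, fp %.4f, fn %.4f, tn %.4f\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' @export
print.test_performance <- function(x, ...) {
  cat(sprintf("%s analytic performance (%s cells)\n", x$gene, x$cells_used))
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    cat(sprintf("  %-12s %s", m, fmt_pct(x[[m]])))
    if (!is.na(x[[m]])) cat(sprintf("  (%.6f)", x[[m]]))
    cat("\n")
  }
  invisible(x)
}

#' @export
print.analytic_validity <- function(x, ...) {
  for (g in x) {
    print(g$counts)
    print(g$metrics)
    cat("\n")
  }
  invisible(x)
}

#' @export
as.data.frame.confusion_counts <- function(x, ...) {
  data.frame(
    gene = x$gene,
    cell = c("tp", "fp", "fn", "tn"),
    expected = c(x$tp, x$fp, x$fn, x$tn),
    rounded = as.integer(x$rounded[c("tp", "fp", "fn", "tn")]),
    row.names = NULL
  )
}

#' @export
as.data.frame.test_performance <- function(x, ...) {
  metric <- c("sensitivity", "specificity", "ppv", "npv")
  vals <- vapply(metric, function(m) x[[m]], numeric(1))
  data.frame(
    gene = x$gene,
    metric = metric,
    proportion = unname(vals),
    percent = fmt_pct(vals),
    defined = unname(x$defined),
    row.names = NULL
  )
}
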