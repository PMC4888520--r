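# Clinical validity: apply lifetime penetrance and background risk to the
# analytic confusion-matrix cells to project expected breast-cancer counts
# per screening outcome.

#' Project expected cancer counts over screening outcomes
#'
#' Carriers — whether detected (true positives) or missed (false negatives) —
#' accrue breast cancer at their gene's lifetime penetrance (central, low and
#' high variants give the projection range). Women with no modelled mutation
#' accrue cancer at the population background risk; that pool is counted
#' once across the whole gene panel (population minus all carriers minus
#' false positives), and false positives, being non-carriers, also accrue
#' the background risk. Projections use the rounded integer cell counts, the
#' scale on which whole-cohort results are reported; expected cancer counts
#' are kept continuous and rounded only in the reported views (round after
#' summing across genes).
#'
#' @param counts a list of [confusion_counts()], one per gene (e.g. the
#'   `counts` elements of [analytic_validity()]).
#' @param genes the matching list of [gene_model()]s (penetrance source);
#'   matched to `counts` by gene name.
#' @param pop a [population_config()].
#' @return an object of class `clinical_outcome`: a data.frame with one row
#'   per gene x scenario plus combined rows (`gene == "combined"`), columns
#'   `scenario` (`true_positive`, `false_positive`, `false_negative`,
#'   `true_negative`), `n_women`, `cancers_central`, `cancers_low`,
#'   `cancers_high` and rounded views of the three cancer columns.
#' @examples
#' cfg <- brca_preset()
#' av <- analytic_validity(cfg)
#' project_cancers(lapply(av, `[[`, "counts"), cfg$genes, cfg$population)
#' @export
project_cancers <- function(counts, genes, pop) {
  stopifnot(inherits(pop, "population_config"))
  if (inherits(counts, "analytic_validity")) counts <- lapply(counts, `[[`, "counts")
  stopifnot(all(vapply(counts, inherits, logical(1), "confusion_counts")),
            all(vapply(genes, inherits, logical(1), "gene_model")))
  gene_names <- vapply(genes, `[[`, character(1), "name")
  names(genes) <- gene_names
  count_names <- vapply(counts, `[[`, character(1), "gene")
  if (!setequal(gene_names, count_names)) {
    validation_error("genes", "gene models and confusion counts must cover the same genes")
  }
  names(counts) <- count_names
  bg <- pop$background_risk

  per_gene <- do.call(rbind, lapply(gene_names, function(nm) {
    r <- counts[[nm]]$rounded
    pen <- genes[[nm]]$penetrance
    data.frame(
      gene = nm,
      scenario = c("true_positive", "false_positive", "false_negative"),
      n_women = as.integer(r[c("tp", "fp", "fn")]),
      cancers_central = c(r[["tp"]] * pen$central, r[["fp"]] * bg, r[["fn"]] * pen$central),
      cancers_low = c(r[["tp"]] * pen$low, r[["fp"]] * bg, r[["fn"]] * pen$low),
      cancers_high = c(r[["tp"]] * pen$high, r[["fp"]] * bg, r[["fn"]] * pen$high),
      row.names = NULL
    )
  }))

  combined <- stats::aggregate(
    per_gene[c("n_women", "cancers_central", "cancers_low", "cancers_high")],
    by = list(scenario = per_gene$scenario), FUN = sum
  )
  combined <- cbind(gene = "combined", combined)

  carriers <- sum(vapply(counts, function(x) x$rounded[["tp"]] + x$rounded[["fn"]], numeric(1)))
  fp_total <- sum(vapply(counts, function(x) x$rounded[["fp"]], numeric(1)))
  tn_pool <- pop$size - carriers - fp_total
  tn_row <- data.frame(
    gene = "combined", scenario = "true_negative", n_women = as.integer(tn_pool),
    cancers_central = tn_pool * bg, cancers_low = tn_pool * bg,
    cancers_high = tn_pool * bg
  )

  out <- rbind(per_gene, combined, tn_row)
  scen_order <- c("true_positive", "false_positive", "false_negative", "true_negative")
  out <- out[order(match(out$gene, c(gene_names, "combined")),
                   match(out$scenario, scen_order)), ]
  rownames(out) <- NULL
  for (col in c("cancers_central", "cancers_low", "cancers_high")) {
    out[[paste0(col, "_rounded")]] <- as.integer(round_half_away(out[[col]]))
  }
  structure(out, class = c("clinical_outcome", "data.frame"),
            population = pop$size)
}

#' Scenario-level outcome report
#'
#' Condenses a [project_cancers()] projection into the four whole-panel
#' screening scenarios: women whose pathogenic mutation was correctly
#' identified (who can be offered risk-reducing intervention), analytic
#' false positives, carriers incorrectly reassured (false negatives, whose
#' prevention opportunity is missed), and true negatives including
#' unreported variants of uncertain significance. For true positives it also
#' derives the number of identified carriers not destined to develop cancer
#' — women who would be offered intervention without personal benefit.
#'
#' @param outcome a `clinical_outcome` from [project_cancers()].
#' @return an object of class `scenario_report`: a data.frame with one row
#'   per scenario, columns `scenario`, `n_women`, `expected_cancers`
#'   (rounded central), `cancers_low`, `cancers_high` (rounded range) and
#'   `carriers_without_cancer` (true-positive row only, `NA` elsewhere).
#'   Scenario headcounts sum to the population size.
#' @examples
#' cfg <- brca_preset()
#' scenario_report(project_cancers(analytic_validity(cfg), cfg$genes, cfg$population))
#' @export
scenario_report <- function(outcome) {
  stopifnot(inherits(outcome, "clinical_outcome"))
  comb <- outcome[outcome$gene == "combined", ]
  cancers <- comb$cancers_central_rounded
  rep <- data.frame(
    scenario = comb$scenario,
    n_women = comb$n_women,
    expected_cancers = cancers,
    cancers_low = comb$cancers_low_rounded,
    cancers_high = comb$cancers_high_rounded,
    carriers_without_cancer = ifelse(comb$scenario == "true_positive",
                                     comb$n_women - cancers, NA_integer_),
    row.names = NULL
  )
  structure(rep, class = c("scenario_report", "data.frame"),
            population = attr(outcome, "population"))
}

#' @export
print.clinical_outcome <- function(x, ...) {
  cat(sprintf("Projected breast-cancer counts by screening outcome (population %s)\n",
              format(attr(x, "population"), big.mark = ",")))
  df <- x
  class(df) <- "data.frame"
  df$cancers <- sprintf("%d (range %d-%d)", df$cancers_central_rounded,
                        df$cancers_low_rounded, df$cancers_high_rounded)
  print(df[c("gene", "scenario", "n_women", "cancers")], row.names = FALSE)
  invisible(x)
}

#' @export
print.scenario_report <- function(x, ...) {
  pop <- attr(x, "population")
  labels <- c(
    true_positive = "Correctly identified mutation carriers",
    false_positive = "Analytic false positives",
    false_negative = "Carriers incorrectly reported negative",
    true_negative = "True negatives (incl. unreported VUS)"
  )
  for (j in seq_len(nrow(x))) {
    r <- x[j, ]
    cat(sprintf("%s: %s/%s women; expected breast cancers %d (range %d-%d)\n",
                labels[[r$scenario]], format(r$n_women, big.mark = ","),
                format(pop, big.mark = ","), r$expected_cancers,
                r$cancers_low, r$cancers_high))
    if (!is.na(r$carriers_without_cancer)) {
      cat(sprintf("  of whom %d identified carriers are not expected to develop breast cancer\n",
                  r$carriers_without_cancer))
    }
  }
  invisible(x)
}
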