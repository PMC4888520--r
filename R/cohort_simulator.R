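# Individual-level cohort simulator: a stochastic oracle for the closed-form
# expectations, and a synthetic-data generator for downstream tooling.

#' Simulate an individual-level screening cohort
#'
#' Draws each woman end to end: carrier status via a single categorical draw
#' over \{genes, none\} (so carriers are disjoint by construction); mutation
#' class from the carrier gene's spectrum; horizontal coverage as an
#' independent Bernoulli per individual; detection as coverage AND a
#' Bernoulli at the class sensitivity; and lifetime breast cancer at the
#' gene's central penetrance for carriers or the background risk otherwise.
#' Tabulating the realised cohort gives empirical confusion cells and cancer
#' counts whose expectations are exactly the closed-form model values, which
#' is this simulator's purpose: every deterministic formula in the package
#' can be checked against it empirically.
#'
#' @param config a [screen_config()].
#' @param seed RNG seed (integer); identical seed and inputs give an
#'   identical cohort.
#' @param n cohort size; defaults to the configured population size. Larger
#'   `n` tightens the binomial standard errors when using the simulator as
#'   an oracle (cells are compared after scaling by `n / population size`).
#' @param keep_table if `FALSE`, skip materialising the per-individual
#'   data.frame and return tabulations only (useful at very large `n`).
#' @return an object of class `cohort_sim`:
#' \describe{
#'   \item{`cohort`}{data.frame (unless `keep_table = FALSE`) with columns
#'     `id`, `carrier_gene` (`"none"` or a gene name), `mutation_class`
#'     (`"none"`, `"indel"`, `"snv"`, `"cnv"`), `covered`, `detected`,
#'     `cancer`.}
#'   \item{`counts`}{named list of empirical [confusion_counts()] per gene
#'     (false positives attributed to no gene are 0 when specificities
#'     are 1).}
#'   \item{`cancers`}{data.frame of observed cancer counts by gene and
#'     screening outcome (`true_positive`, `false_negative`, and a combined
#'     `true_negative` non-carrier pool).}
#'   \item{`n`, `seed`}{the simulation settings.}
#' }
#' @examples
#' sim <- simulate_cohort(brca_preset(), seed = 1, n = 50000)
#' sim$counts$BRCA1$rounded
#' @export
simulate_cohort <- function(config, seed, n = config$population$size,
                            keep_table = TRUE) {
  stopifnot(inherits(config, "screen_config"))
  seed <- check_count(seed, "seed")
  n <- check_count(n, "n")
  genes <- config$genes
  platform <- config$platform
  bg <- config$population$background_risk
  set.seed(seed)

  gene_names <- names(genes)
  prev <- vapply(genes, `[[`, numeric(1), "prevalence")
  carrier_idx <- sample.int(length(genes) + 1L, n, replace = TRUE,
                            prob = c(prev, 1 - sum(prev)))
  is_carrier <- carrier_idx <= length(genes)

  mutation_class <- rep.int(4L, n)  # 4 = none
  covered <- logical(n)
  detected <- logical(n)
  cancer_p <- rep.int(bg, n)
  class_sens <- c(indel = platform$sens_indel, snv = platform$sens_snv,
                  cnv = platform$sens_cnv)
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    idx <- which(carrier_idx == i)
    if (!length(idx)) next
    cls <- sample.int(3L, length(idx), replace = TRUE,
                      prob = c(g$spectrum$p_indel, g$spectrum$p_snv, g$spectrum$p_cnv))
    mutation_class[idx] <- cls
    covered[idx] <- stats::runif(length(idx)) < g$coverage
    detected[idx] <- covered[idx] &
      stats::runif(length(idx)) < class_sens[cls]
    cancer_p[idx] <- g$penetrance$central
  }
  cancer <- stats::runif(n) < cancer_p

  counts <- lapply(seq_along(genes), function(i) {
    carrier_g <- carrier_idx == i
    tp <- sum(carrier_g & detected)
    fn <- sum(carrier_g & !detected)
    fp <- 0  # per-class specificities of 1: no spurious calls simulated
    confusion_counts(gene_names[i], tp = tp, fp = fp, fn = fn,
                     tn = n - tp - fn - fp, size = n)
  })
  names(counts) <- gene_names

  cancers <- do.call(rbind, lapply(seq_along(genes), function(i) {
    carrier_g <- carrier_idx == i
    data.frame(
      gene = gene_names[i],
      scenario = c("true_positive", "false_negative"),
      n_women = c(sum(carrier_g & detected), sum(carrier_g & !detected)),
      cancers = c(sum(cancer[carrier_g & detected]),
                  sum(cancer[carrier_g & !detected])),
      row.names = NULL
    )
  }))
  cancers <- rbind(cancers, data.frame(
    gene = "combined", scenario = "true_negative",
    n_women = sum(!is_carrier), cancers = sum(cancer[!is_carrier])
  ))

  cohort <- NULL
  if (keep_table) {
    cohort <- data.frame(
      id = seq_len(n),
      carrier_gene = c(gene_names, "none")[carrier_idx],
      mutation_class = c("indel", "snv", "cnv", "none")[mutation_class],
      covered = covered,
      detected = detected,
      cancer = cancer
    )
  }
  structure(list(cohort = cohort, counts = counts, cancers = cancers,
                 n = n, seed = seed),
            class = "cohort_sim")
}

#' Write a simulated cohort to CSV
#'
#' Plain CSV with header `id,carrier_gene,mutation_class,covered,detected,cancer`
#' (logical columns as `TRUE`/`FALSE`).
#'
#' @param sim a [simulate_cohort()] result with its per-individual table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(sim, path) {
  stopifnot(inherits(sim, "cohort_sim"))
  if (is.null(sim$cohort)) {
    validation_error("sim", "cohort table was not kept (keep_table = FALSE)")
  }
  utils::write.csv(sim$cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("Simulated cohort of %s women (seed %d)\n",
              format(x$n, big.mark = ","), x$seed))
  for (ct in x$counts) {
    r <- ct$rounded
    cat(sprintf("  %s: tp %d, fn %d, fp %d, tn %s\n", ct$gene,
                as.integer(r["tp"]), as.integer(r["fn"]), as.integer(r["fp"]),
                format(r[["tn"]], big.mark = ",")))
  }
  invisible(x)
}
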