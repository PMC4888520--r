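# Model inputs: constructors, validation, configuration file I/O and the
# built-in preset of published UK BRCA1/BRCA2 screening parameters.

#' Mutation-class spectrum
#'
#' The split of pathogenic mutations in a gene into small insertions/deletions
#' (indels), single nucleotide variants (SNVs: nonsense, pathogenic missense,
#' splice site) and copy number variants (CNVs). Each platform detects these
#' classes with different sensitivity, so the spectrum drives overall assay
#' sensitivity.
#'
#' @param p_indel,p_snv,p_cnv proportions in \[0, 1\] that must sum to 1.
#' @param tol tolerance for the sum-to-one check (default `1e-9`, chosen so
#'   that text round-trips of the proportions never trip the invariant).
#' @return an object of class `mutation_spectrum`.
#' @examples
#' mutation_spectrum(0.54, 0.36, 0.10)
#' @export
mutation_spectrum <- function(p_indel, p_snv, p_cnv, tol = 1e-9) {
  p_indel <- check_prob(p_indel, "p_indel")
  p_snv <- check_prob(p_snv, "p_snv")
  p_cnv <- check_prob(p_cnv, "p_cnv")
  if (abs(p_indel + p_snv + p_cnv - 1) > tol) {
    validation_error(
      "p_indel + p_snv + p_cnv",
      sprintf("class proportions must sum to 1 (got %.12g)", p_indel + p_snv + p_cnv)
    )
  }
  structure(list(p_indel = p_indel, p_snv = p_snv, p_cnv = p_cnv),
            class = "mutation_spectrum")
}

#' Platform detection performance per mutation class
#'
#' Per-class analytic sensitivity and specificity of the sequencing assay.
#' Specificities are carried per class for generality; the default of 1
#' encodes the assumption that every positive call is confirmed by an
#' orthogonal assay, so false positives from the platform are eliminated.
#'
#' @param sens_indel,sens_snv,sens_cnv detection sensitivity per class, in \[0, 1\].
#' @param spec_indel,spec_snv,spec_cnv specificity per class, in \[0, 1\] (default 1).
#' @return an object of class `platform_performance`.
#' @export
platform_performance <- function(sens_indel, sens_snv, sens_cnv,
                                 spec_indel = 1, spec_snv = 1, spec_cnv = 1) {
  structure(list(
    sens_indel = check_prob(sens_indel, "sens_indel"),
    sens_snv = check_prob(sens_snv, "sens_snv"),
    sens_cnv = check_prob(sens_cnv, "sens_cnv"),
    spec_indel = check_prob(spec_indel, "spec_indel"),
    spec_snv = check_prob(spec_snv, "spec_snv"),
    spec_cnv = check_prob(spec_cnv, "spec_cnv")
  ), class = "platform_performance")
}

#' Lifetime penetrance estimate with uncertainty range
#'
#' Central lifetime probability that a mutation carrier develops the disease,
#' with a low/high range spanning the published literature.
#'
#' @param central central lifetime risk in \[0, 1\].
#' @param low,high range endpoints; must bracket `central`. Default to
#'   `central` (a point estimate).
#' @return an object of class `penetrance_estimate`.
#' @export
penetrance_estimate <- function(central, low = central, high = central) {
  central <- check_prob(central, "central")
  low <- check_prob(low, "low")
  high <- check_prob(high, "high")
  if (low > central || central > high) {
    validation_error("penetrance", "must satisfy low <= central <= high")
  }
  structure(list(central = central, low = low, high = high),
            class = "penetrance_estimate")
}

#' One gene's screening model
#'
#' Bundles everything the confusion-matrix model needs for one gene: carrier
#' prevalence in the unselected population, mutation-class spectrum,
#' horizontal sequencing coverage of the gene region, and lifetime penetrance.
#'
#' @param name gene identifier (e.g. `"BRCA1"`).
#' @param prevalence carrier frequency in \[0, 1\].
#' @param spectrum a [mutation_spectrum()].
#' @param coverage horizontal coverage fraction in \[0, 1\].
#' @param penetrance a [penetrance_estimate()].
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(name, prevalence, spectrum, coverage, penetrance) {
  if (!inherits(spectrum, "mutation_spectrum")) {
    validation_error("spectrum", "must be a mutation_spectrum object")
  }
  if (!inherits(penetrance, "penetrance_estimate")) {
    validation_error("penetrance", "must be a penetrance_estimate object")
  }
  structure(list(
    name = check_string(name, "name"),
    prevalence = check_prob(prevalence, "prevalence"),
    spectrum = spectrum,
    coverage = check_prob(coverage, "coverage"),
    penetrance = penetrance
  ), class = "gene_model")
}

#' Screened population
#'
#' @param size number of women screened (positive integer).
#' @param background_risk lifetime disease probability for a woman carrying no
#'   modelled mutation, in \[0, 1\].
#' @return an object of class `population_config`.
#' @export
population_config <- function(size, background_risk) {
  structure(list(
    size = check_count(size, "size"),
    background_risk = check_prob(background_risk, "background_risk")
  ), class = "population_config")
}

#' Full screening configuration
#'
#' @param genes a list of [gene_model()] objects (prevalences treated as
#'   disjoint: at these carrier frequencies double carriers contribute less
#'   than one woman per hundred thousand and are ignored).
#' @param platform a [platform_performance()].
#' @param population a [population_config()].
#' @return an object of class `screen_config`.
#' @export
screen_config <- function(genes, platform, population) {
  if (!is.list(genes) || (length(genes) && !all(vapply(genes, inherits, logical(1), "gene_model")))) {
    validation_error("genes", "must be a list of gene_model objects")
  }
  if (!inherits(platform, "platform_performance")) {
    validation_error("platform", "must be a platform_performance object")
  }
  if (!inherits(population, "population_config")) {
    validation_error("population", "must be a population_config object")
  }
  total_prev <- sum(vapply(genes, `[[`, numeric(1), "prevalence"))
  if (total_prev > 1) {
    validation_error("genes", "summed carrier prevalences exceed 1")
  }
  names(genes) <- vapply(genes, `[[`, character(1), "name")
  structure(list(genes = genes, platform = platform, population = population),
            class = "screen_config")
}

#' Built-in preset: published UK BRCA1/BRCA2 parameters
#'
#' The main-analysis inputs for screening 100,000 unselected UK women by
#' whole genome sequencing: carrier prevalences of 0.12 % (BRCA1) and 0.2 %
#' (BRCA2); mutation spectra of 54/36/10 % and 69/21/10 % for
#' indel/SNV/CNV; horizontal coverage 99.41 % and 99.97 %; platform
#' sensitivity 0.8 for indels, 0.97 for SNVs and 0 for CNVs with all
#' specificities 1 (confirmatory testing removes false positives); lifetime
#' breast-cancer penetrance 59 % (range 57–71 %) for BRCA1 and 51 %
#' (range 45–87.5 %) for BRCA2; and a 12.5 % background lifetime risk.
#'
#' @return a [screen_config()].
#' @examples
#' cfg <- brca_preset()
#' cfg$genes$BRCA2$prevalence
#' @export
brca_preset <- function() {
  screen_config(
    genes = list(
      gene_model(
        name = "BRCA1",
        prevalence = 0.0012,
        spectrum = mutation_spectrum(0.54, 0.36, 0.10),
        coverage = 0.9941,
        penetrance = penetrance_estimate(0.59, 0.57, 0.71)
      ),
      gene_model(
        name = "BRCA2",
        prevalence = 0.002,
        spectrum = mutation_spectrum(0.69, 0.21, 0.10),
        coverage = 0.9997,
        penetrance = penetrance_estimate(0.51, 0.45, 0.875)
      )
    ),
    platform = platform_performance(
      sens_indel = 0.8, sens_snv = 0.97, sens_cnv = 0,
      spec_indel = 1, spec_snv = 1, spec_cnv = 1
    ),
    population = population_config(size = 100000L, background_risk = 0.125)
  )
}

#' Load a screening configuration from a YAML file
#'
#' The schema mirrors [screen_config()]: top-level keys `population`
#' (`size`, `background_risk`), `platform` (`sens_indel`, `sens_snv`,
#' `sens_cnv` and optional `spec_*`), and `genes`, a sequence of maps each
#' with `name`, `prevalence`, `coverage`, `spectrum` (`indel`, `snv`, `cnv`)
#' and `penetrance` (`central` and optional `low`, `high`). Every invariant
#' is checked on load; violations raise an error naming the offending field.
#'
#' @param path path to a YAML configuration file.
#' @return a validated [screen_config()].
#' @seealso [save_config()] for the inverse; loading a saved configuration
#'   reproduces every field.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    validation_error("path", sprintf("config file not found: %s", path))
  }
  raw <- yaml::read_yaml(path)
  for (key in c("population", "platform", "genes")) {
    if (is.null(raw[[key]])) validation_error(key, "missing from config file")
  }
  need <- function(x, field, where) {
    if (is.null(x)) validation_error(paste0(where, ".", field), "missing from config file")
    x
  }
  genes <- lapply(raw$genes, function(g) {
    where <- paste0("genes[", g$name %||% "?", "]")
    sp <- need(g$spectrum, "spectrum", where)
    pe <- need(g$penetrance, "penetrance", where)
    gene_model(
      name = need(g$name, "name", where),
      prevalence = need(g$prevalence, "prevalence", where),
      spectrum = mutation_spectrum(
        need(sp$indel, "spectrum.indel", where),
        need(sp$snv, "spectrum.snv", where),
        need(sp$cnv, "spectrum.cnv", where)
      ),
      coverage = need(g$coverage, "coverage", where),
      penetrance = penetrance_estimate(
        need(pe$central, "penetrance.central", where),
        pe$low %||% pe$central,
        pe$high %||% pe$central
      )
    )
  })
  pl <- raw$platform
  po <- raw$population
  screen_config(
    genes = genes,
    platform = platform_performance(
      sens_indel = need(pl$sens_indel, "sens_indel", "platform"),
      sens_snv = need(pl$sens_snv, "sens_snv", "platform"),
      sens_cnv = need(pl$sens_cnv, "sens_cnv", "platform"),
      spec_indel = pl$spec_indel %||% 1,
      spec_snv = pl$spec_snv %||% 1,
      spec_cnv = pl$spec_cnv %||% 1
    ),
    population = population_config(
      size = need(po$size, "size", "population"),
      background_risk = need(po$background_risk, "background_risk", "population")
    )
  )
}

#' Save a screening configuration to a YAML file
#'
#' Writes the schema documented in [load_config()]; the save/load round trip
#' is lossless field by field.
#'
#' @param config a [screen_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "screen_config"))
  out <- list(
    population = list(
      size = config$population$size,
      background_risk = config$population$background_risk
    ),
    platform = config$platform[c("sens_indel", "sens_snv", "sens_cnv",
                                 "spec_indel", "spec_snv", "spec_cnv")],
    genes = lapply(unname(config$genes), function(g) {
      list(
        name = g$name,
        prevalence = g$prevalence,
        coverage = g$coverage,
        spectrum = list(indel = g$spectrum$p_indel, snv = g$spectrum$p_snv,
                        cnv = g$spectrum$p_cnv),
        penetrance = list(central = g$penetrance$central, low = g$penetrance$low,
                          high = g$penetrance$high)
      )
    })
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

# Stable hash of a configuration, for run manifests: canonical YAML bytes
# hashed with md5. Identical configurations hash identically.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.screen_config <- function(x, ...) {
  cat(sprintf("Screening configuration: %d gene(s), population %s, background risk %s\n",
              length(x$genes), format(x$population$size, big.mark = ","),
              fmt_pct(x$population$background_risk)))
  for (g in x$genes) {
    cat(sprintf("  %s: prevalence %.4g, spectrum indel/snv/cnv %.2f/%.2f/%.2f, coverage %.4f, penetrance %.3g (%.3g-%.3g)\n",
                g$name, g$prevalence, g$spectrum$p_indel, g$spectrum$p_snv,
                g$spectrum$p_cnv, g$coverage, g$penetrance$central,
                g$penetrance$low, g$penetrance$high))
  }
  cat(sprintf("  platform sensitivity indel/snv/cnv: %.2f/%.2f/%.2f\n",
              x$platform$sens_indel, x$platform$sens_snv, x$platform$sens_cnv))
  invisible(x)
}
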