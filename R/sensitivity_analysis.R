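# Monte Carlo probabilistic sensitivity analysis: rerun the deterministic
# confusion-matrix model many times with inputs drawn from uncertainty
# distributions, and summarise the spread of every cell.

#' Sampling distribution for one uncertain parameter
#'
#' Describes how one model input is perturbed across Monte Carlo replicates.
#' Supported families and their `params`:
#' \describe{
#'   \item{`fixed`}{`value` — a point mass; the parameter is not varied.}
#'   \item{`normal`}{`mean`, `sd` — Gaussian, truncated to `bounds`.}
#'   \item{`gamma`}{`shape`, `rate` — Gamma, truncated to `bounds`. With
#'     `transform = "one_minus"` the sampled value is `1 - X`, the natural
#'     way to express a detection sensitivity as one minus a
#'     Gamma-distributed deficit.}
#'   \item{`scaled_beta`}{`shape1`, `shape2` — Beta rescaled onto `bounds`
#'     (which are then required).}
#'   \item{`trunc_exp`}{`rate`, or `mean_frac` when the upper bound is set
#'     dynamically (the false-positive draw, capped at a fraction of the
#'     replicate's true positives: rate is `1/(mean_frac * cap)`), —
#'     Exponential truncated to `bounds`, hence heavily skewed towards 0.}
#' }
#'
#' Truncation uses inverse-CDF sampling, so draws respect `bounds` exactly
#' and are monotone in the underlying uniforms (shifting a location parameter
#' upward can only move paired draws upward).
#'
#' @param family one of `"fixed"`, `"normal"`, `"gamma"`, `"scaled_beta"`,
#'   `"trunc_exp"`.
#' @param params named list of family-specific parameters (above).
#' @param bounds optional `c(lo, hi)` truncation interval.
#' @param transform `"identity"` (default) or `"one_minus"`.
#' @return an object of class `dist_spec`.
#' @examples
#' dist_spec("normal", list(mean = 0.54, sd = 0.05), bounds = c(0, 0.9))
#' dist_spec("gamma", list(shape = 2, rate = 10), transform = "one_minus",
#'           bounds = c(0, 1))
#' @export
dist_spec <- function(family = c("fixed", "normal", "gamma", "scaled_beta", "trunc_exp"),
                      params = list(), bounds = NULL,
                      transform = c("identity", "one_minus")) {
  family <- match.arg(family)
  transform <- match.arg(transform)
  if (!is.null(bounds)) {
    if (!is.numeric(bounds) || length(bounds) != 2L || bounds[1] > bounds[2]) {
      validation_error("bounds", "must be c(lo, hi) with lo <= hi")
    }
  }
  needed <- switch(family,
    fixed = "value",
    normal = c("mean", "sd"),
    gamma = c("shape", "rate"),
    scaled_beta = c("shape1", "shape2"),
    trunc_exp = character(0)  # rate or mean_frac, checked at sampling time
  )
  missing <- setdiff(needed, names(params))
  if (length(missing)) {
    validation_error(missing[1], sprintf("required by family '%s'", family))
  }
  if (family == "trunc_exp" && is.null(params$rate) && is.null(params$mean_frac)) {
    validation_error("rate", "trunc_exp needs either `rate` or `mean_frac`")
  }
  if (family == "scaled_beta" && is.null(bounds)) {
    validation_error("bounds", "scaled_beta needs explicit bounds to scale onto")
  }
  structure(list(family = family, params = params, bounds = bounds,
                 transform = transform),
            class = "dist_spec")
}

# Inverse-CDF draw of n values from a spec, given uniforms u. `cap` supplies
# a dynamic upper bound (per draw) for trunc_exp specs without fixed bounds.
sample_dist <- function(spec, n, u = stats::runif(n), cap = NULL) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  lo <- if (is.null(spec$bounds)) -Inf else spec$bounds[1]
  hi <- if (is.null(spec$bounds)) Inf else spec$bounds[2]
  # bounds constrain the *final* value; map through the transform
  if (spec$transform == "one_minus") {
    raw_lo <- 1 - hi
    raw_hi <- 1 - lo
  } else {
    raw_lo <- lo
    raw_hi <- hi
  }
  x <- switch(spec$family,
    fixed = rep(p$value, n),
    normal = {
      a <- stats::pnorm(raw_lo, p$mean, p$sd)
      b <- stats::pnorm(raw_hi, p$mean, p$sd)
      if (b - a <= 0) validation_error("bounds", "no probability mass inside bounds")
      stats::qnorm(a + u * (b - a), p$mean, p$sd)
    },
    gamma = {
      a <- stats::pgamma(max(raw_lo, 0), p$shape, p$rate)
      b <- stats::pgamma(raw_hi, p$shape, p$rate)
      if (b - a <= 0) validation_error("bounds", "no probability mass inside bounds")
      stats::qgamma(a + u * (b - a), p$shape, p$rate)
    },
    scaled_beta = raw_lo + (raw_hi - raw_lo) * stats::qbeta(u, p$shape1, p$shape2),
    trunc_exp = {
      top <- if (!is.null(cap)) cap else raw_hi
      if (any(!is.finite(top))) validation_error("bounds", "trunc_exp needs a finite upper bound or cap")
      rate <- if (!is.null(p$rate)) rep_len(p$rate, n) else 1 / (p$mean_frac * pmax(top, .Machine$double.eps))
      out <- stats::qexp(u * stats::pexp(top, rate), rate)
      out[top <= 0] <- 0
      out
    }
  )
  if (spec$transform == "one_minus") x <- 1 - x
  # guard against numerical overshoot at the truncation edges
  pmin(pmax(x, lo), hi)
}

#' Default uncertainty distributions for a configuration
#'
#' One spec set per gene, encoding the structure of the published
#' sensitivity analysis: the CNV proportion and CNV sensitivity stay fixed
#' at their main-model values; the indel proportion varies on a truncated
#' normal centred at its main-model value (the SNV proportion absorbs the
#' complement so the spectrum still sums to 1); indel and SNV sensitivities
#' are one minus Gamma-distributed deficits; and false positives follow a
#' truncated exponential on `[0, fp_rate_cap * tp]`, heavily skewed towards
#' zero. The numeric dispersion parameters (sd 0.05 for the indel
#' proportion; Gamma shape 2 with mean deficits 0.20 for indels and 0.03
#' for SNVs; pre-truncation exponential mean at 20 % of the cap) are this
#' package's calibration choices — the distribution families are from the
#' published analysis but their numeric parameters are not, so every spec
#' is overridable.
#'
#' @param config a [screen_config()].
#' @return named list (per gene) of named lists of [dist_spec()] objects
#'   with elements `p_indel`, `sens_indel`, `sens_snv`, `fp`.
#' @export
default_mc_specs <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  lapply(config$genes, function(g) {
    list(
      p_indel = dist_spec("normal",
                          list(mean = g$spectrum$p_indel, sd = 0.05),
                          bounds = c(0, 1 - g$spectrum$p_cnv)),
      sens_indel = dist_spec("gamma",
                             list(shape = 2, rate = 2 / (1 - config$platform$sens_indel)),
                             transform = "one_minus", bounds = c(0, 1)),
      sens_snv = dist_spec("gamma",
                           list(shape = 2, rate = 2 / (1 - config$platform$sens_snv)),
                           transform = "one_minus", bounds = c(0, 1)),
      fp = dist_spec("trunc_exp", list(mean_frac = 0.2))
    )
  })
}

#' Monte Carlo run settings
#'
#' @param n_replicates number of model re-runs (default 100,000).
#' @param seed root RNG seed; each gene gets its own deterministic
#'   substream so adding a gene does not perturb another gene's draws.
#' @param specs per-gene uncertainty distributions as produced by
#'   [default_mc_specs()]; `NULL` means derive defaults from the
#'   configuration at run time. Per-gene entries may override any subset of
#'   `p_indel`, `sens_indel`, `sens_snv`, `fp`.
#' @param fp_rate_cap false positives in each replicate are capped at this
#'   fraction of that replicate's true positives (default 0.10).
#' @param count_sampling if `TRUE`, add a binomial count-level draw per
#'   replicate (integer cohorts); the default `FALSE` evaluates the
#'   deterministic expected cells at the sampled parameters, which is how
#'   the published analysis is described.
#' @return an object of class `mc_config`.
#' @export
mc_config <- function(n_replicates = 100000L, seed = 1L, specs = NULL,
                      fp_rate_cap = 0.1, count_sampling = FALSE) {
  structure(list(
    n_replicates = check_count(n_replicates, "n_replicates"),
    seed = check_count(seed, "seed"),
    specs = specs,
    fp_rate_cap = check_prob(fp_rate_cap, "fp_rate_cap"),
    count_sampling = isTRUE(count_sampling)
  ), class = "mc_config")
}

# Deterministic per-gene substream seed below 2^31.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 1048573 * index) %% 2147483647)
}

#' Draw perturbed model inputs for one gene
#'
#' Vectorised draw of `n` parameter sets under the given specs. The CNV
#' proportion is held at the gene's main-model value and the SNV proportion
#' is set to the remaining mass after the indel draw, so every sampled
#' spectrum sums to 1 by construction; the CNV sensitivity is held at the
#' platform's main-model value. The false-positive draw is capped at
#' `fp_rate_cap` times the replicate's own true-positive count.
#'
#' Uses the current RNG state; seed beforehand for reproducibility (or use
#' [run_mc()], which manages substreams).
#'
#' @param gene a [gene_model()].
#' @param platform a [platform_performance()].
#' @param pop a [population_config()].
#' @param specs named list of [dist_spec()]s (`p_indel`, `sens_indel`,
#'   `sens_snv`, `fp`), e.g. one element of [default_mc_specs()].
#' @param n number of draws.
#' @param fp_rate_cap cap on false positives as a fraction of true positives.
#' @return data.frame with one row per draw: `p_indel`, `p_snv`, `p_cnv`,
#'   `sens_indel`, `sens_snv`, `sens_cnv`, `tp`, `fp`, `fn`, `tn`.
#' @export
sample_parameters <- function(gene, platform, pop, specs, n = 1L,
                              fp_rate_cap = 0.1) {
  stopifnot(inherits(gene, "gene_model"), inherits(platform, "platform_performance"),
            inherits(pop, "population_config"))
  for (nm in c("p_indel", "sens_indel", "sens_snv", "fp")) {
    if (!inherits(specs[[nm]], "dist_spec")) {
      validation_error(nm, "specs must supply a dist_spec for this parameter")
    }
  }
  p_cnv <- gene$spectrum$p_cnv
  sens_cnv <- platform$sens_cnv
  # fixed draw order so results are reproducible under a given seed
  p_indel <- sample_dist(specs$p_indel, n)
  sens_indel <- sample_dist(specs$sens_indel, n)
  sens_snv <- sample_dist(specs$sens_snv, n)
  u_fp <- stats::runif(n)
  p_snv <- (1 - p_cnv) - p_indel
  carriers <- gene$prevalence * pop$size
  tp <- carriers * (p_indel * sens_indel + p_snv * sens_snv + p_cnv * sens_cnv) *
    gene$coverage
  fp <- sample_dist(specs$fp, n, u = u_fp, cap = fp_rate_cap * tp)
  fp <- pmin(fp, fp_rate_cap * tp)
  data.frame(
    p_indel = p_indel, p_snv = p_snv, p_cnv = p_cnv,
    sens_indel = sens_indel, sens_snv = sens_snv, sens_cnv = sens_cnv,
    tp = tp, fp = fp, fn = carriers - tp,
    tn = pop$size - carriers - fp
  )
}

#' Run the Monte Carlo sensitivity analysis
#'
#' Re-evaluates the deterministic confusion-matrix model `n_replicates`
#' times per gene with inputs drawn from the uncertainty distributions, and
#' summarises each cell's replicate distribution (mean, SD, median,
#' quartiles, min, max). Within each replicate the cell calculation is
#' identical to the main model — only the inputs vary — unless
#' `count_sampling` adds a binomial draw on top.
#'
#' @param config a [screen_config()].
#' @param mc an [mc_config()] (or `NULL` for defaults).
#' @param keep_replicates if `TRUE`, attach the full per-replicate cell
#'   table.
#' @return an object of class `mc_summary`: `$summary` is a data.frame with
#'   one row per gene x cell and columns `mean`, `sd`, `median`, `q1`, `q3`,
#'   `min`, `max`; `$replicates` (optional) holds per-replicate cells.
#'   Identical config and seed give identical output.
#' @examples
#' mc <- run_mc(brca_preset(), mc_config(n_replicates = 1000, seed = 7))
#' subset(mc$summary, cell == "tp")
#' @export
run_mc <- function(config, mc = mc_config(), keep_replicates = FALSE) {
  stopifnot(inherits(config, "screen_config"), inherits(mc, "mc_config"))
  specs <- mc$specs %||% default_mc_specs(config)
  defaults <- default_mc_specs(config)
  n <- mc$n_replicates
  pop <- config$population
  summaries <- list()
  reps <- list()
  for (i in seq_along(config$genes)) {
    gene <- config$genes[[i]]
    gene_specs <- defaults[[gene$name]]
    for (nm in names(specs[[gene$name]] %||% list())) {
      gene_specs[[nm]] <- specs[[gene$name]][[nm]]
    }
    set.seed(substream_seed(mc$seed, i))
    draws <- sample_parameters(gene, config$platform, pop, gene_specs,
                               n = n, fp_rate_cap = mc$fp_rate_cap)
    cells <- draws[c("tp", "fp", "fn", "tn")]
    if (mc$count_sampling) {
      carriers <- round_half_away(gene$prevalence * pop$size)
      p_detect <- pmin(pmax(draws$tp / (gene$prevalence * pop$size), 0), 1)
      cells$tp <- stats::rbinom(n, carriers, p_detect)
      cells$fn <- carriers - cells$tp
      cells$fp <- round_half_away(draws$fp)
      cells$tn <- pop$size - carriers - cells$fp
    }
    summaries[[gene$name]] <- do.call(rbind, lapply(
      c("tp", "fp", "fn", "tn"),
      function(cell) {
        x <- cells[[cell]]
        q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
        data.frame(gene = gene$name, cell = cell, mean = mean(x),
                   sd = stats::sd(x), median = q[2], q1 = q[1], q3 = q[3],
                   min = min(x), max = max(x), row.names = NULL)
      }
    ))
    if (keep_replicates) {
      reps[[gene$name]] <- cbind(gene = gene$name, replicate = seq_len(n), cells)
    }
  }
  structure(list(
    summary = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
    replicates = if (keep_replicates) do.call(rbind, c(reps, list(make.row.names = FALSE))),
    n_replicates = n,
    seed = mc$seed,
    fp_rate_cap = mc$fp_rate_cap,
    count_sampling = mc$count_sampling
  ), class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("Monte Carlo sensitivity analysis: %s replicates, seed %d\n",
              format(x$n_replicates, big.mark = ","), x$seed))
  s <- x$summary
  for (g in unique(s$gene)) {
    cat(sprintf("  %s\n", g))
    sg <- s[s$gene == g, ]
    for (j in seq_len(nrow(sg))) {
      r <- sg[j, ]
      cat(sprintf("    %-3s mean %s (SD %.1f)  median %s (IQR %s-%s)  min %s  max %s\n",
                  r$cell,
                  format(round_half_away(r$mean), big.mark = ","), r$sd,
                  format(round_half_away(r$median), big.mark = ","),
                  format(round_half_away(r$q1), big.mark = ","),
                  format(round_half_away(r$q3), big.mark = ","),
                  format(round_half_away(r$min), big.mark = ","),
                  format(round_half_away(r$max), big.mark = ",")))
    }
  }
  invisible(x)
}
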