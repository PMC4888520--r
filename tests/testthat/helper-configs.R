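# Shared fixtures, built in code.

# A minimal single-gene configuration with easy round numbers.
toy_config <- function(prevalence = 0.01, coverage = 1,
                       sens = c(indel = 1, snv = 1, cnv = 1),
                       spectrum = c(0.5, 0.4, 0.1),
                       penetrance = penetrance_estimate(0.5, 0.4, 0.6),
                       size = 10000L, background_risk = 0.1) {
  screen_config(
    genes = list(gene_model("G1", prevalence,
                            mutation_spectrum(spectrum[1], spectrum[2], spectrum[3]),
                            coverage, penetrance)),
    platform = platform_performance(sens[["indel"]], sens[["snv"]], sens[["cnv"]]),
    population = population_config(size, background_risk)
  )
}

# Point-mass Monte Carlo specs that reproduce a configuration's main model
# in every replicate.
degenerate_specs <- function(config) {
  lapply(config$genes, function(g) {
    list(
      p_indel = dist_spec("fixed", list(value = g$spectrum$p_indel)),
      sens_indel = dist_spec("fixed", list(value = config$platform$sens_indel)),
      sens_snv = dist_spec("fixed", list(value = config$platform$sens_snv)),
      fp = dist_spec("fixed", list(value = 0))
    )
  })
}
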