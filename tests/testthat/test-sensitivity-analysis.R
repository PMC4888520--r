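test_that("point-mass specs collapse every replicate to the main model", {
  cfg <- brca_preset()
  mc <- run_mc(cfg, mc_config(n_replicates = 500, seed = 11,
                              specs = degenerate_specs(cfg)),
               keep_replicates = TRUE)
  s <- mc$summary
  tp1 <- s[s$gene == "BRCA1" & s$cell == "tp", ]
  expect_equal(tp1$mean, 93.1909104, tolerance = 1e-9)
  expect_identical(tp1$sd, 0)
  expect_identical(tp1$min, tp1$max)
  expect_true(all(s$sd == 0))
  expect_equal(s[s$gene == "BRCA2" & s$cell == "tp", "mean"], 151.094658,
               tolerance = 1e-9)
  expect_true(all(mc$replicates$fp == 0))
})

test_that("runs are bit-reproducible under a fixed seed", {
  cfg <- brca_preset()
  a <- run_mc(cfg, mc_config(n_replicates = 2000, seed = 99), keep_replicates = TRUE)
  b <- run_mc(cfg, mc_config(n_replicates = 2000, seed = 99), keep_replicates = TRUE)
  expect_identical(a$summary, b$summary)
  expect_identical(a$replicates, b$replicates)
  c <- run_mc(cfg, mc_config(n_replicates = 2000, seed = 100))
  expect_false(identical(a$summary, c$summary))
})

test_that("per-gene substreams isolate genes from panel composition", {
  cfg <- brca_preset()
  solo <- cfg
  solo$genes <- cfg$genes["BRCA1"]
  both <- run_mc(cfg, mc_config(n_replicates = 1000, seed = 5))
  alone <- run_mc(solo, mc_config(n_replicates = 1000, seed = 5))
  expect_identical(both$summary[both$summary$gene == "BRCA1", ],
                   alone$summary[alone$summary$gene == "BRCA1", ])
})

test_that("every replicate conserves the population and respects constraints", {
  cfg <- brca_preset()
  mc <- run_mc(cfg, mc_config(n_replicates = 5000, seed = 21), keep_replicates = TRUE)
  r <- mc$replicates
  expect_equal(r$tp + r$fp + r$fn + r$tn,
               rep(cfg$population$size, nrow(r)), tolerance = 1e-9)
  expect_true(all(r$fp <= 0.1 * r$tp + 1e-12))
  expect_true(all(r$fp >= 0))
  s <- mc$summary
  expect_true(all(s$min <= s$q1 & s$q1 <= s$median &
                  s$median <= s$q3 & s$q3 <= s$max))
  expect_true(all(s$sd >= 0))
})

test_that("sampled parameter sets stay on the simplex with valid sensitivities", {
  cfg <- brca_preset()
  specs <- default_mc_specs(cfg)
  set.seed(31)
  draws <- sample_parameters(cfg$genes$BRCA1, cfg$platform, cfg$population,
                             specs$BRCA1, n = 5000)
  expect_equal(draws$p_indel + draws$p_snv + draws$p_cnv,
               rep(1, 5000), tolerance = 1e-12)
  expect_true(all(draws$p_cnv == 0.1))       # held at main-model value
  expect_true(all(draws$sens_cnv == 0))      # held at main-model value
  expect_true(all(draws$sens_indel >= 0 & draws$sens_indel <= 1))
  expect_true(all(draws$sens_snv >= 0 & draws$sens_snv <= 1))
  expect_true(all(draws$p_indel >= 0 & draws$p_indel <= 0.9))
})

test_that("truncated-normal draws match the closed-form truncated mean", {
  # oracle: E[X | a < X < b] = mu + sd * (phi(alpha) - phi(beta)) / (Phi(beta) - Phi(alpha))
  mu <- 0.54; sd <- 0.05; lo <- 0; hi <- 0.9
  alpha <- (lo - mu) / sd; beta <- (hi - mu) / sd
  truth <- mu + sd * (dnorm(alpha) - dnorm(beta)) / (pnorm(beta) - pnorm(alpha))

  spec <- dist_spec("normal", list(mean = mu, sd = sd), bounds = c(lo, hi))
  set.seed(77)
  x <- screenval:::sample_dist(spec, 10000)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - truth), 3 * se)
  expect_true(all(x >= lo & x <= hi))
})

test_that("infeasible truncation bounds raise a configuration error", {
  bad <- dist_spec("normal", list(mean = 10, sd = 1e-6), bounds = c(0, 1))
  expect_error(screenval:::sample_dist(bad, 10), "bounds",
               class = "screenval_validation_error")
  expect_error(dist_spec("normal", list(mean = 0.5)), "sd",
               class = "screenval_validation_error")
  expect_error(dist_spec("scaled_beta", list(shape1 = 2, shape2 = 2)), "bounds",
               class = "screenval_validation_error")
})

test_that("raising the indel-sensitivity distribution cannot lower mean true positives", {
  cfg <- brca_preset()
  specs_lo <- default_mc_specs(cfg)
  specs_hi <- default_mc_specs(cfg)
  for (g in names(specs_hi)) {
    # smaller mean deficit = distribution shifted towards perfect sensitivity
    specs_hi[[g]]$sens_indel <- dist_spec("gamma", list(shape = 2, rate = 2 / 0.05),
                                          transform = "one_minus", bounds = c(0, 1))
  }
  lo <- run_mc(cfg, mc_config(n_replicates = 4000, seed = 13, specs = specs_lo))
  hi <- run_mc(cfg, mc_config(n_replicates = 4000, seed = 13, specs = specs_hi))
  for (g in c("BRCA1", "BRCA2")) {
    expect_gte(hi$summary[hi$summary$gene == g & hi$summary$cell == "tp", "mean"],
               lo$summary[lo$summary$gene == g & lo$summary$cell == "tp", "mean"])
  }
})

test_that("count-sampling mode yields integer cohorts that still conserve the population", {
  cfg <- brca_preset()
  mc <- run_mc(cfg, mc_config(n_replicates = 2000, seed = 17, count_sampling = TRUE),
               keep_replicates = TRUE)
  r <- mc$replicates
  expect_true(all(r$tp == floor(r$tp)))
  expect_true(all(r$fp == floor(r$fp)))
  expect_equal(r$tp + r$fp + r$fn + r$tn, rep(cfg$population$size, nrow(r)),
               tolerance = 1e-9)
})
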