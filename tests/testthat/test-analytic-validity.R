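# Continuous expectations below were computed independently by hand from the
# defining formula (prevalence x N x spectrum-weighted sensitivity x coverage)
# in a plain R session, then frozen:
#   BRCA1: 0.0012*1e5*(0.54*0.8 + 0.36*0.97 + 0.1*0)*0.9941 = 93.1909104
#   BRCA2: 0.002 *1e5*(0.69*0.8 + 0.21*0.97 + 0.1*0)*0.9997 = 151.094658

test_that("expected confusion cells match hand-computed values for both genes", {
  cfg <- brca_preset()
  b1 <- expected_confusion(cfg$genes$BRCA1, cfg$platform, cfg$population)
  b2 <- expected_confusion(cfg$genes$BRCA2, cfg$platform, cfg$population)

  expect_equal(b1$tp, 93.1909104, tolerance = 1e-12)
  expect_equal(b2$tp, 151.094658, tolerance = 1e-12)
  expect_equal(b1$fn, 120 - 93.1909104, tolerance = 1e-12)
  expect_equal(b2$fn, 200 - 151.094658, tolerance = 1e-12)

  expect_identical(b1$rounded, c(tp = 93, fp = 0, fn = 27, tn = 99880))
  expect_identical(b2$rounded, c(tp = 151, fp = 0, fn = 49, tn = 99800))
})

test_that("degenerate inputs behave as expected", {
  cfg <- toy_config(prevalence = 0)
  cc <- expected_confusion(cfg$genes$G1, cfg$platform, cfg$population)
  expect_identical(c(cc$tp, cc$fn), c(0, 0))
  expect_identical(cc$tn, cfg$population$size - 0)

  # perfect assay: every carrier detected
  cfg <- toy_config(prevalence = 0.03, coverage = 1)
  cc <- expected_confusion(cfg$genes$G1, cfg$platform, cfg$population)
  expect_equal(cc$tp, 0.03 * 10000, tolerance = 1e-12)

  # a supplied false-positive count shifts tn, not the carrier cells
  cc_fp <- expected_confusion(cfg$genes$G1, cfg$platform, cfg$population,
                              fp_count = 12.5)
  expect_identical(cc_fp$fp, 12.5)
  expect_equal(cc_fp$tn, 10000 - 300 - 12.5, tolerance = 1e-12)
  expect_identical(cc_fp$tp, cc$tp)
})

test_that("cells always conserve the population and stay non-negative", {
  set.seed(101)
  for (i in 1:25) {
    p <- sort(stats::runif(2))
    spectrum <- c(p[1], p[2] - p[1], 1 - p[2])
    cfg <- toy_config(
      prevalence = stats::runif(1, 0, 0.05),
      coverage = stats::runif(1),
      sens = c(indel = stats::runif(1), snv = stats::runif(1), cnv = stats::runif(1)),
      spectrum = spectrum,
      size = sample(1000:500000, 1)
    )
    cc <- expected_confusion(cfg$genes$G1, cfg$platform, cfg$population,
                             fp_count = stats::runif(1, 0, 5))
    expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, cfg$population$size,
                 tolerance = 1e-9)
    expect_true(all(c(cc$tp, cc$fp, cc$fn, cc$tn) >= 0))
    expect_equal(cc$tp + cc$fn, cfg$genes$G1$prevalence * cfg$population$size,
                 tolerance = 1e-9)
  }
})

test_that("expected true positives are monotone in every driver", {
  base <- list(prevalence = 0.001, coverage = 0.9, sens_indel = 0.5,
               sens_snv = 0.5, sens_cnv = 0.5, size = 100000L)
  tp_of <- function(args) {
    cfg <- toy_config(prevalence = args$prevalence, coverage = args$coverage,
                      sens = c(indel = args$sens_indel, snv = args$sens_snv,
                               cnv = args$sens_cnv),
                      size = args$size)
    expected_confusion(cfg$genes$G1, cfg$platform, cfg$population)$tp
  }
  tp0 <- tp_of(base)
  for (driver in names(base)) {
    bumped <- base
    bumped[[driver]] <- if (driver == "size") 150000L else base[[driver]] * 1.1
    expect_gt(tp_of(bumped), tp0)
  }
})

test_that("metrics derive from rounded cells and flag undefined ratios", {
  cfg <- brca_preset()
  av <- analytic_validity(cfg)

  m1 <- av$BRCA1$metrics
  expect_identical(m1$sensitivity, 93 / 120)      # 0.775, not continuous 0.7766
  expect_identical(m1$specificity, 1)
  expect_identical(m1$ppv, 1)
  expect_equal(m1$npv, 99880 / 99907, tolerance = 1e-12)
  expect_true(m1$npv >= 0.999)

  m2 <- av$BRCA2$metrics
  expect_identical(m2$sensitivity, 151 / 200)     # 0.755
  expect_true(m2$npv >= 0.999)

  # the continuous view is exposed and differs from the rounded one
  m1c <- performance_metrics(av$BRCA1$counts, use = "continuous")
  expect_equal(m1c$sensitivity, 93.1909104 / 120, tolerance = 1e-9)

  # empty positive class: sensitivity undefined, not silently zero
  empty <- confusion_counts("G", tp = 0, fp = 0, fn = 0, tn = 1000)
  m <- performance_metrics(empty)
  expect_true(is.na(m$sensitivity))
  expect_false(m$defined[["sensitivity"]])
  expect_true(is.na(m$ppv))
  expect_identical(m$specificity, 1)
  expect_identical(m$npv, 1)
})

test_that("rounding is half away from zero, not banker's", {
  expect_identical(round_half_away(c(0.5, 1.5, 2.5, -0.5, -1.5)),
                   c(1, 2, 3, -1, -2))
  expect_identical(round_half_away(93.1909104), 93)
})
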