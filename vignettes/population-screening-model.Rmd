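---
title: "Modelling WGS test performance for population BRCA screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling WGS test performance for population BRCA screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenval)
```

## The question the model answers

When whole genome sequencing (WGS) is applied to people with no particular
risk indication — for example when pathogenic *BRCA1*/*BRCA2* variants are
actively sought as secondary findings in a national sequencing programme —
how many mutation carriers would actually be found, how many would be
missed, and what do those test outcomes mean for future breast-cancer
incidence? `screenval` implements a deterministic expected-count model of
this screening situation, a Monte Carlo probabilistic sensitivity analysis
over its uncertain inputs, a penetrance-based clinical-validity projection,
and an individual-level cohort simulator used as a stochastic oracle for
all of the closed-form results.

## The deterministic model

For one gene in a screened population of $N$ women with carrier prevalence
$\pi$, mutation-class spectrum $(p_\text{indel}, p_\text{snv},
p_\text{cnv})$ summing to 1, per-class platform detection sensitivities
$(s_\text{indel}, s_\text{snv}, s_\text{cnv})$ and horizontal coverage $c$
of the gene region, the expected confusion-matrix cells are

$$
\begin{aligned}
\mathrm{TP} &= \pi N \left(p_\text{indel} s_\text{indel}
  + p_\text{snv} s_\text{snv} + p_\text{cnv} s_\text{cnv}\right) c \\
\mathrm{FN} &= \pi N - \mathrm{TP} \\
\mathrm{FP} &= f \quad (\text{default } 0) \\
\mathrm{TN} &= N - \pi N - \mathrm{FP}.
\end{aligned}
$$

The default $\mathrm{FP} = 0$ encodes the laboratory assumption that every
positive call is confirmed by an orthogonal assay (a fresh DNA dilution or
a SNP array), so platform false positives do not reach the report. Variants
of uncertain significance are assumed not to be reported and are therefore
absorbed into the true negatives rather than given their own cell. The
per-class specificities are still carried in `platform_performance()` so
that non-zero false-positive regimes can be expressed; the sensitivity
analysis draws a false-positive count directly instead.

Analytic performance metrics are the usual ratios: sensitivity
$\mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$, specificity
$\mathrm{TN}/(\mathrm{TN}+\mathrm{FP})$, PPV
$\mathrm{TP}/(\mathrm{TP}+\mathrm{FP})$, NPV
$\mathrm{TN}/(\mathrm{TN}+\mathrm{FN})$. A ratio with a zero denominator is
reported as `NA` and flagged in `$defined`, never silently coerced to 0.

### Rounding conventions

Whole-cohort results are conventionally reported as integer counts of
women. Two choices matter and both are deliberate:

* Cells are rounded **half away from zero** (`round_half_away()`), not with
  base R's round-half-even.
* Metrics are computed **from the rounded cells**. With the shipped preset
  the continuous BRCA1 expectation is 93.19 detected carriers out of 120,
  i.e. 77.7 %; the reported whole-cohort figure is 93/120 = 77.5 %. Working
  from rounded cells is what makes percentage and table mutually
  consistent. The continuous view is always available
  (`performance_metrics(counts, use = "continuous")`).

One consequence is worth knowing: the BRCA1 NPV is 99880/99907 = 0.99973,
which rounds to 100.0 % at one decimal. Summaries that quote "99.9 %" for
such values are truncating rather than rounding; `screenval` reports the
round-half-away percentage and always exposes the raw proportion, and its
own checks assert NPV ≥ 0.999 rather than a one-decimal string.

## The shipped parameter preset

`brca_preset()` returns the main-analysis inputs for 100,000 unselected UK
women (all proportions are lifetime or per-woman probabilities):

| Parameter | BRCA1 | BRCA2 |
|---|---|---|
| Carrier prevalence | 0.0012 | 0.002 |
| Spectrum indel / SNV / CNV | 0.54 / 0.36 / 0.10 | 0.69 / 0.21 / 0.10 |
| Horizontal coverage | 0.9941 | 0.9997 |
| Platform sensitivity indel / SNV / CNV | 0.8 / 0.97 / 0 | same |
| Penetrance, central (range) | 0.59 (0.57–0.71) | 0.51 (0.45–0.875) |
| Background lifetime risk | 0.125 | shared |

Any configuration can instead be supplied as a YAML file
(`load_config()` / `save_config()`; an example ships in
`inst/extdata/brca_main_analysis.yaml`). Validation checks every proportion
is in $[0,1]$ and every spectrum sums to 1 within $10^{-9}$ — a tolerance
chosen so a text round trip of the proportions can never trip the
invariant.

## Monte Carlo sensitivity analysis

`run_mc()` re-evaluates the deterministic model many times (default
100,000 replicates) with inputs drawn from per-parameter uncertainty
distributions, then summarises each cell's replicate distribution (mean,
SD, median, quartiles by linear interpolation — R's default type-7
quantiles — min, max). Within a replicate the cell calculation is exactly
the main model; only inputs vary. An optional `count_sampling` mode adds a
binomial draw per replicate for users who want realised integer cohorts
rather than expectations.

The structure of the default distributions is fixed by the screening
situation being modelled: the CNV share of the spectrum and the (zero) CNV
sensitivity stay at their main-model values; the indel share follows a
truncated normal, with the SNV share taking the remaining mass so every
sampled spectrum sums to 1 by construction; the indel and SNV sensitivities
are one minus Gamma-distributed deficits; and the false-positive count
follows an exponential truncated to $[0, 0.1 \cdot \mathrm{TP}]$ of the
same replicate — at most 10 % of true positives, heavily skewed towards
zero. The *numeric* dispersion parameters are this package's calibration
choices, because only the families, not their parameters, are published:

* indel share: SD 0.05 on the truncated normal — a spread wide enough to
  cover the variation between published mutation-spectrum series without
  letting the indel share collapse below zero or swallow the SNV share;
* sensitivity deficits: Gamma with shape 2 and mean deficit $1 -$ the
  main-model sensitivity (0.20 for indels, 0.03 for SNVs), so each
  sensitivity distribution is centred on its main-model value with a
  right-skewed tail towards poorer performance;
* false positives: pre-truncation exponential mean at 20 % of the cap,
  concentrating mass near zero.

All of these are overridable per gene and per parameter via
`mc_config(specs = ...)`, and `dist_spec()` additionally offers point
masses and scaled Beta distributions. Carrier prevalence is *not* varied by
default: it is listed among the fixed inputs of the analysis being
modelled, and we keep it fixed rather than tuning extra spread into the
replicates. Published replicate spreads obtained with unpublished
distribution parameters are therefore *not* reproduction targets; the
package's own contracts are the ones tested (degenerate point-mass specs
collapse every replicate onto the main model with zero SD, seeded runs are
bit-identical, every replicate conserves the population, and the main-model
true-positive count falls inside the replicate distribution's central 95 %
interval).

Sampling uses inverse-CDF draws throughout, so truncation bounds are
respected exactly and draws are monotone in the underlying uniforms —
shifting a location parameter upward can only move paired draws upward,
which makes the monotonicity stress tests exact rather than statistical.
Each gene consumes its own deterministically derived substream of the root
seed, so adding a gene to the panel never perturbs another gene's draws.

## Clinical validity

`project_cancers()` converts test outcomes into expected breast-cancer
counts: carriers accrue cancer at their gene's lifetime penetrance whether
detected (true positives) or missed (false negatives); women without a
modelled mutation accrue the background lifetime risk. The
penetrance range (low/high) propagates to a projection range. Conventions,
chosen to keep whole-cohort reporting self-consistent:

* penetrance is applied to the **rounded** cells (the reported cohort), and
  the resulting expectation is rounded **after** summing across genes —
  with the preset this yields 132 (range 121–198) expected cancers among
  the 244 women with correctly identified mutations;
* the true-negative pool is counted once across the whole panel
  ($N -$ all carriers $-$ FP $= 99{,}680$ women here, 12,460 expected
  cancers at 12.5 % background risk), while each gene's false negatives
  get that gene's penetrance, not background risk;
* false positives carry no mutation, so they accrue background risk;
* double carriers are ignored (prevalences treated as disjoint); at these
  carrier frequencies the error is below one woman per hundred thousand.

One range endpoint deserves a note: the false-negative lower bound computed
under these conventions is $27 \times 0.57 + 49 \times 0.45 = 37.4
\rightarrow 37$. A published figure of 36 for this quantity matches the
Monte-Carlo mean false-negative counts (26 and 48) rather than the
deterministic cells; `screenval` reports the deterministic 37 and does not
force agreement.

`scenario_report()` condenses the projection into the four whole-panel
scenarios (identified carriers / analytic false positives / carriers
incorrectly reassured / true negatives including unreported VUS) and
derives the number of identified carriers not destined to develop cancer —
here $244 - 132 = 112$ women who would be offered risk-reducing
intervention without personal benefit.

## The cohort simulator as oracle

`simulate_cohort()` realises the model at the individual level: carrier
status by a single categorical draw over genes-plus-none (disjoint carriers
by construction), mutation class from the gene's spectrum, horizontal
coverage as an independent per-woman Bernoulli, detection as coverage AND a
Bernoulli at the class sensitivity, and lifetime cancer at the gene's
central penetrance or the background risk. Every closed-form expectation in
the package is checked against tabulations of this simulator: at
$n = 10^7$ every confusion cell and every scenario's cancer count must
fall within three binomial standard errors of its expectation, and does.

What the generator emulates is exactly the probabilistic structure of the
expectation formulas — which is its purpose, and also its limit. It does
not simulate reads, variant calling, or classification pipelines; coverage
is an independent lottery rather than a property of genomic position;
penetrance is a lifetime coin flip with no age structure, family history,
or risk-modifier correlation; and carriers of two genes do not occur. A
passing oracle suite therefore certifies the arithmetic of the model, not
the realism of any of these simplifications with respect to real screening
cohorts.

## Problem sizes and numerical choices

The deterministic model is a handful of products and runs in microseconds
at any population size. The default analysis sizes used throughout the
package's own checks are 100,000 Monte Carlo replicates per gene (a couple
of seconds, single core) and a simulated cohort of $10^7$ women (a few
seconds, vectorised, well under a gigabyte of memory); unit tests use
smaller cohorts where a looser statistical bound suffices. Seeds are plain
integers; every seed derived internally stays below $2^{31}$. Degenerate
inputs are handled explicitly: zero prevalence gives an empty carrier
class with the undefined sensitivity flagged rather than zeroed; an empty
gene panel renders header-only reports and exits cleanly.

## Known limitations

* No clinical-utility or intervention-effect modelling (uptake, efficacy
  and harms of surveillance, chemoprevention or surgery), no
  cost-effectiveness, and no survival/age structure — the projection stops
  at expected lifetime case counts per test outcome.
* Penetrance estimates for carriers without family history are themselves
  uncertain; the low/high range propagates that uncertainty crudely
  (applied uniformly, not sampled).
* The Monte Carlo defaults are calibration choices on published
  distribution families; conclusions about replicate spread should be
  drawn only after setting specs appropriate to the platform under study.
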