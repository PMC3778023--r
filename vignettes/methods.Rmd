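---
title: "Methods: CI-based risk categorisation from published summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CI-based risk categorisation from published summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskcat)
```

## The model

`riskcat` predicts disease risk from published per-factor summary
statistics rather than from individual-level training data. The model is
multiplicative and assumes risk-factor independence: a profile carrying
dosage $k_i \in \{0,1,2\}$ of genetic factor $i$ and exposure indicator
$x_e \in \{0,1\}$ has

$$\log OR = \sum_i k_i \log OR_i + \sum_e x_e \log OR_e, \qquad
  \mathrm{Var} = \sum_i k_i^2 \sigma_i^2 + \sum_e x_e \sigma_e^2,$$

relative to a profile with no risk factors. Consequences of the
multiplicative allelic-dosage form: a homozygote carries the allelic OR
squared, and its log-OR variance is four times the allelic variance
($k^2\sigma^2$). The same form is applied to the multi-allelic HLA-DRB1
locus — each of the two carried alleles contributes one allelic OR term —
because the source meta-analyses publish allelic, not genotype-level, ORs.
Known interactions (shared epitope × smoking, PTPN22 × HLA) are
deliberately not modelled: no reliable pooled interaction ORs exist, so the
independence assumption is retained and stated as a limitation.

### Per-factor precision

The categorisation machinery needs a variance for every published OR.
When a 95% CI is published (every bundled factor has one), the SE is
recovered directly as $(\log CI_{hi} - \log CI_{lo}) / (2z_{0.975})$
(`se_from_ci()`); this is the directly published precision. When only
discovery sample sizes are available, `se_from_counts()` applies Woolf's
formula to expected allele counts, with the case frequency implied by the
OR and the control frequency. The CI route is preferred because it makes
no assumption about the discovery design beyond Wald normality.

## Stage 1: the simulated population and the categoriser

Risk profiles are simulated from population frequencies: SNP dosages
$\mathrm{Binomial}(2, f)$ under HWE; the HLA allele pair as two
independent draws from a categorical distribution whose support is the
modelled four-digit alleles, a residual class per two-digit group (group
frequency minus its modelled subtypes, scored at the group OR), and an
"other" class (everything outside modelled groups, scoring nothing);
exposures as Bernoulli draws. Raw profile log ORs are computed relative
to the factor-free profile and then **calibrated** by subtracting
$\log(\overline{OR})$, the log of the arithmetic mean simulated OR, so
the population mean OR is exactly 1 and a mean-OR profile is the
baseline. The arithmetic mean was chosen because it keeps population mean
risk consistent with downstream prevalence scaling; a geometric option
(`mean_type = "geometric"`, centring the mean log OR) is retained for
sensitivity analysis.

Category boundaries are frozen from the simulated population
(`build_categoriser()`):

* the **baseline profile** is the simulated profile whose calibrated OR is
  nearest 1.0. Nearest-ness is not defined by the verbal description of
  the method, so ties are broken toward the smaller variance (the more
  precisely known profile);
* scanning profiles in ascending OR order, the **first elevated** profile
  is the first whose whole CI exceeds the baseline CI;
* a profile is *reduced* if its CI is entirely below the baseline CI,
  *average* if the CIs overlap, *high* if its CI is entirely above the
  first-elevated CI, and *elevated* otherwise.

Numerical conventions: duplicate simulated profiles (identical log OR and
variance) are collapsed to unique profiles with multiplicity before
scanning, so "the first elevated profile" is well defined; a CI touching
the baseline CI at a single endpoint counts as overlap (average), since
the non-average classes require strict separation; when no profile
separates from baseline, the elevated and high classes are simply
unreachable and everything not reduced is average.

Monte-Carlo size defaults to $m = 10^5$ profiles. For small models
(≤ 12 factors and ≤ $10^6$ profile states) the profile space is instead
enumerated exhaustively with its HWE/categorical probabilities, which is
exact and underlies the Monte-Carlo-versus-enumeration equivalence tests.
Identical `(config, m, seed)` reproduce the fit bit-for-bit.

## Stage 2: individual scoring

Individuals are scored with the same multiplicative rule, the same
calibration shift, and the frozen boundaries. HLA typing arrives at mixed
resolution; each allele slot is scored once, at the highest resolution at
which it is known. A two-digit-typed allele whose group contains modelled
four-digit subtypes uses the two-digit OR — no subtype is ever imputed. A
four-digit allele matching a modelled four-digit factor never also
contributes its parent group (no double counting); an unmodelled
four-digit subtype falls back to its group; alleles outside every
modelled group contribute log OR 0 and variance 0, i.e. are baseline.

Eligibility mirrors data availability: smoking models are evaluated in
males only (ever-smoking is a significant risk factor in men but not
women, and the bundled smoking OR is the male meta-analysis value), and a
person missing any modelled SNP, or both HLA alleles, is excluded from
the corresponding models rather than imputed. A person typed at a single
HLA allele is scored on the known allele and flagged
(`note = "single_hla_allele"`); the alternative — exclusion — would
discard a substantial fraction of real cohorts.

Lifetime risk multiplies published baseline lifetime risks (2.4% women,
1.1% men) by the summary OR, capped at 100%. No rare-disease correction
is applied because at the modelled prevalence ORs approximate relative
risks; the cap is an artifact decision (far beyond the range where the
approximation is meaningful).

## Key tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `m` | 1e5 | profiles | boundary Monte-Carlo error well below CI widths |
| `level` | 0.95 | — | the level the source CIs are published at |
| `prevalence` | 0.008 | proportion | UK seropositive RA prevalence scale; the method's verbal description cites an external prevalence source without printing a value, so this is a package choice |
| lifetime baselines | 2.4 / 1.1 | % | published US cohort lifetime risks (women/men) |
| smoking `exposure_prev` | 0.57 | proportion | male control ever-smoking rate in the first evaluation cohort |

## The synthetic cohort generator

`simulate_cohort()` exists because the original evaluation cohorts are
access-controlled. It generates the structure the analysis *assumes*:
profiles drawn exactly as in stage 1; sex assigned 50/50; ever-smoking by
sex-specific prevalence (defaults 0.57 male / 0.50 female); disease
status $\mathrm{Bernoulli}(\mathrm{expit}(\alpha + \log OR))$ with the
intercept $\alpha$ solved numerically (`solve_intercept()`, to within
$10^{-4}$ of the target prevalence) and rejection sampling to the
requested case/control counts; serostatus labels for cases (ACPA-positive
fraction 0.85, matching the published cohort tables, with no differential
genetics); onset ages for cases from a Weibull proportional-hazards model
(baseline shape 4, scale 52 years — median ≈ 47 years, matching published
mean onset ages — with hazard multiplier
$HR_{OR}^{\,OR\ score} \times HR_{smoke}^{\,smoker}$, defaults 1.026 per
HLA-model OR unit and 0.848 for ever-smoking, the published multivariate
hazard ratios); HLA typing degraded to the published resolution mix
(78% four-digit / 6% two-digit / 16% mixed); and MCAR missingness
(defaults: 0.5% per SNP call, 15% smoking, 4% onset).

What it deliberately does **not** emulate: linkage disequilibrium between
SNPs, population stratification, genotype-dependent smoking, sex effects
on disease risk other than smoking (so synthetic case series are not
female-predominant as real RA series are), differential genetics between
serostatus subsets, and informative missingness. Passing end-to-end tests
therefore demonstrates internal consistency of the pipeline — that the
method recovers what the generator encodes — not that the published
cohort-specific AUCs, category percentages or log-rank statistics are
reproduced; those depend on the access-controlled data and are only
mirrored directionally (HLA discriminates better than SNPs; high genetic
risk brings onset forward; ever-smoking delays it).

Ground truth is retained (`hla_true_*` columns and the `"truth"`
attribute) so that `recover_parameters()` can check the generator against
itself: one multivariable logistic regression of status on all
ground-truth dosage columns jointly estimates the generative conditional
log ORs (univariate fits would be attenuated by non-collapsibility).
Two-digit groups whose residual frequency is zero (every modelled group
member is a modelled four-digit subtype, e.g. `*03`, `*07`, `*10`) never
vary in the realised dosage matrix and are reported as inestimable rather
than counted against coverage.

## Problem sizes and numerical tolerances

The test suite and the acceptance script use: $m = 10^5$ population
profiles; synthetic cohorts of 2,000 + 2,000 for discrimination and
onset stratification and 10,000 + 10,000 for parameter recovery; 1,000
replicates for the type-I error of the DeLong and log-rank tests
(binomial 3·SE ≈ 0.02 around 0.05). Monte-Carlo assertions use
3·SE tolerances throughout. The log-rank statistic inverts its
covariance by pseudo-inverse so that degenerate risk sets (all events
tied) yield a zero statistic rather than an error; the paired DeLong test
reports $z = 0, p = 1$ for identical scores and refuses (with an error)
genuinely degenerate nonzero comparisons.

## Known limitations

* Independence of risk factors is assumed everywhere; where real
  interactions exist the combined ORs at the extremes will be biased.
* The categoriser freezes boundaries from one simulated population;
  boundary positions inherit Monte-Carlo error (repeat-seed agreement is
  tested to be within that error).
* Multivariate Cox modelling of onset is out of scope by design;
  `yora_export()` produces the tidy table for dedicated survival
  tooling, and only Kaplan–Meier estimation and the log-rank test are
  implemented natively.
* Lifetime-risk conversion ignores competing risks and secular trends in
  incidence; it is a communication device, not a calibrated absolute
  risk.
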