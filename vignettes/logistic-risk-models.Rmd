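---
title: "Building logistic disease-risk models from published SNP odds ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building logistic disease-risk models from published SNP odds ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snplogit)
```

## The problem

Risk variants for a common disease are discovered piecemeal: each
genome-wide association study reports an odds ratio (OR) and a population
allele frequency for one or a few SNPs, fitted in its own cohort. No single
published logistic model covers all known variants, and refitting one from
raw genotypes requires a large clinical study every time a new variant
appears. `snplogit` assembles the published summary statistics directly
into one calibrated logistic model, so the panel can be revised — markers
added, removed, or their ORs updated — by rebuilding the model on the new
catalog, with no new cohort.

## The model

The disease risk of a genotyped individual is

$$P \;=\; \frac{1}{1 + e^{-(\beta_0 + \sum_i \beta_i x_i)}},$$

with one term per catalogued SNP. The three ingredients are derived as
follows.

**Coefficients.** In logistic regression the OR for a one-unit change in a
covariate is $e^{\beta}$, so a published heterozygous odds ratio maps
directly onto a coefficient, $\beta_i = \ln OR_{het,i}$, without access to
the original genotype data (`betaFromOR()`).

**Genotype encoding.** Non-carriers take $x_i = 0$ and heterozygotes
$x_i = 1$. When the source study also reports a homozygous OR, the
homozygote is treated as a dummy variable with
$x_i = \ln OR_{hom,i} / \ln OR_{het,i}$, which makes its log-odds
contribution exactly $\ln OR_{hom,i}$ — no additivity assumption is
imposed on the two genotypes. When no homozygous OR exists, homozygotes
default to carrier coding ($x_i = 1$), the minimal assumption; an additive
alternative ($x_i = 2$) is available through `homEncoding = 2` in
`buildModel()`.

**Intercept.** If a variant contributes to disease in individuals, its
population-average contribution must be consistent with the
population-average risk. Writing $P_0$ for the stratum's average lifetime
risk and $\bar f_i$ for the population-expected value of $\beta_i x_i$,

$$\beta_0 \;=\; \ln\frac{P_0}{1 - P_0} - \sum_i \beta_i \bar f_i,$$

so the intercept absorbs everything the panel does not measure: unselected
variants and non-genetic risk factors alike (`calibrateIntercept()`).
Strata are arbitrary labels — typically sexes, because lifetime-risk
statistics are published by sex — each with its own $P_0$ and hence its own
$\beta_0$ over a shared coefficient vector.

### The two calibration rules

The population term $\bar f_i$ uses Hardy–Weinberg genotype frequencies
computed from the risk-allele frequency $f_i$: heterozygotes $2f_i(1-f_i)$,
risk homozygotes $f_i^2$ (`hweGenotypeFreqs()`). For a marker with both
ORs the contribution is the HWE-weighted sum

$$\beta_i \bar f_i = \ln(OR_{het})\,2f(1-f) + \ln(OR_{hom})\,f^2 .$$

For a marker with only a heterozygous OR, the default `"literature"`
calibration multiplies the coefficient by the allele frequency itself,
$\beta_i f_i$ — the convention established for this class of model, which
the shipped example panel reproduces cell by cell. That convention is not
the HWE expectation of $\beta_i x_i$ under carrier coding (which would be
$\beta_i\,(2f(1-f) + f^2)$), so the model's population-mean linear
predictor differs from $\mathrm{logit}(P_0)$ by a small documented offset
at such markers. The `"consistent"` calibration mode closes that gap by
using the HWE expectation of $\beta_i x_i$ under the model's own encoding
for every marker; it is off by default because the literature rule is the
established contract, and the test suite pins down the exact offset between
the two.

## Parameters that matter

| parameter | meaning | default | rationale |
|---|---|---|---|
| `threshold` (`filterByOR`) | minimum heterozygous OR for inclusion | 1.15 | customary curation bound for minor-effect variants; applies to the heterozygous OR only |
| `homEncoding` | $x$ for homozygotes without a homozygous OR | 1 | carrier coding; the minimal assumption when the literature is silent |
| `calibration` | population term for no-homozygous-OR markers | `"literature"` | reproduces the established arithmetic; `"consistent"` available |
| `missing` (`encodeProfiles`) | imputation of missing calls | `"zero"` | population-reference imputation, conservative and transparent; `"hwe"` imputes the HWE-expected $x$ |
| baselines $P_0$ | average lifetime risk per stratum | none (user input) | e.g. 0.0562 (men) / 0.0256 (women) for lung cancer in a Chinese population |

All arithmetic is carried at full double precision; three-decimal
coefficients and one-decimal relative risks are display conventions only
(`writeRiskReport()`).

## Predictions and intervals

`predictRisk()` is the exact inverse logit of the linear predictor, so
every predicted risk lies strictly in $(0,1)$ by construction — unlike
ratio-multiplication schemes, which can exceed 100%. The relative lifetime
risk is the absolute risk divided by the subject's stratum baseline $P_0$,
not by the cohort mean. Subjects are ranked by descending absolute risk;
ties share the smaller rank.

`riskInterval()` propagates the sampling uncertainty of the published ORs
through the delta method: each coefficient's variance is recovered from its
95% CI as $\big(\ln(CI_{hi}/CI_{lo}) / (2 \times 1.96)\big)^2$, the
linear-predictor variance is $\sum_i x_i^2\,\mathrm{var}(\beta_i)$
(coefficients independent, intercept fixed), and the bounds are the inverse
logit of $LP \pm 1.96\,SE$. The interval is deliberately labelled
approximate: it ignores covariance between markers, uncertainty in $P_0$
and in the allele frequencies.

## Missing genotypes

A missing call encodes as $x = 0$ — the subject is treated as a population
non-carrier at that site — and is counted in `nMissing`, which reports
flag. This biases risk toward the baseline, never away from it. The
alternative `"hwe"` mode imputes the HWE-expected encoding, which is
unbiased on the linear predictor but invents a fractional genotype; it is
opt-in for that reason. VCF input matches markers by rsID, never
auto-resolves strand flips, and warns on strand-ambiguous A/T and C/G
sites — silent strand guessing is a classic failure mode of polygenic
scores.

## What the simulator emulates — and what it does not

`simulateGenotypes()` draws genotypes per subject and marker with HWE
probabilities $\{(1-f)^2,\, 2f(1-f),\, f^2\}$, independently across
markers — exactly the assumptions the calibration makes. Its default
cohort, 38 men and 10 women, mirrors the validation cohort of the shipped
lung-cancer panel. `simulateCaseControl()` closes the loop on the
OR-to-coefficient correspondence: genotypes under HWE, disease status from
the calibrated single-SNP model, and the heterozygote-vs-non-carrier OR
recovered from the 2×2 table. Recovery is tested one SNP at a time because
marginal ORs from a multi-SNP logistic model do not equal the conditional
ORs that went in (non-collapsibility); a multi-SNP marginal check would
"fail" even with a perfect implementation.

The simulator does **not** emulate linkage disequilibrium between markers,
departures from HWE (inbreeding, population stratification), genotyping
error, or correlation between genotype and stratum. Passing tests
therefore show internal consistency of the algorithm under its own
assumptions — not that a real panel's published ORs are transferable to a
particular cohort, which additionally requires matched ancestry,
LD-independent markers, and comparable phenotype definitions.

## Numerical choices and degenerate inputs

- Validation sizes: genotype-frequency recovery uses 10 000 subjects
  (±3 SE band around the HWE expectations); case/control recovery uses
  200 000 subjects per draw, three independent draws per marker, requiring
  the majority within 3 SE of the generating log-OR — a single-draw check
  at 95% would false-alarm a few percent of the time per marker.
- The brute-force equivalence check enumerates all $3^8 = 6561$ genotype
  combinations of the 8-SNP example panel and compares the engine against
  direct evaluation of the risk formula (agreement to $10^{-12}$).
- The calibration identity $\beta_0 + \sum_i \beta_i \bar f_i =
  \mathrm{logit}(P_0)$ is enforced as a class invariant (to $10^{-9}$ at
  validation, $10^{-12}$ in tests).
- An empty catalog is legal: $\beta_0 = \mathrm{logit}(P_0)$.
- An OR of exactly 1 gives a zero coefficient; if such a marker also
  carried a homozygous OR its dummy encoding would be undefined, and
  `buildModel()` rejects that combination.
- A zero cell in a simulated contingency table triggers a warning with
  seed guidance rather than silently returning an infinite OR.
- Every simulation requires an explicit seed; no wall-clock seeding.

## Known limitations

- The `"literature"` rule for markers without a homozygous OR uses
  $\beta f$, whose dimensional status (allele dosage vs carrier frequency)
  the source convention leaves ambiguous; we replicate it literally and
  provide the consistent mode as the alternative.
- Published ORs from different studies are combined as if estimated
  jointly; confounding structures and covariate adjustments differ across
  sources.
- Significance testing of individual-vs-cohort risks is out of scope; the
  package computes risks, ranks and stratum means, not p-values.
- No LD pruning is performed; supplying genetically dependent markers
  double-counts their effect, and marker selection remains the user's
  responsibility.
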