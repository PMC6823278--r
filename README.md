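# snplogit

Logistic disease-risk models assembled directly from published SNP odds
ratios.

Common diseases are linked to many SNPs of small effect, each reported in a
different genome-wide association study with its own odds ratio (OR) and
population allele frequency. `snplogit` integrates those summary statistics
into a single calibrated logistic model for individual risk prediction —
no refitting on raw genotypes, and the panel can be updated by simply
rebuilding on a revised marker table.

The model is

```
P = 1 / (1 + exp(-(b0 + sum_i b_i * x_i)))
```

* **Coefficients** — `b_i = ln(OR_het,i)`, straight from the literature.
* **Genotype encoding** — non-carrier `x = 0`, heterozygote `x = 1`;
  a homozygote is a dummy variable with `x = ln(OR_hom)/ln(OR_het)` when
  the homozygous OR is published (so its log-odds contribution is exactly
  `ln(OR_hom)`), else carrier-coded `x = 1`.
* **Intercept** — calibrated per stratum against the population's average
  lifetime risk `P0`: `b0 = logit(P0) - sum_i b_i * fbar_i`, where
  `fbar_i` weights the coefficients by Hardy–Weinberg genotype frequencies
  (`2f(1-f)` heterozygote, `f^2` homozygote) derived from the risk-allele
  frequency `f`.

Because the prediction is an inverse logit, every risk lies strictly
between 0 and 100% by construction. Relative lifetime risk is the absolute
risk divided by the stratum baseline `P0`.

The package ships an eight-SNP lung-cancer panel
(`inst/extdata/lung_markers.tsv`) with Chinese-population allele
frequencies and sex-specific baselines (men 5.62%, women 2.56%), a
genotype reader for VCF and tabular calls, a synthetic-cohort and
case/control simulator for validation, and a CLI (`inst/cli/snplogit.R`).

## Worked example

```r
library(snplogit)

tbl   <- system.file("extdata", "lung_markers.tsv", package = "snplogit")
base  <- system.file("extdata", "baselines_lung_china.tsv", package = "snplogit")
model <- buildModel(readMarkerTable(tbl, populationLabel = "Chinese"),
                    readBaselines(base))
model
```

```
LogisticRiskModel: 8 SNP(s), 2 stratum/strata [calibration: literature]
     snp_id  beta x_hom contribution
  rs1820453 0.399 1.256        0.174
   rs716274 0.604 1.796        0.294
  rs9981861 0.285 1.000        0.036
 rs16951095 0.262 1.000        0.211
  rs1051730 0.270 1.000        0.010
   rs402710 0.166 1.000        0.121
  rs2808630 0.199 1.000        0.044
  rs7626795 0.148 1.000        0.031
  contribution sum: 0.921
  beta0[men] = -3.742 (P0 = 0.0562)
  beta0[women] = -4.560 (P0 = 0.0256)
```

Each `beta` is the log of that SNP's heterozygous OR (e.g. rs1820453:
`ln 1.49 = 0.399`); `x_hom` is the homozygote's dummy-variable encoding
(`ln 1.65 / ln 1.49 = 1.256`); `contribution` is the HWE-weighted
population term entering calibration, and the intercepts satisfy
`b0 = logit(P0) - 0.921` for each sex.

Predict risks for a simulated cohort of 38 men and 10 women:

```r
cohort <- simulateGenotypes(model@catalog, n = c(men = 38, women = 10), seed = 42)
report <- predictRisk(encodeProfiles(cohort, model), model)
head(report, 3)
```

```
  subject_id stratum linear_predictor absolute_risk relative_risk n_missing rank
1       S009     men        -1.826736     0.1386275      2.466682         0    1
2       S001     men        -1.829893     0.1382510      2.459983         0    2
3       S028     men        -1.963495     0.1230893      2.190201         0    3
```

The top-ranked subject has a 13.9% absolute lifetime risk, 2.5 times the
male population baseline. `cohortSummary(report)$strata` gives per-stratum
mean risks; `riskInterval()` adds approximate delta-method intervals from
the published OR confidence limits.

From the shell:

```sh
Rscript inst/cli/snplogit.R build \
  --markers inst/extdata/lung_markers.tsv \
  --baselines inst/extdata/baselines_lung_china.tsv \
  --out-model model.json
Rscript inst/cli/snplogit.R simulate --markers inst/extdata/lung_markers.tsv \
  --seed 7 --out cohort.tsv
Rscript inst/cli/snplogit.R predict --model model.json --genotypes cohort.tsv \
  --out report.tsv
```

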