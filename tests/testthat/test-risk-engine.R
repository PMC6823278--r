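test_that("prediction is the exact inverse logit of the linear predictor", {
  model <- table1_model()
  prof <- simulateGenotypes(table1_catalog(), n = c(men = 30, women = 10),
                            seed = 7)
  rep <- predictRisk(encodeProfiles(prof, model), model)
  expect_true(all(rep$absolute_risk > 0 & rep$absolute_risk < 1))
  expect_equal(qlogis(rep$absolute_risk), rep$linear_predictor,
               tolerance = 1e-12)
  expect_equal(rep$relative_risk,
               rep$absolute_risk / baselines(model)[rep$stratum],
               tolerance = 1e-15, ignore_attr = TRUE)
  # sorted descending, ranks 1-based
  expect_true(all(diff(rep$absolute_risk) <= 0))
  expect_identical(rep$rank[1], 1L)
})

test_that("a non-carrier male subject lands on the baseline-only risk", {
  model <- table1_model()
  calls <- matrix("non_carrier", 1, 8,
                  dimnames = list(NULL, modelCoefficients(model)$snp_id))
  rep <- predictRisk(encodeProfiles(make_profiles(calls), model), model)
  expect_equal(rep$linear_predictor, intercepts(model)[["men"]],
               tolerance = 1e-12)
  expect_equal(round(rep$absolute_risk, 4), 0.0232)
})

test_that("risk is monotone in each genotype and bounded away from 0 and 1", {
  model <- table1_model()
  cf <- modelCoefficients(model)
  base <- matrix("non_carrier", 1, 8, dimnames = list(NULL, cf$snp_id))
  p_prev <- predictRisk(encodeProfiles(make_profiles(base), model),
                        model)$absolute_risk
  for (s in cf$snp_id) {
    for (g in c("heterozygous", "homozygous_risk")) {
      calls <- base; calls[1, s] <- g
      p <- predictRisk(encodeProfiles(make_profiles(calls), model),
                       model)$absolute_risk
      expect_gt(p, p_prev)  # every beta > 0, x_hom >= 1
      expect_lt(p, 1)
    }
  }
  # even the maximal genotype cannot reach risk 1
  allhom <- matrix("homozygous_risk", 1, 8, dimnames = list(NULL, cf$snp_id))
  p_max <- predictRisk(encodeProfiles(make_profiles(allhom), model),
                       model)$absolute_risk
  expect_lt(p_max, 1)
  expect_gt(p_max, 0)
})

test_that("ties share the smaller rank and sorting is stable", {
  rep <- data.frame(subject_id = c("a", "b", "c", "d"),
                    stratum = "men",
                    absolute_risk = c(0.1, 0.3, 0.1, 0.05))
  ranked <- cohortSummary(rep)$ranked
  expect_identical(ranked$subject_id, c("b", "a", "c", "d"))
  expect_identical(ranked$rank, c(1L, 2L, 2L, 4L))
})

test_that("the HWE-weighted mean linear predictor reproduces the baseline logit", {
  # with consistent calibration the model is exactly centred; with the
  # literature rule the offset equals the documented discrepancy for
  # markers lacking a homozygous OR
  raw <- table1_raw()
  e_x <- 2 * raw$f * (1 - raw$f) +
    raw$f^2 * ifelse(is.na(raw$or_hom), 1, log(raw$or_hom) / log(raw$or_het))
  for (calib in c("consistent", "literature")) {
    model <- table1_model(calibration = calib)
    cf <- modelCoefficients(model)
    mean_lp <- intercepts(model)[["men"]] + sum(cf$beta * e_x)
    no_hom <- is.na(raw$or_hom)
    offset <- if (calib == "consistent") 0 else
      sum(log(raw$or_het[no_hom]) * (e_x[no_hom] - raw$f[no_hom]))
    expect_equal(mean_lp, qlogis(0.0562) + offset, tolerance = 1e-12)
  }
})

test_that("delta-method intervals follow the published-CI variance rule", {
  one <- SNPMarkerCatalog(data.frame(
    snp_id = "rs1", risk_allele = "A", freq = 0.3,
    or_het = 1.5, source = "x"))
  model <- buildModel(one, c(all = 0.05))
  calls <- matrix("heterozygous", 1, 1, dimnames = list(NULL, "rs1"))
  enc <- encodeProfiles(make_profiles(calls, stratum = "all"), model)
  ci <- data.frame(snp_id = "rs1", ci_lo = 1.2, ci_hi = 1.8)
  iv <- riskInterval(enc, model, ci)
  se <- log(1.8 / 1.2) / (2 * 1.96)  # published-CI rule for se(beta)
  lp <- qlogis(0.05) - log(1.5) * 0.3 + log(1.5)
  expect_equal(iv$risk, plogis(lp), tolerance = 1e-12)
  expect_equal(iv$risk_low, plogis(lp - 1.96 * se), tolerance = 1e-12)
  expect_equal(iv$risk_high, plogis(lp + 1.96 * se), tolerance = 1e-12)
  expect_true(iv$risk_low < iv$risk && iv$risk < iv$risk_high)
  # widening the CI widens the interval
  iv2 <- riskInterval(enc, model, data.frame(snp_id = "rs1",
                                             ci_lo = 1.1, ci_hi = 2.0))
  expect_gt(iv2$risk_high - iv2$risk_low, iv$risk_high - iv$risk_low)
  # all-zero x: the interval collapses onto the point risk
  calls0 <- matrix("non_carrier", 1, 1, dimnames = list(NULL, "rs1"))
  enc0 <- encodeProfiles(make_profiles(calls0, stratum = "all"), model)
  iv0 <- riskInterval(enc0, model, ci)
  expect_equal(iv0$risk_low, iv0$risk, tolerance = 1e-15)
  expect_equal(iv0$risk_high, iv0$risk, tolerance = 1e-15)
  # a missing CI for an active SNP names the rsID; a non-bracketing CI errors
  expect_error(riskInterval(enc, model,
                            data.frame(snp_id = "rsX", ci_lo = 1, ci_hi = 2)),
               "rs1")
  expect_error(riskInterval(enc, model,
                            data.frame(snp_id = "rs1", ci_lo = 1.6, ci_hi = 1.8)),
               "bracket")
})

test_that("cohort summaries average per stratum and a singleton equals itself", {
  rep <- data.frame(subject_id = "a", stratum = "men", absolute_risk = 0.12,
                    relative_risk = 2.1)
  s <- cohortSummary(rep)$strata
  expect_equal(s$mean_absolute_risk, 0.12)
  expect_equal(s$mean_relative_risk, 2.1)
  expect_error(cohortSummary(data.frame()), "at least one")
})

test_that("risk reports write the canonical table and a full-precision JSON", {
  model <- table1_model()
  prof <- simulateGenotypes(table1_catalog(), n = c(men = 4, women = 2),
                            seed = 3)
  rep <- predictRisk(encodeProfiles(prof, model), model)
  p_tsv <- withr::local_tempfile(fileext = ".tsv")
  writeRiskReport(rep, p_tsv, "tsv")
  tab <- read.table(p_tsv, header = TRUE, sep = "\t",
                    colClasses = "character")
  expect_identical(names(tab),
                   c("subject_id", "absolute_risk", "relative_risk", "stratum"))
  expect_identical(tab$absolute_risk, sprintf("%.3f", rep$absolute_risk))
  expect_identical(tab$relative_risk, sprintf("%.1f", rep$relative_risk))
  p_json <- withr::local_tempfile(fileext = ".json")
  writeRiskReport(rep, p_json, "json")
  back <- jsonlite::read_json(p_json, simplifyVector = TRUE)
  expect_equal(back$absolute_risk, rep$absolute_risk, tolerance = 1e-12)
  expect_true(all(c("linear_predictor", "n_missing") %in% names(back)))
})
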