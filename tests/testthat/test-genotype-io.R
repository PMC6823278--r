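test_that("genotype TSV calls are classified by risk-allele count, unordered", {
  cat <- table1_catalog()
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tstratum\trs1820453\trs716274",
               "s1\tmen\tGG\tAG",
               "s2\twomen\tAG\tGA",
               "s3\tmen\tAA\t./."), p)
  prof <- readGenotypeTSV(p, cat)
  calls <- genotypeCalls(prof)
  expect_identical(calls["s1", "rs1820453"], "homozygous_risk")
  expect_identical(calls["s1", "rs716274"], "heterozygous")
  expect_identical(calls["s2", "rs1820453"], "heterozygous")
  expect_identical(calls["s2", "rs716274"], "heterozygous")  # "GA" == "AG"
  expect_identical(calls["s3", "rs1820453"], "non_carrier")
  expect_identical(calls["s3", "rs716274"], "missing")
  expect_identical(stratum(prof), c("men", "women", "men"))
})

test_that("uninterpretable calls warn and become missing, or error under strict", {
  cat <- table1_catalog()
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tstratum\trs1820453", "s1\tmen\tGN"), p)
  expect_warning(prof <- readGenotypeTSV(p, cat), "uninterpretable")
  expect_identical(unname(genotypeCalls(prof)[1, 1]), "missing")
  expect_error(suppressWarnings(readGenotypeTSV(p, cat, strict = TRUE)),
               "uninterpretable")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tstratum\trs_unknown", "s1\tmen\tAA"), p2)
  expect_error(readGenotypeTSV(p2, cat), "absent from the catalog")
})

test_that("VCF genotypes are matched by rsID and counted against REF/ALT", {
  cat <- table1_catalog()
  p <- withr::local_tempfile(fileext = ".vcf")
  # risk alleles: rs1820453 G (ALT), rs716274 G (REF), rs9981861 G (neither)
  write_test_vcf(p, c(
    "1\t100\trs1820453\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1\t0/0",
    "2\t200\trs716274\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/1\t./.",
    "3\t300\trs9981861\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1"),
    samples = c("s1", "s2", "s3"))
  smap <- c(s1 = "men", s2 = "women", s3 = "men")
  expect_warning(prof <- readVCF(p, cat, smap), "matches neither REF nor ALT")
  calls <- genotypeCalls(prof)
  expect_identical(unname(calls[c("s1", "s2", "s3"), "rs1820453"]),
                   c("heterozygous", "homozygous_risk", "non_carrier"))
  # risk allele equal to REF: 0/0 is the homozygous risk genotype
  expect_identical(unname(calls[c("s1", "s2", "s3"), "rs716274"]),
                   c("homozygous_risk", "heterozygous", "missing"))
  # mismatched risk allele -> missing everywhere
  expect_true(all(calls[, "rs9981861"] == "missing"))
  # sites absent from the VCF -> missing
  expect_true(all(calls[, "rs402710"] == "missing"))
  expect_identical(stratum(prof), unname(smap))
  expect_error(suppressWarnings(readVCF(p, cat, smap, strict = TRUE)),
               "matches neither")
  expect_error(readVCF(p, cat, c(s1 = "men")), "missing from the stratum map")
})

test_that("strand-ambiguous A/T and C/G sites raise a warning", {
  cat <- table1_catalog()
  p <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(p, "5\t500\trs402710\tG\tC\t.\tPASS\t.\tGT\t0/1",
                 samples = "s1")
  expect_warning(readVCF(p, cat, c(s1 = "men")), "strand-ambiguous")
})

test_that("encoding maps genotype classes onto {0, 1, x_hom} and counts missing", {
  model <- table1_model()
  cf <- modelCoefficients(model)
  calls <- matrix("non_carrier", nrow = 3, ncol = 8,
                  dimnames = list(NULL, cf$snp_id))
  calls[2, "rs1820453"] <- "homozygous_risk"
  calls[2, "rs9981861"] <- "homozygous_risk"  # no hom OR: carrier coding
  calls[2, "rs716274"] <- "heterozygous"
  calls[3, ] <- "missing"
  enc <- encodeProfiles(make_profiles(calls), model)
  x <- encodedX(enc)
  expect_equal(unname(x[1, ]), rep(0, 8))
  expect_equal(x[2, "rs1820453"], log(1.65) / log(1.49), tolerance = 1e-12)
  expect_equal(x[2, "rs1820453"], 1.256, tolerance = 1e-3)
  expect_identical(unname(x[2, "rs9981861"]), 1)
  expect_identical(unname(x[2, "rs716274"]), 1)
  expect_equal(unname(x[3, ]), rep(0, 8))
  expect_identical(nMissing(enc), c(0L, 0L, 8L))
  # dummy rule: the homozygote's odds ratio is recovered exactly
  hom <- cf$has_hom_or
  expect_equal(exp(cf$beta[hom] * cf$x_hom[hom]),
               markers(model@catalog)$or_hom[hom], tolerance = 1e-12)
})

test_that("missing calls can be imputed at the HWE expectation instead of zero", {
  model <- table1_model()
  calls <- matrix("missing", nrow = 1, ncol = 8,
                  dimnames = list(NULL, modelCoefficients(model)$snp_id))
  enc <- encodeProfiles(make_profiles(calls), model, missing = "hwe")
  raw <- table1_raw()
  x_hom <- ifelse(is.na(raw$or_hom), 1, log(raw$or_hom) / log(raw$or_het))
  expect_equal(unname(encodedX(enc)[1, ]),
               2 * raw$f * (1 - raw$f) + raw$f^2 * x_hom, tolerance = 1e-14)
  expect_identical(nMissing(enc), 8L)
})

test_that("encoding rejects unknown strata and SNPs outside the model", {
  model <- table1_model()
  calls <- matrix("non_carrier", 1, 8,
                  dimnames = list(NULL, modelCoefficients(model)$snp_id))
  expect_error(encodeProfiles(make_profiles(calls, stratum = "children"), model),
               "stratum not in the model.*P1")
  calls2 <- calls; colnames(calls2)[1] <- "rs_other"
  expect_error(encodeProfiles(make_profiles(calls2), model),
               "absent from the model")
})

test_that("simulated cohorts round-trip through the genotype TSV dialect", {
  cat <- table1_catalog()
  prof <- simulateGenotypes(cat, n = c(men = 12, women = 5), seed = 99)
  p <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypeTSV(prof, cat, p)
  back <- readGenotypeTSV(p, cat)
  expect_identical(genotypeCalls(back), genotypeCalls(prof))
  expect_identical(stratum(back), stratum(prof))
})
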