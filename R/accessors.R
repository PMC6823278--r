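#' @rdname SNPMarkerCatalog-class
#' @export
setMethod("markers", "SNPMarkerCatalog", function(x) x@markers)

#' @rdname SNPMarkerCatalog-class
#' @export
setMethod("populationLabel", "SNPMarkerCatalog", function(x) x@populationLabel)

#' @rdname SNPMarkerCatalog-class
#' @export
setMethod("length", "SNPMarkerCatalog", function(x) nrow(x@markers))

setMethod("show", "SNPMarkerCatalog", function(object) {
  cat(sprintf("SNPMarkerCatalog with %d marker(s)", length(object)))
  if (!is.na(object@populationLabel))
    cat(sprintf(" [population: %s]", object@populationLabel))
  cat("\n")
  if (length(object)) {
    m <- object@markers
    n_hom <- sum(!is.na(m$or_hom))
    cat(sprintf("  or_het range: %.2f-%.2f; %d with homozygous OR\n",
                min(m$or_het), max(m$or_het), n_hom))
    print(utils::head(m[, c("snp_id", "risk_allele", "freq", "or_het", "or_hom")], 8L),
          row.names = FALSE)
    if (nrow(m) > 8L) cat(sprintf("  ... and %d more\n", nrow(m) - 8L))
  }
  invisible(NULL)
})

#' @rdname LogisticRiskModel-class
#' @export
setMethod("modelCoefficients", "LogisticRiskModel", function(x) x@coefficients)

#' @rdname LogisticRiskModel-class
#' @export
setMethod("intercepts", "LogisticRiskModel", function(x) x@intercepts)

#' @rdname LogisticRiskModel-class
#' @export
setMethod("baselines", "LogisticRiskModel", function(x) x@baselines)

#' @rdname LogisticRiskModel-class
#' @export
setMethod("contributionSum", "LogisticRiskModel", function(x) x@contributionSum)

setMethod("show", "LogisticRiskModel", function(object) {
  cat(sprintf("LogisticRiskModel: %d SNP(s), %d stratum/strata [calibration: %s]\n",
              nrow(object@coefficients), length(object@intercepts),
              object@calibration))
  cf <- object@coefficients
  tab <- data.frame(snp_id = cf$snp_id,
                    beta = round(cf$beta, 3),
                    x_hom = round(cf$x_hom, 3),
                    contribution = round(cf$contribution, 3))
  print(tab, row.names = FALSE)
  cat(sprintf("  contribution sum: %.3f\n", object@contributionSum))
  for (s in names(object@intercepts))
    cat(sprintf("  beta0[%s] = %.3f (P0 = %.4f)\n",
                s, object@intercepts[[s]], object@baselines[[s]]))
  invisible(NULL)
})

#' @rdname GenotypeProfiles-class
#' @export
setMethod("subjectId", "GenotypeProfiles", function(x) x@subjectId)

#' @rdname GenotypeProfiles-class
#' @export
setMethod("stratum", "GenotypeProfiles", function(x) x@stratum)

#' @rdname GenotypeProfiles-class
#' @export
setMethod("genotypeCalls", "GenotypeProfiles", function(x) x@calls)

#' @rdname GenotypeProfiles-class
#' @export
setMethod("length", "GenotypeProfiles", function(x) length(x@subjectId))

setMethod("show", "GenotypeProfiles", function(object) {
  cat(sprintf("GenotypeProfiles: %d subject(s) x %d SNP(s)\n",
              length(object@subjectId), ncol(object@calls)))
  n_miss <- sum(object@calls == "missing")
  if (n_miss) cat(sprintf("  %d missing call(s)\n", n_miss))
  invisible(NULL)
})

#' @rdname EncodedProfiles-class
#' @export
setMethod("subjectId", "EncodedProfiles", function(x) x@subjectId)

#' @rdname EncodedProfiles-class
#' @export
setMethod("stratum", "EncodedProfiles", function(x) x@stratum)

#' @rdname EncodedProfiles-class
#' @export
setMethod("encodedX", "EncodedProfiles", function(x) x@x)

#' @rdname EncodedProfiles-class
#' @export
setMethod("nMissing", "EncodedProfiles", function(x) x@nMissing)

setMethod("show", "EncodedProfiles", function(object) {
  cat(sprintf("EncodedProfiles: %d subject(s) x %d SNP(s); %d with missing calls\n",
              length(object@subjectId), ncol(object@x),
              sum(object@nMissing > 0L)))
  invisible(NULL)
})
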