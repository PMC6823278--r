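#' @import methods
NULL

GENOTYPE_CLASSES <- c("non_carrier", "heterozygous", "homozygous_risk", "missing")

MARKER_COLUMNS <- c("snp_id", "risk_allele", "freq", "freq_all",
                    "or_het", "or_hom", "source")

#' Catalog of SNP risk-factor markers
#'
#' An ordered collection of literature-derived SNP risk factors. Each marker
#' carries its rsID, risk allele, risk-allele frequency in the target
#' population, the odds ratio (OR) of the heterozygous genotype and, when the
#' literature reports one, the OR of the homozygous risk genotype.
#'
#' @slot markers a \code{data.frame} with columns \code{snp_id},
#'   \code{risk_allele}, \code{freq}, \code{freq_all}, \code{or_het},
#'   \code{or_hom} (\code{NA} when unavailable) and \code{source}.
#'   \code{freq_all} (frequency in a broader reference population) is stored
#'   for provenance but unused by model building.
#' @slot populationLabel free-text label of the population whose allele
#'   frequencies and baseline risks the catalog refers to (e.g. "Chinese").
#'
#' @seealso [readMarkerTable()], [filterByOR()], [buildModel()]
#' @export
setClass("SNPMarkerCatalog",
  representation(markers = "data.frame", populationLabel = "character"),
  prototype(
    markers = data.frame(
      snp_id = character(), risk_allele = character(),
      freq = numeric(), freq_all = numeric(),
      or_het = numeric(), or_hom = numeric(), source = character(),
      stringsAsFactors = FALSE),
    populationLabel = NA_character_))

setValidity("SNPMarkerCatalog", function(object) {
  m <- object@markers
  msgs <- character()
  missing_cols <- setdiff(MARKER_COLUMNS, names(m))
  if (length(missing_cols))
    return(paste("markers lacks columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(m) == 0L) return(TRUE)
  if (any(is.na(m$snp_id) | !nzchar(m$snp_id)))
    msgs <- c(msgs, "snp_id must be non-empty")
  if (anyDuplicated(m$snp_id))
    msgs <- c(msgs, paste("duplicate snp_id:",
                          paste(unique(m$snp_id[duplicated(m$snp_id)]), collapse = ", ")))
  if (!all(m$risk_allele %in% c("A", "C", "G", "T")))
    msgs <- c(msgs, "risk_allele must be one of A, C, G, T")
  bad_f <- which(!is.finite(m$freq) | m$freq <= 0 | m$freq >= 1)
  if (length(bad_f))
    msgs <- c(msgs, paste0("freq must lie in (0,1); offending rows: ",
                           paste(bad_f, collapse = ", ")))
  bad_or <- which(!is.finite(m$or_het) | m$or_het <= 0)
  if (length(bad_or))
    msgs <- c(msgs, paste0("or_het must be > 0; offending rows: ",
                           paste(bad_or, collapse = ", ")))
  bad_hom <- which(!is.na(m$or_hom) & m$or_hom <= 0)
  if (length(bad_hom))
    msgs <- c(msgs, paste0("or_hom must be > 0 when present; offending rows: ",
                           paste(bad_hom, collapse = ", ")))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Calibrated logistic risk model
#'
#' A logistic disease-risk model assembled from a marker catalog and one or
#' more population baselines. The linear predictor is
#' \eqn{\beta_0 + \sum_i \beta_i x_i} with \eqn{\beta_i = \ln OR_i}
#' (heterozygous OR) and genotype encoding \eqn{x_i \in \{0, 1, x_{hom,i}\}}.
#' The per-stratum intercept \eqn{\beta_0} is calibrated so that
#' \eqn{\beta_0 + \sum_i \beta_i \bar f_i = \mathrm{logit}(P_0)} where
#' \eqn{P_0} is the stratum's average lifetime disease risk.
#'
#' @slot coefficients \code{data.frame} with one row per SNP, columns
#'   \code{snp_id}, \code{beta}, \code{x_hom} (homozygote encoding value),
#'   \code{has_hom_or} and \code{contribution} (the calibration term
#'   \eqn{\beta \bar f}).
#' @slot intercepts named numeric, one \eqn{\beta_0} per stratum.
#' @slot baselines named numeric, the stratum average lifetime risks
#'   \eqn{P_0}.
#' @slot contributionSum numeric, \eqn{\sum_i \beta_i \bar f_i}.
#' @slot calibration \code{"literature"} (the published per-frequency rule
#'   for SNPs lacking a homozygous OR) or \code{"consistent"} (HWE
#'   expectation of \eqn{\beta x} under the model's own encoding).
#' @slot homEncoding numeric, the \code{x} assigned to homozygotes at SNPs
#'   without a homozygous OR (default 1, carrier coding).
#' @slot catalog the source [SNPMarkerCatalog-class].
#'
#' @seealso [buildModel()], [predictRisk()]
#' @export
setClass("LogisticRiskModel",
  representation(
    coefficients = "data.frame",
    intercepts = "numeric",
    baselines = "numeric",
    contributionSum = "numeric",
    calibration = "character",
    homEncoding = "numeric",
    catalog = "SNPMarkerCatalog"))

setValidity("LogisticRiskModel", function(object) {
  msgs <- character()
  cf <- object@coefficients
  need <- c("snp_id", "beta", "x_hom", "has_hom_or", "contribution")
  if (!all(need %in% names(cf)))
    return("coefficients lacks required columns")
  if (is.null(names(object@intercepts)) || anyDuplicated(names(object@intercepts)))
    msgs <- c(msgs, "intercepts must be uniquely named by stratum")
  if (!identical(sort(names(object@intercepts)), sort(names(object@baselines))))
    msgs <- c(msgs, "intercepts and baselines must name the same strata")
  if (any(object@baselines <= 0 | object@baselines >= 1))
    msgs <- c(msgs, "baselines must lie in (0,1)")
  # calibration identity: beta0 + sum(contribution) = logit(p0)
  resid <- object@intercepts + object@contributionSum -
    stats::qlogis(object@baselines[names(object@intercepts)])
  if (any(abs(resid) > 1e-9))
    msgs <- c(msgs, "intercepts violate the calibration identity")
  # dummy-variable rule: x_hom * beta = ln(or_hom) where or_hom is present
  hom <- cf$has_hom_or
  if (any(hom)) {
    or_hom <- object@catalog@markers$or_hom[match(cf$snp_id, object@catalog@markers$snp_id)]
    if (any(abs(cf$x_hom[hom] * cf$beta[hom] - log(or_hom[hom])) > 1e-9))
      msgs <- c(msgs, "x_hom * beta must equal ln(or_hom)")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Subject genotype profiles
#'
#' Genotype classes for a set of subjects at the catalog's SNPs, as read from
#' a genotype table or VCF, before numeric encoding.
#'
#' @slot subjectId character vector of subject labels.
#' @slot stratum character vector, baseline stratum per subject.
#' @slot calls character matrix (subjects x SNPs, dimnames set) with values
#'   \code{"non_carrier"}, \code{"heterozygous"}, \code{"homozygous_risk"} or
#'   \code{"missing"}.
#' @export
setClass("GenotypeProfiles",
  representation(subjectId = "character", stratum = "character",
                 calls = "matrix"))

setValidity("GenotypeProfiles", function(object) {
  msgs <- character()
  n <- length(object@subjectId)
  if (length(object@stratum) != n)
    msgs <- c(msgs, "stratum length must match subjectId")
  if (nrow(object@calls) != n)
    msgs <- c(msgs, "calls must have one row per subject")
  if (anyDuplicated(object@subjectId))
    msgs <- c(msgs, "duplicate subject_id")
  if (!all(object@calls %in% GENOTYPE_CLASSES))
    msgs <- c(msgs, "calls contain invalid genotype classes")
  if (is.null(colnames(object@calls)))
    msgs <- c(msgs, "calls must have snp_id column names")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Numerically encoded genotype profiles
#'
#' The model-aligned x-vectors: 0 for non-carriers, 1 for heterozygotes, the
#' model's \code{x_hom} for homozygous risk genotypes; missing calls are
#' imputed (0 by default) and counted.
#'
#' @slot subjectId character vector of subject labels.
#' @slot stratum character vector, baseline stratum per subject.
#' @slot x numeric matrix (subjects x SNPs) aligned to the model's
#'   coefficient order.
#' @slot nMissing integer vector, number of missing calls per subject.
#' @export
setClass("EncodedProfiles",
  representation(subjectId = "character", stratum = "character",
                 x = "matrix", nMissing = "integer"))

setValidity("EncodedProfiles", function(object) {
  n <- length(object@subjectId)
  if (length(object@stratum) != n) return("stratum length must match subjectId")
  if (nrow(object@x) != n) return("x must have one row per subject")
  if (length(object@nMissing) != n) return("nMissing length must match subjectId")
  if (any(object@nMissing < 0)) return("nMissing must be non-negative")
  TRUE
})
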