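#' Predict absolute and relative lifetime risk
#'
#' Computes, per subject, the linear predictor
#' \eqn{\beta_0 + \sum_i \beta_i x_i}, the absolute lifetime risk
#' \eqn{P = 1/(1 + e^{-(\beta_0 + \sum \beta_i x_i)})} and the relative
#' lifetime risk \eqn{P / P_0} against the subject's stratum baseline. The
#' inverse-logit construction guarantees \eqn{0 < P < 1} for any input.
#' Ranks are 1-based by descending absolute risk within the cohort, ties
#' sharing the smaller rank.
#'
#' @param encoded an [EncodedProfiles-class] aligned to the model
#' @param model a [LogisticRiskModel-class]
#' @return a \code{data.frame} with columns \code{subject_id},
#'   \code{stratum}, \code{linear_predictor}, \code{absolute_risk},
#'   \code{relative_risk}, \code{n_missing} and \code{rank}, sorted by
#'   descending absolute risk (stable for ties).
#' @examples
#' tbl <- system.file("extdata", "lung_markers.tsv", package = "snplogit")
#' model <- buildModel(readMarkerTable(tbl), c(men = 0.0562, women = 0.0256))
#' cohort <- simulateGenotypes(model@catalog, n = c(men = 5), seed = 1)
#' predictRisk(encodeProfiles(cohort, model), model)
#' @export
predictRisk <- function(encoded, model) {
  stopifnot(is(encoded, "EncodedProfiles"), is(model, "LogisticRiskModel"))
  cf <- modelCoefficients(model)
  x <- encodedX(encoded)
  if (ncol(x) != nrow(cf) || !identical(colnames(x), cf$snp_id))
    stop("encoded profiles are not aligned to the model's coefficients")
  strata <- stratum(encoded)
  unknown <- !(strata %in% names(intercepts(model)))
  if (any(unknown))
    stop("no intercept for stratum of subject(s): ",
         paste(subjectId(encoded)[unknown], collapse = ", "))
  b0 <- intercepts(model)[strata]
  lp <- as.numeric(b0 + x %*% cf$beta)
  p <- stats::plogis(lp)
  p0 <- baselines(model)[strata]
  rep <- data.frame(
    subject_id = subjectId(encoded),
    stratum = strata,
    linear_predictor = lp,
    absolute_risk = p,
    relative_risk = p / p0,
    n_missing = nMissing(encoded),
    stringsAsFactors = FALSE)
  ord <- order(-rep$absolute_risk)
  rep <- rep[ord, , drop = FALSE]
  rep$rank <- rank(-rep$absolute_risk, ties.method = "min")
  rownames(rep) <- NULL
  rep
}

#' Approximate risk interval from odds-ratio confidence bounds
#'
#' Delta-method interval for a subject's absolute risk. The variance of each
#' coefficient is recovered from the published 95\% confidence interval of
#' its OR, \eqn{\mathrm{var}(\beta_i) = (\ln(CI_{hi}/CI_{lo})/(2 \cdot 1.96))^2};
#' the linear-predictor variance is \eqn{\sum_i x_i^2 \mathrm{var}(\beta_i)}
#' (the intercept is treated as fixed), and the bounds are the inverse logit
#' of \eqn{LP \pm 1.96\sqrt{\mathrm{var}(LP)}}. The interval is approximate:
#' it ignores covariance between coefficients and any uncertainty in the
#' baseline.
#'
#' @param encoded an [EncodedProfiles-class] (any number of subjects)
#' @param model a [LogisticRiskModel-class]
#' @param orCI data.frame with columns \code{snp_id}, \code{ci_lo},
#'   \code{ci_hi}: published 95\% CI bounds of the heterozygous OR. Bounds
#'   must be present for every SNP at which any subject has \eqn{x \ne 0}
#'   and must bracket the point OR.
#' @return a \code{data.frame} with columns \code{subject_id},
#'   \code{risk_low}, \code{risk}, \code{risk_high}
#' @export
riskInterval <- function(encoded, model, orCI) {
  stopifnot(is(encoded, "EncodedProfiles"), is(model, "LogisticRiskModel"))
  if (!all(c("snp_id", "ci_lo", "ci_hi") %in% names(orCI)))
    stop("orCI must have columns snp_id, ci_lo, ci_hi")
  cf <- modelCoefficients(model)
  x <- encodedX(encoded)
  idx <- match(cf$snp_id, orCI$snp_id)
  var_beta <- (log(orCI$ci_hi[idx] / orCI$ci_lo[idx]) / (2 * 1.96))^2
  active <- colSums(x != 0) > 0
  no_ci <- which(active & is.na(var_beta))
  if (length(no_ci))
    stop("missing OR confidence interval for SNP(s): ",
         paste(cf$snp_id[no_ci], collapse = ", "))
  ok <- !is.na(idx)
  or_pt <- exp(cf$beta)
  bad <- which(ok & (orCI$ci_lo[idx] > or_pt | orCI$ci_hi[idx] < or_pt))
  if (length(bad))
    stop("CI does not bracket the point OR for SNP(s): ",
         paste(cf$snp_id[bad], collapse = ", "))
  var_beta[is.na(var_beta)] <- 0
  b0 <- intercepts(model)[stratum(encoded)]
  lp <- as.numeric(b0 + x %*% cf$beta)
  se_lp <- sqrt(as.numeric((x^2) %*% var_beta))
  data.frame(subject_id = subjectId(encoded),
             risk_low = stats::plogis(lp - 1.96 * se_lp),
             risk = stats::plogis(lp),
             risk_high = stats::plogis(lp + 1.96 * se_lp),
             stringsAsFactors = FALSE)
}

#' Cohort summary of predicted risks
#'
#' Per-stratum arithmetic mean of absolute (and relative) risk, plus the
#' ranked report table sorted by descending absolute risk (stable for ties).
#'
#' @param reports the \code{data.frame} returned by [predictRisk()], or any
#'   data.frame with columns \code{subject_id}, \code{stratum} and
#'   \code{absolute_risk} (a \code{relative_risk} column is summarised when
#'   present)
#' @return a list with elements \code{strata} (per-stratum n and mean risks)
#'   and \code{ranked} (the sorted table with a \code{rank} column)
#' @export
cohortSummary <- function(reports) {
  if (!is.data.frame(reports) || nrow(reports) < 1L)
    stop("reports must be a data.frame with at least one row")
  need <- c("subject_id", "stratum", "absolute_risk")
  if (!all(need %in% names(reports)))
    stop("reports must have columns ", paste(need, collapse = ", "))
  strata <- unique(reports$stratum)
  per <- data.frame(
    stratum = strata,
    n = vapply(strata, function(s) sum(reports$stratum == s), integer(1)),
    mean_absolute_risk = vapply(strata, function(s)
      mean(reports$absolute_risk[reports$stratum == s]), numeric(1)),
    stringsAsFactors = FALSE)
  if ("relative_risk" %in% names(reports))
    per$mean_relative_risk <- vapply(strata, function(s)
      mean(reports$relative_risk[reports$stratum == s]), numeric(1))
  rownames(per) <- NULL
  ranked <- reports[order(-reports$absolute_risk), , drop = FALSE]
  ranked$rank <- rank(-ranked$absolute_risk, ties.method = "min")
  rownames(ranked) <- NULL
  list(strata = per, ranked = ranked)
}

#' Write a risk report
#'
#' TSV output mirrors the canonical report layout (\code{subject_id},
#' \code{absolute_risk} to 3 decimals, \code{relative_risk} to 1 decimal,
#' \code{stratum}); JSON output keeps full precision and all columns.
#'
#' @param reports the \code{data.frame} from [predictRisk()]
#' @param path output path
#' @param format \code{"tsv"} or \code{"json"}
#' @return \code{path}, invisibly
#' @export
writeRiskReport <- function(reports, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- data.frame(subject_id = reports$subject_id,
                      absolute_risk = sprintf("%.3f", reports$absolute_risk),
                      relative_risk = sprintf("%.1f", reports$relative_risk),
                      stratum = reports$stratum,
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(reports, path, auto_unbox = FALSE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}
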