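#' Simulate a genotype cohort under Hardy-Weinberg equilibrium
#'
#' Draws, for each subject and marker, a genotype with probabilities
#' \eqn{(1-f)^2} (non-carrier), \eqn{2f(1-f)} (heterozygous) and \eqn{f^2}
#' (homozygous risk), independently across markers — the same assumptions
#' the calibration makes. Default cohort sizes mirror the validation cohort
#' the model was demonstrated on (38 men, 10 women).
#'
#' @param catalog a [SNPMarkerCatalog-class]
#' @param n named integer vector: subjects per stratum
#'   (default \code{c(men = 38, women = 10)})
#' @param seed mandatory RNG seed; two runs with the same seed produce
#'   identical cohorts
#' @param prefix subject-id prefix (default \code{"S"})
#' @return a [GenotypeProfiles-class] of \code{sum(n)} subjects
#' @export
simulateGenotypes <- function(catalog, n = c(men = 38, women = 10), seed,
                              prefix = "S") {
  stopifnot(is(catalog, "SNPMarkerCatalog"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("a single numeric seed is required")
  if (any(n < 1L) || is.null(names(n)) || any(!nzchar(names(n))))
    stop("n must be a named vector of positive counts per stratum")
  m <- markers(catalog)
  if (nrow(m) == 0L) stop("catalog is empty")
  total <- sum(n)
  strata <- rep(names(n), times = n)
  ids <- sprintf("%s%0*d", prefix, max(3L, nchar(total)), seq_len(total))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  classes <- c("non_carrier", "heterozygous", "homozygous_risk")
  calls <- matrix("missing", nrow = total, ncol = nrow(m),
                  dimnames = list(ids, m$snp_id))
  for (j in seq_len(nrow(m))) {
    f <- m$freq[j]
    probs <- c((1 - f)^2, 2 * f * (1 - f), f^2)
    calls[, j] <- sample(classes, total, replace = TRUE, prob = probs)
  }
  GenotypeProfiles(ids, strata, calls)
}

#' Simulate a single-SNP case/control study
#'
#' End-to-end check of the OR-to-coefficient correspondence: genotypes are
#' drawn under HWE, disease status per subject is drawn from the calibrated
#' single-SNP logistic model, and the heterozygote-vs-non-carrier odds ratio
#' is recovered from the resulting 2x2 contingency table (homozygous risk
#' subjects are excluded from the table, so the sample OR estimates the
#' heterozygous OR). A single SNP avoids the non-collapsibility of marginal
#' odds ratios in multi-covariate logistic models.
#'
#' @param marker a one-row data.frame (or one-marker
#'   [SNPMarkerCatalog-class]) with \code{snp_id}, \code{risk_allele},
#'   \code{freq}, \code{or_het} and optionally \code{or_hom}
#' @param p0 baseline average lifetime risk of the simulated stratum
#' @param n number of subjects; should be large enough that all four cells
#'   have expected counts of at least 5
#' @param seed mandatory RNG seed
#' @return a list: \code{counts} (2x2 matrix, genotype x status),
#'   \code{sample_or}, \code{ci} (95\% Woolf interval for the sample OR),
#'   \code{true_or}, \code{n}, \code{seed}
#' @export
simulateCaseControl <- function(marker, p0, n, seed) {
  if (is(marker, "SNPMarkerCatalog")) {
    if (length(marker) != 1L)
      stop("case/control simulation takes a single marker")
    marker <- markers(marker)
  }
  marker <- as.data.frame(marker, stringsAsFactors = FALSE)
  if (nrow(marker) != 1L) stop("marker must be a single row")
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("a single numeric seed is required")
  if (!is.numeric(n) || n < 1L) stop("n must be a positive count")
  catalog <- SNPMarkerCatalog(marker)
  model <- buildModel(catalog, c(cohort = p0))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  f <- marker$freq
  geno <- sample(c("non_carrier", "heterozygous", "homozygous_risk"), n,
                 replace = TRUE, prob = c((1 - f)^2, 2 * f * (1 - f), f^2))
  cf <- modelCoefficients(model)
  x <- c(non_carrier = 0, heterozygous = 1, homozygous_risk = cf$x_hom)[geno]
  p <- stats::plogis(intercepts(model)[["cohort"]] + cf$beta * x)
  case <- stats::rbinom(n, 1L, p)
  keep <- geno != "homozygous_risk"
  counts <- table(
    genotype = factor(geno[keep], levels = c("heterozygous", "non_carrier")),
    status = factor(ifelse(case[keep] == 1L, "case", "control"),
                    levels = c("case", "control")))
  counts <- unclass(counts)
  if (any(counts == 0L))
    warning("zero cell in the contingency table; increase n or change the seed",
            call. = FALSE)
  a <- counts["heterozygous", "case"]; b <- counts["heterozygous", "control"]
  c_ <- counts["non_carrier", "case"]; d <- counts["non_carrier", "control"]
  sample_or <- (a * d) / (b * c_)
  se_log <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(counts = counts,
       sample_or = sample_or,
       ci = exp(log(sample_or) + c(-1.96, 1.96) * se_log),
       true_or = marker$or_het,
       n = n,
       seed = as.integer(seed))
}
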