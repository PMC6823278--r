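#' Log-odds coefficient from a published odds ratio
#'
#' \eqn{\beta = \ln(OR)}. In a logistic model the odds ratio for a unit
#' increase of a covariate is \eqn{e^\beta}, so a literature-reported OR maps
#' directly onto a coefficient without refitting.
#'
#' @param or_value odds ratio(s), each > 0
#' @return natural-log coefficient(s); \code{exp(betaFromOR(x)) == x} at
#'   machine precision
#' @examples
#' betaFromOR(1.49)  # 0.399 (3 dp)
#' @export
betaFromOR <- function(or_value) {
  if (!is.numeric(or_value) || any(!is.finite(or_value) | or_value <= 0))
    stop("odds ratio must be a positive finite number")
  log(or_value)
}

#' Per-marker calibration contribution
#'
#' The population-expected term \eqn{\beta \bar f} entering intercept
#' calibration. With \code{calibration = "literature"} (the default) a marker
#' lacking a homozygous OR contributes \eqn{\beta f} — the published rule —
#' while a marker with both ORs contributes the HWE-weighted sum
#' \eqn{\beta_{het} \cdot 2f(1-f) + \beta_{hom} \cdot f^2}.
#' With \code{calibration = "consistent"} every marker contributes the HWE
#' expectation of \eqn{\beta x} under the model's own genotype encoding,
#' i.e. \eqn{\beta(2f(1-f) \cdot 1 + f^2 \cdot x_{hom})}.
#'
#' @param catalog a [SNPMarkerCatalog-class]
#' @param calibration \code{"literature"} or \code{"consistent"}
#' @param homEncoding x value for homozygotes at markers without a
#'   homozygous OR (used by the consistent mode and at prediction time);
#'   1 = carrier coding (default), 2 = additive.
#' @return named numeric vector of contributions, one per marker
#' @examples
#' tbl <- system.file("extdata", "lung_markers.tsv", package = "snplogit")
#' round(markerContribution(readMarkerTable(tbl)), 3)
#' @export
markerContribution <- function(catalog,
                               calibration = c("literature", "consistent"),
                               homEncoding = 1) {
  stopifnot(is(catalog, "SNPMarkerCatalog"))
  calibration <- match.arg(calibration)
  m <- markers(catalog)
  if (nrow(m) == 0L) return(stats::setNames(numeric(), character()))
  beta <- betaFromOR(m$or_het)
  gf <- hweGenotypeFreqs(m$freq)
  has_hom <- !is.na(m$or_hom)
  x_hom <- ifelse(has_hom, log(m$or_hom) / beta, homEncoding)
  contrib <- beta * (gf[, "het"] + gf[, "hom"] * x_hom)
  if (calibration == "literature")
    contrib[!has_hom] <- beta[!has_hom] * m$freq[!has_hom]
  stats::setNames(contrib, m$snp_id)
}

#' Calibrate the model intercept for one stratum
#'
#' Solves \eqn{\beta_0 = \mathrm{logit}(P_0) - \sum_i \beta_i \bar f_i}:
#' the intercept absorbs whatever part of the population's average log-odds
#' of disease the catalogued SNPs do not account for (unselected SNPs and
#' non-genetic risk factors alike).
#'
#' @param catalog a [SNPMarkerCatalog-class]; an empty catalog is legal and
#'   yields \eqn{\beta_0 = \mathrm{logit}(P_0)}.
#' @param p0 average lifetime disease risk of the stratum, in (0,1)
#' @inheritParams markerContribution
#' @return the intercept \eqn{\beta_0} (log-odds)
#' @examples
#' tbl <- system.file("extdata", "lung_markers.tsv", package = "snplogit")
#' cat <- readMarkerTable(tbl)
#' round(calibrateIntercept(cat, 0.0562), 3)  # -3.742
#' @export
calibrateIntercept <- function(catalog, p0,
                               calibration = c("literature", "consistent"),
                               homEncoding = 1) {
  if (!is.numeric(p0) || length(p0) != 1L || !is.finite(p0) ||
      p0 <= 0 || p0 >= 1)
    stop("p0 must lie strictly in (0,1)")
  stats::qlogis(p0) - sum(markerContribution(catalog, calibration, homEncoding))
}

#' Read stratum baselines
#'
#' Reads a two-column table (\code{stratum}, \code{p0}) of average lifetime
#' disease risks per stratum.
#'
#' @param path path to a TSV file with header \code{stratum<TAB>p0}
#' @return named numeric vector of baselines
#' @export
readBaselines <- function(path) {
  if (!file.exists(path)) stop("baselines file not found: ", path)
  b <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (!all(c("stratum", "p0") %in% names(b)))
    stop("baselines file must have columns 'stratum' and 'p0'")
  p0 <- suppressWarnings(as.numeric(b$p0))
  if (any(is.na(p0) | p0 <= 0 | p0 >= 1))
    stop("p0 must be numeric in (0,1) for every stratum")
  if (anyDuplicated(b$stratum)) stop("duplicate stratum labels")
  stats::setNames(p0, b$stratum)
}

#' Build a calibrated logistic risk model
#'
#' Assembles per-SNP coefficients (\eqn{\beta = \ln OR_{het}}), homozygote
#' encodings (\eqn{x_{hom} = \ln OR_{hom} / \ln OR_{het}} when the
#' homozygous OR is reported, else \code{homEncoding}), per-marker
#' calibration contributions and one intercept per stratum. Rebuilding after
#' adding or removing markers re-derives the intercepts, so the model is
#' cheap to update as new risk factors are published.
#'
#' @param catalog a validated [SNPMarkerCatalog-class]
#' @param baselines named numeric vector of stratum average lifetime risks
#'   (names are stratum labels), or a data.frame with columns \code{stratum}
#'   and \code{p0}.
#' @inheritParams markerContribution
#' @return an immutable [LogisticRiskModel-class]
#' @examples
#' tbl <- system.file("extdata", "lung_markers.tsv", package = "snplogit")
#' model <- buildModel(readMarkerTable(tbl), c(men = 0.0562, women = 0.0256))
#' round(contributionSum(model), 3)  # 0.921
#' round(intercepts(model), 3)       # -3.742, -4.560
#' @export
buildModel <- function(catalog, baselines,
                       calibration = c("literature", "consistent"),
                       homEncoding = 1) {
  stopifnot(is(catalog, "SNPMarkerCatalog"))
  calibration <- match.arg(calibration)
  if (is.data.frame(baselines)) {
    if (!all(c("stratum", "p0") %in% names(baselines)))
      stop("baselines data.frame must have columns 'stratum' and 'p0'")
    baselines <- stats::setNames(baselines$p0, baselines$stratum)
  }
  if (length(baselines) < 1L) stop("at least one baseline stratum is required")
  if (is.null(names(baselines)) || any(!nzchar(names(baselines))))
    stop("baselines must be named by stratum")
  if (anyDuplicated(names(baselines)))
    stop("duplicate stratum labels: ",
         paste(unique(names(baselines)[duplicated(names(baselines))]),
               collapse = ", "))
  if (any(!is.finite(baselines) | baselines <= 0 | baselines >= 1))
    stop("every baseline p0 must lie strictly in (0,1)")
  m <- markers(catalog)
  beta <- if (nrow(m)) betaFromOR(m$or_het) else numeric()
  has_hom <- !is.na(m$or_hom)
  x_hom <- ifelse(has_hom, log(m$or_hom) / beta, homEncoding)
  # beta == 0 (OR 1) with a homozygous OR would make x_hom undefined;
  # contribution of such a marker is ln(or_hom) at the homozygote directly
  if (any(has_hom & beta == 0))
    stop("or_het == 1 with a homozygous OR gives an undefined dummy encoding")
  contrib <- markerContribution(catalog, calibration, homEncoding)
  coef <- data.frame(snp_id = m$snp_id, beta = beta, x_hom = x_hom,
                     has_hom_or = has_hom,
                     contribution = as.numeric(contrib),
                     stringsAsFactors = FALSE)
  csum <- sum(coef$contribution)
  b0 <- stats::qlogis(baselines) - csum
  new("LogisticRiskModel",
      coefficients = coef,
      intercepts = b0,
      baselines = baselines,
      contributionSum = csum,
      calibration = calibration,
      homEncoding = homEncoding,
      catalog = catalog)
}

#' Serialize a model to JSON
#'
#' Writes a flat JSON document with coefficients, encodings, intercepts,
#' baselines and the source markers plus an md5 provenance hash of the
#' marker table, so a built model can be shared and diffed.
#'
#' @param model a [LogisticRiskModel-class]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeModelJSON <- function(model, path) {
  stopifnot(is(model, "LogisticRiskModel"))
  doc <- list(
    format = "snplogit-model",
    version = 1L,
    population = populationLabel(model@catalog),
    calibration = model@calibration,
    hom_encoding = model@homEncoding,
    coefficients = model@coefficients,
    contribution_sum = model@contributionSum,
    intercepts = as.list(model@intercepts),
    baselines = as.list(model@baselines),
    markers = markers(model@catalog),
    marker_table_md5 = catalogHash(model@catalog))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized model
#'
#' Rebuilds the model from the markers and baselines stored in the JSON
#' document and checks that the stored coefficients and intercepts match the
#' re-derived ones.
#'
#' @param path path to a JSON file written by [writeModelJSON()]
#' @return a [LogisticRiskModel-class]
#' @export
readModelJSON <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "snplogit-model"))
    stop("not a snplogit model document: ", path)
  catalog <- SNPMarkerCatalog(doc$markers, doc$population)
  model <- buildModel(catalog, unlist(doc$baselines),
                      calibration = doc$calibration,
                      homEncoding = doc$hom_encoding)
  stored_b0 <- unlist(doc$intercepts)
  if (any(abs(stored_b0[names(intercepts(model))] - intercepts(model)) > 1e-9))
    stop("stored intercepts do not match re-derived values; corrupt model file?")
  model
}

# md5 of a canonical TSV rendering of the catalog, for provenance logging
catalogHash <- function(catalog) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeMarkerTable(catalog, tmp)
  unname(tools::md5sum(tmp))
}
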