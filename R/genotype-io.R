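#' Construct genotype profiles from a call matrix
#'
#' @param subjectId character vector of subject labels
#' @param stratum character vector of baseline stratum labels, one per subject
#' @param calls character matrix (subjects x SNPs) of genotype classes
#'   (\code{"non_carrier"}, \code{"heterozygous"}, \code{"homozygous_risk"},
#'   \code{"missing"}) with SNP ids as column names
#' @return a [GenotypeProfiles-class]
#' @export
GenotypeProfiles <- function(subjectId, stratum, calls) {
  rownames(calls) <- subjectId
  new("GenotypeProfiles", subjectId = as.character(subjectId),
      stratum = as.character(stratum), calls = calls)
}

# classify a two-letter call ("AG", "GA", "./.") against a risk allele
classifyCall <- function(call, risk_allele, strict = FALSE, context = "") {
  if (is.na(call) || call %in% c("./.", ".", "..", "--"))
    return("missing")
  alleles <- strsplit(gsub("[/|]", "", call), "")[[1]]
  if (length(alleles) != 2L || !all(alleles %in% c("A", "C", "G", "T"))) {
    msg <- paste0("uninterpretable genotype call '", call, "'", context)
    if (strict) stop(msg)
    warning(msg, "; treated as missing", call. = FALSE)
    return("missing")
  }
  switch(as.character(sum(alleles == risk_allele)),
         "0" = "non_carrier", "1" = "heterozygous", "2" = "homozygous_risk")
}

#' Read subject genotypes from a genotype table
#'
#' Reads a TSV with header \code{subject_id, stratum, <snp_id>...} where each
#' genotype cell is an unordered two-letter call (e.g. \code{"AG"}, equal to
#' \code{"GA"}) or \code{"./."} for missing. The genotype class is assigned
#' by counting occurrences of the marker's risk allele in the call
#' (0/1/2 risk alleles -> non-carrier / heterozygous / homozygous risk).
#'
#' @param path path to the genotype TSV
#' @param catalog the [SNPMarkerCatalog-class] naming the expected SNPs and
#'   their risk alleles
#' @param strict if \code{TRUE}, an uninterpretable call is an error;
#'   otherwise it is warned about and treated as missing
#' @return a [GenotypeProfiles-class]
#' @export
readGenotypeTSV <- function(path, catalog, strict = FALSE) {
  stopifnot(is(catalog, "SNPMarkerCatalog"))
  if (!file.exists(path)) stop("genotype file not found: ", path)
  g <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = "character", check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!all(c("subject_id", "stratum") %in% names(g)))
    stop("genotype table must start with columns 'subject_id' and 'stratum'")
  snp_cols <- setdiff(names(g), c("subject_id", "stratum"))
  unknown <- setdiff(snp_cols, markers(catalog)$snp_id)
  if (length(unknown))
    stop("genotype table has SNP column(s) absent from the catalog: ",
         paste(unknown, collapse = ", "))
  risk <- stats::setNames(markers(catalog)$risk_allele, markers(catalog)$snp_id)
  calls <- matrix("missing", nrow = nrow(g), ncol = length(snp_cols),
                  dimnames = list(g$subject_id, snp_cols))
  for (s in snp_cols) {
    calls[, s] <- vapply(seq_len(nrow(g)), function(i)
      classifyCall(g[[s]][i], risk[[s]], strict,
                   context = paste0(" (subject ", g$subject_id[i],
                                    ", SNP ", s, ")")),
      character(1))
  }
  GenotypeProfiles(g$subject_id, g$stratum, calls)
}

#' Write genotype profiles as a genotype table
#'
#' Emits the dialect [readGenotypeTSV()] reads: heterozygotes as
#' risk+alternative allele, homozygotes as doubled risk allele, non-carriers
#' as doubled alternative allele, missing as \code{"./."}. The alternative
#' allele is an arbitrary fixed non-risk base (the catalog does not record
#' the true other allele; classification only counts risk alleles, so the
#' choice is immaterial for round-tripping).
#'
#' @param profiles a [GenotypeProfiles-class]
#' @param catalog the matching [SNPMarkerCatalog-class]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeGenotypeTSV <- function(profiles, catalog, path) {
  stopifnot(is(profiles, "GenotypeProfiles"), is(catalog, "SNPMarkerCatalog"))
  snps <- colnames(genotypeCalls(profiles))
  risk <- stats::setNames(markers(catalog)$risk_allele, markers(catalog)$snp_id)
  other <- vapply(risk, function(a) setdiff(c("A", "C", "G", "T"), a)[1L],
                  character(1))
  out <- data.frame(subject_id = subjectId(profiles),
                    stratum = stratum(profiles),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (s in snps) {
    out[[s]] <- c(non_carrier = paste0(other[[s]], other[[s]]),
                  heterozygous = paste0(risk[[s]], other[[s]]),
                  homozygous_risk = paste0(risk[[s]], risk[[s]]),
                  missing = "./.")[genotypeCalls(profiles)[, s]]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a subject-to-stratum map
#'
#' @param path two-column TSV with header \code{subject_id<TAB>stratum}
#' @return named character vector mapping subject id to stratum label
#' @export
readStratumMap <- function(path) {
  if (!file.exists(path)) stop("stratum map not found: ", path)
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("subject_id", "stratum") %in% names(m)))
    stop("stratum map must have columns 'subject_id' and 'stratum'")
  if (anyDuplicated(m$subject_id)) stop("duplicate subject_id in stratum map")
  stats::setNames(m$stratum, m$subject_id)
}

#' Read subject genotypes from a VCF
#'
#' Matches catalog markers to VCF records by the ID field (rsID) and derives
#' each sample's risk-allele count from the GT field against REF/ALT. The
#' risk allele may be REF (homozygous reference is then the homozygous risk
#' genotype) or any ALT allele. Sites absent from the VCF, half-called or
#' missing genotypes become \code{"missing"}. A risk allele matching neither
#' REF nor ALT is warned about and treated as missing (or is an error with
#' \code{strict = TRUE}); strand flips are never auto-resolved, and
#' strand-ambiguous A/T and C/G sites raise a warning.
#'
#' @param path path to a VCF (v4.x) file
#' @param catalog the [SNPMarkerCatalog-class]
#' @param stratumMap named character vector (see [readStratumMap()]); every
#'   VCF sample must be present
#' @param strict if \code{TRUE}, allele mismatches are errors
#' @return a [GenotypeProfiles-class], one profile per VCF sample
#' @export
readVCF <- function(path, catalog, stratumMap, strict = FALSE) {
  stopifnot(is(catalog, "SNPMarkerCatalog"))
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF drops dimensions
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  if (is.null(samples) || !length(samples)) stop("VCF has no sample columns")
  absent <- setdiff(samples, names(stratumMap))
  if (length(absent))
    stop("sample(s) missing from the stratum map: ",
         paste(absent, collapse = ", "))
  m <- markers(catalog)
  calls <- matrix("missing", nrow = length(samples), ncol = nrow(m),
                  dimnames = list(samples, m$snp_id))
  for (i in seq_len(nrow(m))) {
    row <- match(m$snp_id[i], fix$ID)
    if (is.na(row)) next  # site not genotyped -> missing
    alleles <- c(fix$REF[row], strsplit(fix$ALT[row], ",", fixed = TRUE)[[1]])
    if (setequal(alleles, c("A", "T")) || setequal(alleles, c("C", "G")))
      warning("strand-ambiguous site ", m$snp_id[i],
              " (", paste(alleles, collapse = "/"),
              "): verify the risk allele's strand", call. = FALSE)
    risk_idx <- match(m$risk_allele[i], alleles) - 1L
    if (is.na(risk_idx)) {
      msg <- paste0("risk allele ", m$risk_allele[i], " of ", m$snp_id[i],
                    " matches neither REF nor ALT (", fix$REF[row], "/",
                    fix$ALT[row], ")")
      if (strict) stop(msg)
      warning(msg, "; treated as missing", call. = FALSE)
      next
    }
    for (s in samples) {
      g <- gt[row, s]
      if (is.na(g)) next
      al <- strsplit(g, "[/|]")[[1]]
      if (length(al) != 2L || any(al == ".")) next
      n_risk <- sum(as.integer(al) == risk_idx)
      calls[s, i] <- c("non_carrier", "heterozygous", "homozygous_risk")[n_risk + 1L]
    }
  }
  GenotypeProfiles(samples, unname(stratumMap[samples]), calls)
}

#' Encode genotype profiles into model x-vectors
#'
#' Maps genotype classes onto the model's numeric encoding: non-carrier
#' \eqn{\to 0}, heterozygous \eqn{\to 1}, homozygous risk
#' \eqn{\to x_{hom}} (the dummy-variable value
#' \eqn{\ln OR_{hom}/\ln OR_{het}} when the homozygous OR is reported, else
#' the model's configured carrier value). Model SNPs absent from the
#' profiles are treated as missing. Missing calls encode as 0
#' (population reference) by default, or as the HWE expectation of x with
#' \code{missing = "hwe"}; either way they are counted in \code{nMissing}.
#'
#' @param profiles a [GenotypeProfiles-class]
#' @param model a [LogisticRiskModel-class]
#' @param missing \code{"zero"} (default) or \code{"hwe"}
#' @return an [EncodedProfiles-class] aligned to the model's coefficient
#'   order
#' @export
encodeProfiles <- function(profiles, model, missing = c("zero", "hwe")) {
  stopifnot(is(profiles, "GenotypeProfiles"), is(model, "LogisticRiskModel"))
  missing <- match.arg(missing)
  unknown_stratum <- !(stratum(profiles) %in% names(intercepts(model)))
  if (any(unknown_stratum))
    stop("stratum not in the model for subject(s): ",
         paste(subjectId(profiles)[unknown_stratum], collapse = ", "))
  cf <- modelCoefficients(model)
  calls <- genotypeCalls(profiles)
  unknown_snp <- setdiff(colnames(calls), cf$snp_id)
  if (length(unknown_snp))
    stop("profile SNP(s) absent from the model: ",
         paste(unknown_snp, collapse = ", "))
  n <- length(subjectId(profiles))
  x <- matrix(0, nrow = n, ncol = nrow(cf),
              dimnames = list(subjectId(profiles), cf$snp_id))
  n_miss <- integer(n)
  f <- markers(model@catalog)$freq[match(cf$snp_id, markers(model@catalog)$snp_id)]
  gf <- hweGenotypeFreqs(f)
  x_expect <- gf[, "het"] * 1 + gf[, "hom"] * cf$x_hom
  for (j in seq_len(nrow(cf))) {
    s <- cf$snp_id[j]
    cl <- if (s %in% colnames(calls)) calls[, s] else rep("missing", n)
    x[, j] <- c(non_carrier = 0, heterozygous = 1,
                homozygous_risk = cf$x_hom[j],
                missing = if (missing == "hwe") x_expect[j] else 0)[cl]
    n_miss <- n_miss + (cl == "missing")
  }
  new("EncodedProfiles", subjectId = subjectId(profiles),
      stratum = stratum(profiles), x = x, nMissing = as.integer(n_miss))
}
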