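#' Construct a marker catalog from a data.frame
#'
#' @param markers data.frame with columns \code{snp_id}, \code{risk_allele},
#'   \code{freq}, \code{or_het} and optionally \code{or_hom}, \code{freq_all},
#'   \code{source}. Missing optional columns are filled with \code{NA}.
#' @param populationLabel free-text population label.
#' @return a [SNPMarkerCatalog-class]
#' @export
SNPMarkerCatalog <- function(markers, populationLabel = NA_character_) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  for (col in c("freq_all", "or_hom")) {
    if (is.null(markers[[col]])) markers[[col]] <- NA_real_
  }
  if (is.null(markers$source)) markers$source <- NA_character_
  markers <- markers[, MARKER_COLUMNS, drop = FALSE]
  rownames(markers) <- NULL
  new("SNPMarkerCatalog", markers = markers,
      populationLabel = as.character(populationLabel))
}

#' Read a SNP marker table
#'
#' Reads a tabular catalog of SNP risk factors, one row per SNP. Required
#' headers: \code{snp_id}, \code{risk_allele}, \code{freq}, \code{or_het},
#' \code{or_hom}, \code{source}; an optional \code{freq_all} column is kept
#' for provenance. \code{or_hom} may be empty or the literal \code{"NA"}
#' when the homozygous odds ratio is unavailable.
#'
#' @param path path to the marker table.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @param populationLabel optional population label stored on the catalog.
#' @return a validated [SNPMarkerCatalog-class]; row order is preserved.
#' @examples
#' tbl <- system.file("extdata", "lung_markers.tsv", package = "snplogit")
#' cat <- readMarkerTable(tbl, populationLabel = "Chinese")
#' length(cat)  # 8
#' @export
readMarkerTable <- function(path, dialect = c("tsv", "csv"),
                            populationLabel = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("marker table not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character",
                           na.strings = c("NA", ""), quote = "\"",
                           stringsAsFactors = FALSE, check.names = TRUE)
  required <- c("snp_id", "risk_allele", "freq", "or_het", "or_hom", "source")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("marker table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  parse_num <- function(col, allow_na = FALSE) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(allow_na & is.na(raw[[col]])))
    if (length(bad))
      stop("non-numeric ", col, " in marker table row(s): ",
           paste(bad, collapse = ", "))
    v
  }
  m <- data.frame(
    snp_id = raw$snp_id,
    risk_allele = toupper(trimws(raw$risk_allele)),
    freq = parse_num("freq"),
    freq_all = if ("freq_all" %in% names(raw)) parse_num("freq_all", allow_na = TRUE)
               else NA_real_,
    or_het = parse_num("or_het"),
    or_hom = parse_num("or_hom", allow_na = TRUE),
    source = raw$source,
    stringsAsFactors = FALSE)
  bad_freq <- which(m$freq <= 0 | m$freq >= 1)
  if (length(bad_freq))
    stop("freq outside (0,1) in marker table row(s): ",
         paste(bad_freq, collapse = ", "))
  if (anyDuplicated(m$snp_id))
    stop("duplicate rsID in marker table row(s): ",
         paste(which(duplicated(m$snp_id)), collapse = ", "))
  SNPMarkerCatalog(m, populationLabel)
}

#' Write a marker catalog back to a table
#'
#' Inverse of [readMarkerTable()]; numeric fields round-trip at stored
#' precision (written with \code{format(..., digits = 15)}).
#'
#' @param catalog a [SNPMarkerCatalog-class]
#' @param path output path
#' @param dialect \code{"tsv"} or \code{"csv"}
#' @return \code{path}, invisibly
#' @export
writeMarkerTable <- function(catalog, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(is(catalog, "SNPMarkerCatalog"))
  sep <- if (dialect == "tsv") "\t" else ","
  m <- markers(catalog)
  for (col in c("freq", "freq_all", "or_het", "or_hom"))
    m[[col]] <- vapply(m[[col]], function(v)
      if (is.na(v)) NA_character_ else format(v, digits = 15), character(1))
  utils::write.table(m, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Filter markers by heterozygous odds ratio
#'
#' Retains markers whose heterozygous OR is at least \code{threshold}
#' (default 1.15, the customary lower bound for including a marker in the
#' model). The filter deliberately applies to the heterozygous OR only.
#'
#' @param catalog a [SNPMarkerCatalog-class]
#' @param threshold OR lower bound, > 0
#' @return a new catalog with the retained markers in their original order;
#'   the input is unchanged. An empty result is legal.
#' @export
filterByOR <- function(catalog, threshold = 1.15) {
  stopifnot(is(catalog, "SNPMarkerCatalog"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive number")
  keep <- markers(catalog)$or_het >= threshold
  SNPMarkerCatalog(markers(catalog)[keep, , drop = FALSE],
                   populationLabel(catalog))
}

#' Hardy-Weinberg genotype frequencies
#'
#' Converts a risk-allele frequency \eqn{f} into the heterozygote and
#' risk-homozygote genotype frequencies expected under Hardy-Weinberg
#' equilibrium: \eqn{2f(1-f)} and \eqn{f^2}.
#'
#' @param freq risk-allele frequency (vectorised), each in (0,1)
#' @return a two-column matrix with columns \code{het} and \code{hom}
#' @examples
#' hweGenotypeFreqs(0.239)  # het 0.364, hom 0.057 (3 dp)
#' @export
hweGenotypeFreqs <- function(freq) {
  if (!is.numeric(freq) || any(!is.finite(freq) | freq <= 0 | freq >= 1))
    stop("freq must lie strictly in (0,1)")
  cbind(het = 2 * freq * (1 - freq), hom = freq^2)
}
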