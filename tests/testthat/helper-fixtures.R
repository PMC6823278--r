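# shared fixtures: the packaged 8-SNP lung-cancer catalog and raw copies of
# its published inputs, kept as plain numbers so oracle arithmetic in the
# tests stays independent of the package's readers and builders

`%||%` <- function(a, b) if (is.null(a)) b else a

table1_path <- function()
  system.file("extdata", "lung_markers.tsv", package = "snplogit")

table1_catalog <- function()
  readMarkerTable(table1_path(), populationLabel = "Chinese")

lung_baselines <- function() c(men = 0.0562, women = 0.0256)

table1_model <- function(...)
  buildModel(table1_catalog(), lung_baselines(), ...)

# published inputs, typed in directly (not read through the package)
table1_raw <- function() data.frame(
  snp_id = c("rs1820453", "rs716274", "rs9981861", "rs16951095",
             "rs1051730", "rs402710", "rs2808630", "rs7626795"),
  risk_allele = c("G", "G", "G", "C", "T", "C", "G", "G"),
  f = c(0.239, 0.25, 0.125, 0.805, 0.037, 0.733, 0.22, 0.207),
  or_het = c(1.49, 1.83, 1.33, 1.3, 1.31, 1.18, 1.22, 1.16),
  or_hom = c(1.65, 2.96, NA, NA, NA, NA, NA, NA),
  stringsAsFactors = FALSE)

# build GenotypeProfiles from a subjects x SNPs matrix of class labels
make_profiles <- function(calls, stratum = "men",
                          ids = paste0("P", seq_len(nrow(calls)))) {
  if (length(stratum) == 1L) stratum <- rep(stratum, nrow(calls))
  GenotypeProfiles(ids, stratum, calls)
}

# minimal single-sample-per-column VCF writer for read tests
write_test_vcf <- function(path, records, samples) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}
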