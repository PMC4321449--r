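#' Read a dosage VCF
#'
#' Reads a VCF 4.x file carrying per-sample dosages in the `DS` FORMAT field
#' and, when present, per-variant imputation quality in the `RSQ` INFO key.
#' MAF and MAC are recomputed from the dosages on load. Multi-allelic sites
#' are readable and flagged `is_biallelic = FALSE` (they are removed later
#' by [filter_variants()], not here).
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return A [dosage_matrix()].
#' @export
read_dosage_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  fmt <- v@gt[, 1]
  if (!all(grepl("DS", fmt))) stop("FORMAT field lacks DS (dosage) entries")
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  rsq <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "RSQ")))
  variants <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"), fix$ID),
    ref = fix$REF,
    alt = fix$ALT,
    rsq = ifelse(is.na(rsq), 1, rsq),
    stringsAsFactors = FALSE
  )
  dosage_matrix(ds, variants, samples = colnames(ds))
}

#' Write a dosage VCF
#'
#' Emits a minimal VCF 4.2 file with one `DS` FORMAT value per sample and
#' the variant's imputation quality as the `RSQ` INFO key. Dosages are
#' written with 3 decimals.
#'
#' @param x A [dosage_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(x, path) {
  stopifnot(inherits(x, "dosage_matrix"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=RSQ,Number=1,Type=Float,Description=\"Imputation quality (variance ratio r2)\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            x$samples), collapse = "\t")
  )
  ds <- formatC(x$dosages, format = "f", digits = 3)
  ds[is.na(x$dosages)] <- "."
  body <- paste(
    x$variants$chrom, x$variants$pos, x$variants$id, x$variants$ref, x$variants$alt,
    ".", "PASS", sprintf("RSQ=%.4f", x$variants$rsq), "DS",
    apply(ds, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Variant inclusion filter for association analyses
#'
#' Applies the standard dosage-data inclusion rules: biallelic variants
#' only, minor allele count at least `mac_min` (inclusive) and imputation
#' quality strictly greater than `quality_min`. The filter is idempotent.
#'
#' @param x A [dosage_matrix()].
#' @param mac_min Minimum minor allele count (default 4, inclusive).
#' @param quality_min Imputation r-squared threshold (default 0.7, strict).
#' @param require_biallelic Drop multi-allelic sites (default TRUE).
#' @return List with `matrix` (the filtered [dosage_matrix()]) and `report`
#'   (a `filter_report`: counts in/out per rule and MAF-bin counts of the
#'   retained variants).
#' @export
filter_variants <- function(x, mac_min = 4, quality_min = 0.7, require_biallelic = TRUE) {
  stopifnot(inherits(x, "dosage_matrix"))
  v <- x$variants
  pass_bi <- if (require_biallelic) v$is_biallelic else rep(TRUE, nrow(v))
  pass_mac <- v$mac >= mac_min
  pass_rsq <- v$rsq > quality_min
  keep <- pass_bi & pass_mac & pass_rsq
  out <- x[keep, ]
  maf <- out$variants$maf
  report <- structure(list(
    n_in = nrow(v),
    n_out = sum(keep),
    n_fail_biallelic = sum(!pass_bi),
    n_fail_mac = sum(pass_bi & !pass_mac),
    n_fail_quality = sum(pass_bi & pass_mac & !pass_rsq),
    n_common = sum(maf >= 0.05),
    n_low_frequency = sum(maf < 0.05),
    n_rare = sum(maf < 0.01),
    mac_min = mac_min, quality_min = quality_min
  ), class = "filter_report")
  list(matrix = out, report = report)
}

#' @method print filter_report
#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d in -> %d retained\n", x$n_in, x$n_out))
  cat(sprintf("  removed: %d multi-allelic, %d MAC < %g, %d quality <= %g\n",
              x$n_fail_biallelic, x$n_fail_mac, x$mac_min, x$n_fail_quality, x$quality_min))
  cat(sprintf("  retained bins: %d common, %d low frequency (of which %d rare < 1%%)\n",
              x$n_common, x$n_low_frequency, x$n_rare))
  invisible(x)
}

#' Allele-frequency bin of a variant
#'
#' Bins by minor allele frequency: `common` when MAF >= 5%, `low_frequency`
#' below. Variants below 1% additionally carry a `rare` flag (see
#' [maf_is_rare()]). Monomorphic variants (MAF = 0) are untestable and map
#' to `NA` with a warning.
#'
#' @param maf Numeric vector of minor allele frequencies in `[0, 0.5]`.
#' @return Character vector of `"common"` / `"low_frequency"` labels.
#' @examples
#' maf_bin(c(0.05, 0.049, 0.009))
#' @export
maf_bin <- function(maf) {
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE)) stop("MAF must be in [0, 0.5]")
  out <- ifelse(maf >= 0.05, "common", "low_frequency")
  if (any(maf == 0, na.rm = TRUE)) {
    warning("monomorphic variant(s) (MAF = 0) are untestable; bin set to NA")
    out[maf == 0] <- NA_character_
  }
  out
}

#' @rdname maf_bin
#' @export
maf_is_rare <- function(maf) maf < 0.01 & maf > 0

#' Imputation quality of a dosage vector
#'
#' The MaCH-style variance-ratio r-squared: empirical dosage variance over
#' the binomial variance `2p(1-p)` implied by the allele frequency estimated
#' from the mean dosage. Values are clipped to `[0, 1]`. A variant whose
#' dosages are all equal to twice its allele frequency carries no genotype
#' information and scores 0; hard genotypes in Hardy-Weinberg proportions
#' score about 1.
#'
#' @param d Numeric dosage vector (length >= 2) or a variants-by-samples
#'   matrix (one estimate per row).
#' @return r-squared estimate(s) in `[0, 1]`; `NA` with a warning for
#'   monomorphic variants (estimated frequency 0 or 1).
#' @export
estimate_imputation_quality <- function(d) {
  if (is.matrix(d)) return(apply(d, 1, estimate_imputation_quality))
  d <- d[!is.na(d)]
  if (length(d) < 2) stop("need at least 2 samples")
  p <- mean(d) / 2
  if (p <= 0 || p >= 1) {
    warning("monomorphic variant: imputation quality undefined")
    return(NA_real_)
  }
  # population variance (divide by n), matching the binomial denominator
  v <- mean((d - mean(d))^2)
  min(1, max(0, v / (2 * p * (1 - p))))
}
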