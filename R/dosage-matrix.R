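#' Dosage matrix container
#'
#' Holds per-sample genotype dosages (expected minor-allele counts in
#' `[0, 2]`) for a set of variants, together with per-variant metadata. MAF
#' and MAC are recomputed from the dosages: MAF from the mean dosage, MAC
#' from dosages rounded to the nearest hard genotype (stable under small
#' dosage noise).
#'
#' @param dosages Numeric matrix, variants in rows, samples in columns,
#'   values in `[0, 2]` (NA allowed for missing entries).
#' @param variants Data frame with one row per variant; must contain
#'   `chrom`, `pos`, `ref`, `alt`; optional `id`, `rsq` (imputation
#'   quality), `kind` (`"SNP"`/`"indel"`).
#' @param samples Character vector of sample identifiers (defaults to the
#'   dosage column names).
#' @return Object of class `dosage_matrix`: list with elements `dosages`,
#'   `variants` (metadata including computed `maf`, `mac`, `is_biallelic`)
#'   and `samples`.
#' @export
dosage_matrix <- function(dosages, variants, samples = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (!is.numeric(dosages)) stop("dosages must be numeric")
  rng <- range(dosages, na.rm = TRUE)
  if (ncol(dosages) > 0 && (rng[1] < -1e-8 || rng[2] > 2 + 1e-8)) {
    stop("dosages must lie in [0, 2]")
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variants is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(variants) != nrow(dosages)) stop("variants and dosages disagree on variant count")
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(dosages)))
  if (is.null(variants$id)) {
    variants$id <- paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
  }
  if (is.null(variants$rsq)) variants$rsq <- 1
  if (is.null(variants$kind)) {
    variants$kind <- ifelse(nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
                              !grepl(",", variants$alt), "SNP", "indel")
  }
  variants$is_biallelic <- !grepl(",", variants$alt)
  fq <- dosage_freq(dosages)
  variants$maf <- fq$maf
  variants$mac <- fq$mac
  rownames(dosages) <- variants$id
  colnames(dosages) <- samples
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "dosage_matrix")
}

## alt-allele frequency, MAF and hard-call MAC from a dosage matrix
dosage_freq <- function(d) {
  n_ok <- rowSums(!is.na(d))
  af <- rowSums(d, na.rm = TRUE) / (2 * pmax(n_ok, 1L))
  maf <- pmin(af, 1 - af)
  hard <- round(d)
  alt_count <- rowSums(hard, na.rm = TRUE)
  mac <- pmin(alt_count, 2 * n_ok - alt_count)
  list(af = af, maf = maf, mac = as.integer(mac))
}

#' @method print dosage_matrix
#' @export
print.dosage_matrix <- function(x, ...) {
  cat("dosage_matrix:", nrow(x$dosages), "variants x", length(x$samples), "samples\n")
  nb <- table(factor(maf_bin(pmax(x$variants$maf, 1e-12)),
                     levels = c("common", "low_frequency")))
  cat(sprintf("  common (MAF >= 5%%): %d, low frequency (< 5%%): %d\n",
              nb[["common"]], nb[["low_frequency"]]))
  invisible(x)
}

#' @export
`[.dosage_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_along(x$samples)
  dosage_matrix(x$dosages[i, j, drop = FALSE],
                x$variants[i, , drop = FALSE],
                samples = x$samples[j])
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosages)
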