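#' Genotype call set
#'
#' Light container for call-set comparisons: per-site metadata, hard
#' genotypes (0 = hom-ref, 1 = het, 2 = hom-alt, NA = missing) and,
#' optionally, per-genotype sequencing depth.
#'
#' @param variants Data frame with `chrom`, `pos`, `ref`, `alt`.
#' @param genotypes Sites x samples integer matrix in `{0, 1, 2, NA}`.
#'   Dosages are accepted and rounded to the nearest hard call.
#' @param depth Optional sites x samples numeric matrix of read depths.
#' @param samples Sample identifiers.
#' @return Object of class `call_set`.
#' @export
call_set <- function(variants, genotypes, depth = NULL, samples = colnames(genotypes)) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  genotypes <- round(as.matrix(genotypes))
  if (!all(genotypes %in% c(0, 1, 2, NA))) stop("genotypes must round to 0/1/2 or NA")
  stopifnot(nrow(variants) == nrow(genotypes))
  if (!is.null(depth)) stopifnot(all(dim(depth) == dim(genotypes)))
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(genotypes)))
  variants$is_biallelic <- !grepl(",", variants$alt)
  structure(list(variants = variants, genotypes = genotypes, depth = depth,
                 samples = samples),
            class = "call_set")
}

site_key <- function(v) paste(v$chrom, v$pos, sep = ":")

in_mask <- function(v, mask) {
  if (is.null(mask) || nrow(mask) == 0) return(rep(FALSE, nrow(v)))
  hit <- rep(FALSE, nrow(v))
  for (i in seq_len(nrow(mask))) {
    hit <- hit | (v$chrom == mask$chrom[i] &
                    v$pos >= mask$start[i] & v$pos <= mask$end[i])
  }
  hit
}

subset_call_set <- function(cs, keep) {
  call_set(cs$variants[keep, , drop = FALSE],
           cs$genotypes[keep, , drop = FALSE],
           depth = if (is.null(cs$depth)) NULL else cs$depth[keep, , drop = FALSE],
           samples = cs$samples)
}

#' Site-level overlap between a query and a truth call set
#'
#' Applies, in order, the three comparison filters to both sets: (1) drop
#' sites inside the excluded-region mask, (2) drop sites where any truth
#' genotype was called below `min_truth_depth` coverage, (3) drop
#' non-biallelic sites from the respective set. Then computes the two-way
#' overlap on (chrom, pos) keys: the true-positive proportion
#' `|query & truth| / |query|` and the false-negative rate
#' `|truth \ query| / |truth|`.
#'
#' @param query,truth [call_set()] objects on the same coordinates.
#' @param mask Optional data frame of excluded regions (`chrom`, `start`,
#'   `end`, 1-based inclusive).
#' @param min_truth_depth Optional depth threshold; a site is removed from
#'   both sets when any truth genotype at it has depth below the threshold.
#' @return List with `tp_proportion`, `fn_rate`, `n_query`, `n_truth`,
#'   `n_shared`, and the filtered sets (`query`, `truth`).
#' @export
site_overlap <- function(query, truth, mask = NULL, min_truth_depth = NULL) {
  stopifnot(inherits(query, "call_set"), inherits(truth, "call_set"))
  qk <- !in_mask(query$variants, mask)
  tk <- !in_mask(truth$variants, mask)
  query <- subset_call_set(query, qk)
  truth <- subset_call_set(truth, tk)
  if (!is.null(min_truth_depth)) {
    if (is.null(truth$depth)) stop("truth set has no depth data for the depth filter")
    low <- rowSums(truth$depth < min_truth_depth, na.rm = TRUE) > 0
    bad_keys <- site_key(truth$variants)[low]
    truth <- subset_call_set(truth, !low)
    query <- subset_call_set(query, !(site_key(query$variants) %in% bad_keys))
  }
  query <- subset_call_set(query, query$variants$is_biallelic)
  truth <- subset_call_set(truth, truth$variants$is_biallelic)
  qkeys <- site_key(query$variants)
  tkeys <- site_key(truth$variants)
  if (length(tkeys) == 0) stop("truth set empty after filtering; overlap undefined")
  if (length(qkeys) == 0) stop("query set empty after filtering; overlap undefined")
  shared <- intersect(qkeys, tkeys)
  list(tp_proportion = length(shared) / length(qkeys),
       fn_rate = length(setdiff(tkeys, qkeys)) / length(tkeys),
       n_query = length(qkeys), n_truth = length(tkeys),
       n_shared = length(shared), query = query, truth = truth)
}

#' Genotype concordance between call sets at overlapping sites
#'
#' Counts a 3x3 matrix of (truth class x query class) over hom-ref, het
#' and hom-alt at the shared (chrom, pos) sites and shared samples.
#' Overall concordance is the diagonal fraction; non-reference concordance
#' excludes the truth-hom-ref/query-hom-ref cell from numerator and
#' denominator (the agreement that comes free with rare alternate
#' alleles). A per-sample concordance vector feeds sample-swap detection.
#'
#' @param query,truth [call_set()] objects.
#' @return Object of class `concordance_report`: `matrix` (3x3 counts),
#'   `overall`, `nonref` (NA with a warning when no non-reference cell is
#'   populated), `per_sample` (named vector), `n_sites`, `n_samples`.
#' @export
genotype_concordance <- function(query, truth) {
  stopifnot(inherits(query, "call_set"), inherits(truth, "call_set"))
  samples <- intersect(query$samples, truth$samples)
  if (!length(samples)) stop("no shared samples between call sets")
  qi <- match(samples, query$samples)
  ti <- match(samples, truth$samples)
  keys <- intersect(site_key(query$variants), site_key(truth$variants))
  if (!length(keys)) stop("no shared sites between call sets")
  qs <- match(keys, site_key(query$variants))
  ts <- match(keys, site_key(truth$variants))
  Q <- query$genotypes[qs, qi, drop = FALSE]
  T_ <- truth$genotypes[ts, ti, drop = FALSE]
  ok <- !is.na(Q) & !is.na(T_)
  classes <- c("hom_ref", "het", "hom_alt")
  M <- table(factor(T_[ok], levels = 0:2, labels = classes),
             factor(Q[ok], levels = 0:2, labels = classes))
  M <- unclass(as.matrix(M))
  names(dimnames(M)) <- c("truth", "query")
  total <- sum(M)
  overall <- sum(diag(M)) / total
  nr_den <- total - M[1, 1]
  nonref <- if (nr_den == 0) {
    warning("all genotypes hom-ref in both sets: non-reference concordance undefined")
    NA_real_
  } else {
    (sum(diag(M)) - M[1, 1]) / nr_den
  }
  per_sample <- vapply(seq_along(samples), function(j) {
    okj <- ok[, j]
    if (!any(okj)) return(NA_real_)
    mean(Q[okj, j] == T_[okj, j])
  }, 0)
  names(per_sample) <- samples
  structure(list(matrix = M, overall = overall, nonref = nonref,
                 per_sample = per_sample, n_sites = length(keys),
                 n_samples = length(samples)),
            class = "concordance_report")
}

#' @method print concordance_report
#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance over %d sites x %d samples: overall %.4f, non-reference %s\n",
              x$n_sites, x$n_samples, x$overall,
              if (is.na(x$nonref)) "NA" else sprintf("%.4f", x$nonref)))
  print(x$matrix)
  invisible(x)
}

#' Transition/transversion ratio of a SNP call set
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine swaps
#' (A<->G, C<->T); all other single-base substitutions are transversions.
#' Indels must be excluded before calling.
#'
#' @param variants Data frame with single-base `ref` and `alt` columns.
#' @return Ti/Tv ratio.
#' @export
titv_ratio <- function(variants) {
  ref <- toupper(variants$ref)
  alt <- toupper(variants$alt)
  if (any(nchar(ref) != 1 | nchar(alt) != 1)) stop("Ti/Tv is defined for SNPs only")
  pair <- paste0(pmin(ref, alt), pmax(ref, alt))
  ti <- sum(pair %in% c("AG", "CT"))
  tv <- sum(!(pair %in% c("AG", "CT")))
  if (tv == 0) stop("no transversions observed: Ti/Tv undefined")
  ti / tv
}

#' Flag samples for exclusion by chip concordance
#'
#' Samples whose genotype concordance with an orthogonal genotyping array
#' fails the keep rule (strictly above `keep_threshold`) are flagged for
#' exclusion; those whose concordance falls in the swap band (around the
#' ~50% agreement a mixed-up sample shows against its labelled array data)
#' are additionally labelled swap-like.
#'
#' @param per_sample Named numeric vector of per-sample concordances in
#'   `[0, 1]`.
#' @param keep_threshold Keep rule (default 0.98, strict: exactly 0.98 is
#'   flagged).
#' @param swap_band Two-element concordance interval labelled swap-like
#'   (default `c(0.4, 0.6)`).
#' @return Data frame with `sample`, `concordance`, `keep`, `swap_like`.
#' @export
detect_sample_swaps <- function(per_sample, keep_threshold = 0.98,
                                swap_band = c(0.4, 0.6)) {
  if (any(per_sample < 0 | per_sample > 1, na.rm = TRUE)) {
    stop("concordances must be in [0, 1]")
  }
  data.frame(
    sample = names(per_sample) %||% seq_along(per_sample),
    concordance = as.numeric(per_sample),
    keep = per_sample > keep_threshold,
    swap_like = per_sample >= swap_band[1] & per_sample <= swap_band[2],
    row.names = NULL
  )
}
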