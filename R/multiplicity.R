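#' Pairwise LD between two dosage vectors
#'
#' Linkage disequilibrium measured as the squared Pearson correlation of
#' dosages; invariant to allele flips (`2 - x`). For independent variants
#' the null expectation is about `1/(n-1)`.
#'
#' @param a,b Numeric dosage vectors of equal length, both polymorphic.
#' @return r-squared in `[0, 1]`.
#' @export
pairwise_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("r2 undefined for a constant (monomorphic) dosage vector")
  }
  min(1, stats::cor(a, b)^2)
}

#' Greedy LD binning of a variant window
#'
#' The tagSNP binning algorithm used to count independent variants:
#' repeatedly pick the unbinned variant with the most unbinned companions
#' at `r2 > r2_threshold`, form a bin of the tag plus those companions, and
#' remove them; variants with no companions become singleton bins. The
#' number of bins estimates the number of independent variants in the
#' window. Ties on companion count are broken by lowest genomic position.
#'
#' @param D Variants x samples dosage matrix (>= 1 variant).
#' @param pos Genomic positions (tie-break order); defaults to row order.
#' @param r2_threshold Binning threshold (default 0.8): variants are
#'   companions when their pairwise r-squared exceeds it.
#' @return Object of class `ld_bin_set`: list with `bins` (list of integer
#'   vectors of row indices, first element the tag), `n_bins`,
#'   `r2_threshold`.
#' @export
ldselect_bins <- function(D, pos = seq_len(nrow(D)), r2_threshold = 0.8) {
  D <- as.matrix(D)
  m <- nrow(D)
  if (m < 1) stop("need at least one variant")
  if (m == 1) {
    return(structure(list(bins = list(1L), n_bins = 1L, r2_threshold = r2_threshold),
                     class = "ld_bin_set"))
  }
  R2 <- suppressWarnings(stats::cor(t(D)))^2
  R2[is.na(R2)] <- 0
  comp <- R2 > r2_threshold
  diag(comp) <- FALSE
  # companion counts among still-unbinned variants, updated incrementally
  # as bins are removed (the greedy result is identical to recomputing)
  unbinned <- rep(TRUE, m)
  counts <- rowSums(comp)
  ord <- order(pos)
  rank_pos <- integer(m)
  rank_pos[ord] <- seq_len(m)
  bins <- list()
  while (any(unbinned)) {
    idx <- which(unbinned)
    best <- idx[order(-counts[idx], rank_pos[idx])][1]
    members <- idx[comp[best, idx]]
    bin <- c(best, members)
    bins[[length(bins) + 1L]] <- bin
    unbinned[bin] <- FALSE
    counts <- counts - if (length(bin) == 1) comp[bin, ] else colSums(comp[bin, , drop = FALSE])
  }
  structure(list(bins = bins, n_bins = length(bins), r2_threshold = r2_threshold),
            class = "ld_bin_set")
}

#' @method print ld_bin_set
#' @export
print.ld_bin_set <- function(x, ...) {
  cat(sprintf("ld_bin_set: %d bins at r2 > %g (%d variants)\n",
              x$n_bins, x$r2_threshold, sum(lengths(x$bins))))
  invisible(x)
}

#' Independent-variant counts in randomly drawn windows
#'
#' Estimates the average number of independent variants per window by
#' drawing one window per chromosome (or `n_windows` windows from a single
#' simulated chromosome, flagged), applying the inclusion filters
#' (imputation quality strictly above `quality_min`, MAC >= `mac_min`),
#' and greedy LD binning each window. Counts are reported for all retained
#' variants and separately for the low-frequency and common strata (each
#' stratum binned on its own).
#'
#' @param dm A [dosage_matrix()].
#' @param n_windows Number of windows when only one chromosome is present
#'   (default 22, one per autosome otherwise).
#' @param window_len Window length in bp (default 2 Mb).
#' @param r2_threshold Binning threshold (default 0.8).
#' @param quality_min,mac_min Inclusion filters (defaults 0.7 strict, 4).
#' @param seed Integer seed for the window draws.
#' @return List with `per_window` (data frame: window coordinates and
#'   counts `n_all`, `n_low`, `n_common`), `mean_all`, `mean_low`,
#'   `mean_common`, `single_chromosome` flag.
#' @export
estimate_independent_per_window <- function(dm, n_windows = 22, window_len = 2e6,
                                            r2_threshold = 0.8, quality_min = 0.7,
                                            mac_min = 4, seed = 1) {
  stopifnot(inherits(dm, "dosage_matrix"))
  set.seed(seed)
  v <- dm$variants
  chroms <- unique(v$chrom)
  single <- length(chroms) == 1
  draws <- if (single) {
    span <- range(v$pos)
    if (diff(span) < window_len) {
      data.frame(chrom = chroms, start = rep(span[1], n_windows))
    } else {
      data.frame(chrom = chroms,
                 start = sample(seq(span[1], span[2] - window_len), n_windows,
                                replace = TRUE))
    }
  } else {
    do.call(rbind, lapply(chroms, function(ch) {
      span <- range(v$pos[v$chrom == ch])
      st <- if (diff(span) < window_len) span[1] else
        sample(seq(span[1], max(span[1], span[2] - window_len)), 1)
      data.frame(chrom = ch, start = st)
    }))
  }
  count_bins <- function(idx) {
    if (!length(idx)) return(0L)
    ldselect_bins(dm$dosages[idx, , drop = FALSE], pos = v$pos[idx],
                  r2_threshold = r2_threshold)$n_bins
  }
  rows <- lapply(seq_len(nrow(draws)), function(i) {
    ch <- draws$chrom[i]; st <- draws$start[i]
    idx <- which(v$chrom == ch & v$pos >= st & v$pos < st + window_len &
                   v$rsq > quality_min & v$mac >= mac_min & v$maf > 0)
    low <- idx[v$maf[idx] < 0.05]
    com <- idx[v$maf[idx] >= 0.05]
    data.frame(chrom = ch, start = st, end = st + window_len,
               n_variants = length(idx),
               n_all = count_bins(idx), n_low = count_bins(low),
               n_common = count_bins(com),
               empty = length(idx) == 0L)
  })
  per_window <- do.call(rbind, rows)
  list(per_window = per_window,
       mean_all = mean(per_window$n_all),
       mean_low = mean(per_window$n_low),
       mean_common = mean(per_window$n_common),
       single_chromosome = single)
}

#' Effective number of independent tests and Bonferroni threshold
#'
#' Combines the per-window independent-variant count into a study-wide
#' multiplicity correction. In `cis` mode each phenotype contributes one
#' window: `total = per_window_count * n_phenotypes`. In `genome` mode the
#' per-window count is first scaled to the whole genome by the approximate
#' number of windows it contains (`genome_multiplier`, default 1500 for
#' 2 Mb windows), then multiplied by the number of phenotypes.
#'
#' @param per_window_count Average independent variants per window.
#' @param mode `"cis"` or `"genome"`.
#' @param n_phenotypes Number of phenotypes tested.
#' @param genome_multiplier Approximate windows per genome (default 1500).
#' @param alpha_family Family-wise error rate (default 0.05).
#' @return List of class `threshold_spec`: `per_window_count`, `mode`,
#'   `n_phenotypes`, `genome_multiplier` (genome mode), `total_tests`,
#'   `alpha_family`, `bonferroni_p`.
#' @examples
#' effective_tests(2848, "cis", n_phenotypes = 11122)$total_tests  # 31675456
#' @export
effective_tests <- function(per_window_count, mode = c("cis", "genome"),
                            n_phenotypes = 1, genome_multiplier = 1500,
                            alpha_family = 0.05) {
  mode <- match.arg(mode)
  if (per_window_count <= 0 || n_phenotypes <= 0) stop("counts must be positive")
  total <- if (mode == "cis") {
    per_window_count * n_phenotypes
  } else {
    per_window_count * genome_multiplier * n_phenotypes
  }
  if (total <= 0) stop("zero total tests")
  structure(list(per_window_count = per_window_count, mode = mode,
                 n_phenotypes = n_phenotypes,
                 genome_multiplier = if (mode == "genome") genome_multiplier else NA,
                 total_tests = total, alpha_family = alpha_family,
                 bonferroni_p = alpha_family / total),
            class = "threshold_spec")
}

#' @method print threshold_spec
#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("threshold_spec (%s): %s independent tests, Bonferroni p = %.2g\n",
              x$mode, format(x$total_tests, big.mark = ","), x$bonferroni_p))
  invisible(x)
}

#' False-discovery-rate estimate at a p-value threshold
#'
#' Expected false positives (`p_threshold` times the number of independent
#' tests) divided by the observed number of hits at that threshold.
#'
#' @param p_threshold P-value threshold.
#' @param total_tests Number of independent tests.
#' @param n_hits Observed discoveries at the threshold (> 0).
#' @return FDR estimate.
#' @export
estimate_fdr <- function(p_threshold, total_tests, n_hits) {
  if (n_hits <= 0) stop("FDR undefined with zero observed hits")
  (p_threshold * total_tests) / n_hits
}
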