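#' Most significant variant in the opposing MAF bin
#'
#' Given the association results of a region and the bin of the index
#' variant, returns the minimum-p variant of the opposite allele-frequency
#' bin (common vs low frequency), or `NULL` when that bin is empty in the
#' region. Ties in p are broken by lower genomic position.
#'
#' @param region_results Data frame of association results carrying `maf`,
#'   `p`, `pos` columns (e.g. `scan_cis()$results`).
#' @param index_bin Bin of the index variant: `"common"` or
#'   `"low_frequency"`.
#' @return One-row data frame or `NULL`.
#' @export
best_opposing_variant <- function(region_results, index_bin) {
  index_bin <- match.arg(index_bin, c("common", "low_frequency"))
  opp <- setdiff(c("common", "low_frequency"), index_bin)
  res <- region_results[!is.na(region_results$p) & region_results$maf > 0, ]
  if (!nrow(res)) return(NULL)
  res <- res[maf_bin(res$maf) == opp, ]
  if (!nrow(res)) return(NULL)
  res[order(res$p, res$pos), ][1, ]
}

#' Conditional association test
#'
#' Multiple regression of the phenotype on the index variant's dosage plus
#' a set of conditioning dosages; reports the index variant's partial
#' effect, standard error and p-value. An empty conditioning set reduces
#' exactly to the unconditional OLS test. An index that is essentially a
#' copy of a conditioner (r-squared > `collinear_r2`) is reported as an
#' `"untestable_collinear"` record rather than fit; conditioners collinear
#' among themselves are dropped with a warning.
#'
#' @param y Phenotype (vector or [prepare_phenotype()]).
#' @param index_dosage Dosage vector of the index variant.
#' @param conditioning Dosage vector, matrix (variants in rows or a
#'   samples-by-k matrix with `by_row = FALSE`), or `NULL`.
#' @param by_row Are conditioning variants in rows (default TRUE, matching
#'   [dosage_matrix()] orientation)?
#' @param collinear_r2 Guard threshold (default 0.999).
#' @param variant_id,trait_id Labels.
#' @return One-row association record; `conditioning` records the number
#'   of covariate dosages retained, `note` flags collinearity.
#' @export
conditional_test <- function(y, index_dosage, conditioning = NULL, by_row = TRUE,
                             collinear_r2 = 0.999, variant_id = "v",
                             trait_id = "t") {
  yv <- pheno_values(y)
  n <- length(yv)
  if (length(index_dosage) != n) stop("index dosage length mismatch")
  C <- NULL
  if (!is.null(conditioning) && length(conditioning)) {
    C <- if (is.matrix(conditioning)) {
      if (by_row) t(conditioning) else conditioning
    } else {
      matrix(conditioning, ncol = 1)
    }
    if (nrow(C) != n) stop("conditioning dosage length mismatch")
    for (k in seq_len(ncol(C))) {
      if (stats::var(C[, k]) > 0 && stats::var(index_dosage) > 0 &&
          stats::cor(index_dosage, C[, k])^2 > collinear_r2) {
        return(assoc_record(variant_id, trait_id, NA, NA, NA, n, "ols",
                            conditioning = sprintf("%d", ncol(C)),
                            note = "untestable_collinear"))
      }
    }
    # drop conditioners collinear among themselves (keep full rank)
    X <- cbind(1, C)
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) {
      keep <- sort(qrx$pivot[seq_len(qrx$rank)])
      keep <- setdiff(keep, 1L) - 1L
      warning("dropping ", ncol(C) - length(keep), " collinear conditioning dosage(s)")
      C <- C[, keep, drop = FALSE]
      if (ncol(C) == 0) C <- NULL
    }
  }
  if (stats::var(index_dosage) == 0) {
    return(assoc_record(variant_id, trait_id, NA, NA, NA, n, "ols",
                        note = "untestable"))
  }
  k <- if (is.null(C)) 0L else ncol(C)
  if (k == 0L) {
    fit <- ols_core(index_dosage, yv)
  } else {
    X <- cbind(`(Intercept)` = 1, C, index = index_dosage)
    ft <- stats::lm.fit(X, yv)
    df <- n - ncol(X)
    rss <- sum(ft$residuals^2)
    XtXinv <- chol2inv(qr.R(ft$qr))
    j <- ncol(X)
    se <- sqrt(rss / df * XtXinv[j, j])
    beta <- ft$coefficients[j]
    fit <- list(beta = beta, se = se,
                p = 2 * stats::pt(abs(beta / se), df, lower.tail = FALSE))
  }
  assoc_record(variant_id, trait_id, fit$beta, fit$se, fit$p, n, "ols",
               conditioning = sprintf("%d", k))
}

#' Association-based variant clumping
#'
#' PLINK-style greedy thinning: among variants with `p < p_max`, repeatedly
#' take the most significant remaining variant as a clump index and remove
#' every remaining variant in LD with it at `r2 >= r2_max`. Surviving
#' indices are mutually below the r-squared ceiling.
#'
#' @param region_results Association results data frame with `id`, `p`,
#'   `pos` (rows aligned with `D`).
#' @param D Dosage matrix for the same variants (rows aligned with
#'   `region_results`).
#' @param p_max Significance ceiling for clump membership (default 1e-4).
#' @param r2_max LD ceiling between surviving indices (default 0.2).
#' @return Object of class `clump_set`: list with `index_rows` (integer
#'   rows of `region_results` surviving), `indices` (their subset of the
#'   results), `p_max`, `r2_max`.
#' @export
clump <- function(region_results, D, p_max = 1e-4, r2_max = 0.2) {
  stopifnot(nrow(region_results) == nrow(D))
  cand <- which(!is.na(region_results$p) & region_results$p < p_max)
  surv <- integer(0)
  if (length(cand)) {
    cand <- cand[order(region_results$p[cand], region_results$pos[cand])]
    active <- rep(TRUE, length(cand))
    for (i in seq_along(cand)) {
      if (!active[i]) next
      surv <- c(surv, cand[i])
      if (i < length(cand)) {
        rest <- which(active)
        rest <- rest[rest > i]
        for (j in rest) {
          r2 <- suppressWarnings(stats::cor(D[cand[i], ], D[cand[j], ])^2)
          if (!is.na(r2) && r2 >= r2_max) active[j] <- FALSE
        }
      }
    }
  }
  structure(list(index_rows = surv,
                 indices = region_results[surv, , drop = FALSE],
                 p_max = p_max, r2_max = r2_max),
            class = "clump_set")
}

#' @method print clump_set
#' @export
print.clump_set <- function(x, ...) {
  cat(sprintf("clump_set: %d index variant(s) at p < %g, r2 < %g\n",
              length(x$index_rows), x$p_max, x$r2_max))
  invisible(x)
}

#' Classify a conditional-analysis outcome
#'
#' Labels an index signal by what conditioning did to it:
#' `fully_explained` when all evidence of association is lost (conditional
#' p > 0.05), `retained` when it still clears the discovery threshold,
#' `attenuated` in between. A conditional test reported as collinear maps
#' to `collinear` and is excluded from classification counts.
#'
#' @param unconditional_p,conditional_p P-values before/after conditioning.
#' @param discovery_threshold Study discovery threshold (e.g. 1e-6).
#' @return Character label.
#' @export
classify_signal <- function(unconditional_p, conditional_p, discovery_threshold) {
  if (is.na(conditional_p)) return("collinear")
  if (is.na(unconditional_p)) stop("unconditional p must be defined")
  if (conditional_p > 0.05) "fully_explained"
  else if (conditional_p <= discovery_threshold) "retained"
  else "attenuated"
}

#' Conditional classification of an index signal against the opposing bin
#'
#' The two-stage decision procedure for one region: find the index
#' variant's opposing-bin competition, condition the index on either the
#' single best opposing variant (`mode = "single"`) or on all clumped
#' opposing-bin variants with `p < p_max` at mutual `r2 < r2_max`
#' (`mode = "full"`), and classify the outcome.
#'
#' @param y Prepared phenotype.
#' @param dm [dosage_matrix()] covering the region.
#' @param region_results Association results for the region's variants
#'   (rows aligned with `dm`).
#' @param index_row Row index (into `region_results`/`dm`) of the index
#'   variant.
#' @param discovery_threshold Discovery threshold for the `retained` label.
#' @param mode `"single"` or `"full"`.
#' @param p_max,r2_max Clumping parameters for `mode = "full"`.
#' @return Object of class `signal_record`: list with the index identity
#'   and bin, `unconditional_p`, conditioning variant ids, `conditional_p`,
#'   `classification`.
#' @export
condition_on_opposing_bin <- function(y, dm, region_results, index_row,
                                      discovery_threshold, mode = c("single", "full"),
                                      p_max = 1e-4, r2_max = 0.2) {
  mode <- match.arg(mode)
  stopifnot(nrow(region_results) == nrow(dm$dosages))
  idx <- region_results[index_row, ]
  index_bin <- maf_bin(idx$maf)
  opp_bin <- setdiff(c("common", "low_frequency"), index_bin)
  testable <- !is.na(region_results$p) & region_results$maf > 0
  opp_rows <- which(testable & maf_bin(pmax(region_results$maf, 1e-12)) == opp_bin)
  opp_rows <- setdiff(opp_rows, index_row)   # never condition on self
  cond_rows <- integer(0)
  if (length(opp_rows)) {
    if (mode == "single") {
      best <- opp_rows[order(region_results$p[opp_rows], region_results$pos[opp_rows])][1]
      cond_rows <- best
    } else {
      cl <- clump(region_results[opp_rows, , drop = FALSE],
                  dm$dosages[opp_rows, , drop = FALSE],
                  p_max = p_max, r2_max = r2_max)
      cond_rows <- opp_rows[cl$index_rows]
    }
  }
  cond <- if (length(cond_rows)) dm$dosages[cond_rows, , drop = FALSE] else NULL
  rec <- conditional_test(y, dm$dosages[index_row, ], cond,
                          variant_id = idx$id, trait_id = idx$trait %||% "trait")
  label <- if (length(cond_rows) == 0) {
    "no_opposing_variant"
  } else {
    classify_signal(idx$p, rec$p, discovery_threshold)
  }
  structure(list(index_id = idx$id, index_bin = index_bin,
                 unconditional_p = idx$p,
                 conditioning_ids = region_results$id[cond_rows],
                 conditional_p = rec$p, classification = label, mode = mode),
            class = "signal_record")
}

#' @method print signal_record
#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("signal %s (%s): p %.3g -> %.3g conditioning on %d variant(s): %s\n",
              x$index_id, x$index_bin, x$unconditional_p,
              if (is.na(x$conditional_p)) NA else x$conditional_p,
              length(x$conditioning_ids), x$classification))
  invisible(x)
}

#' Compare signal detection between two dosage call sets
#'
#' For each index signal discovered in call set A, looks for a proxy
#' association in call set B's results for the same trait within
#' `proxy_window` of the A index position, and reports the fraction of A
#' signals detected in B at the strict (discovery) and loose thresholds,
#' plus the fraction whose B evidence is weaker than A's or absent
#' altogether. A trait missing from B counts as no proxy.
#'
#' @param signals_a Data frame of A index signals with `trait`, `chrom`,
#'   `pos`, `p`.
#' @param results_b Data frame of B association results with `trait`,
#'   `chrom`, `pos`, `p`.
#' @param strict_threshold Discovery threshold (e.g. 1e-6).
#' @param loose_threshold Relaxed threshold (default 1e-4).
#' @param proxy_window Half-window around the A index (default 250 kb).
#' @return List with `per_signal` (data frame: best B p per A signal and
#'   detection flags), `frac_detected_strict`, `frac_detected_loose`,
#'   `frac_weaker_or_absent`.
#' @export
compare_detection <- function(signals_a, results_b, strict_threshold,
                              loose_threshold = 1e-4, proxy_window = 250e3) {
  n <- nrow(signals_a)
  best_b <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sub <- results_b[results_b$trait == signals_a$trait[i] &
                       results_b$chrom == signals_a$chrom[i] &
                       abs(results_b$pos - signals_a$pos[i]) <= proxy_window &
                       !is.na(results_b$p), ]
    if (nrow(sub)) best_b[i] <- min(sub$p)
  }
  per_signal <- data.frame(
    trait = signals_a$trait, chrom = signals_a$chrom, pos = signals_a$pos,
    p_a = signals_a$p, best_p_b = best_b,
    detected_strict = !is.na(best_b) & best_b < strict_threshold,
    detected_loose = !is.na(best_b) & best_b < loose_threshold,
    weaker_or_absent = is.na(best_b) | best_b > signals_a$p
  )
  list(per_signal = per_signal,
       frac_detected_strict = mean(per_signal$detected_strict),
       frac_detected_loose = mean(per_signal$detected_loose),
       frac_weaker_or_absent = mean(per_signal$weaker_or_absent))
}
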