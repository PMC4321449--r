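#' Single-variant OLS association test on dosages
#'
#' Simple linear regression of a prepared phenotype on an allele dosage,
#' the workhorse of cis-eQTL scans in unrelated samples. Dosages enter the
#' regression as-is (not rounded to hard calls). Two-sided p-values come
#' from the t distribution with `n - 2` degrees of freedom.
#'
#' @param dosage Numeric dosage vector in `[0, 2]`.
#' @param y Phenotype: numeric vector or [prepare_phenotype()] result.
#' @param variant_id,trait_id Optional labels carried into the result.
#' @return One-row data frame (an association record): `variant`, `trait`,
#'   `beta` (per-allele effect in phenotype-SD units when `y` is
#'   inverse-normalized), `se`, `p`, `n`, `model`, `note`. A constant
#'   dosage yields an `"untestable"` record (NA statistics), not an error.
#' @export
test_variant_ols <- function(dosage, y, variant_id = "v", trait_id = "t") {
  yv <- pheno_values(y)
  ok <- !is.na(dosage) & !is.na(yv)
  n <- sum(ok)
  if (n < 10) stop("need at least 10 complete dosage/phenotype pairs")
  x <- dosage[ok]
  yy <- yv[ok]
  if (stats::var(x) == 0) {
    return(assoc_record(variant_id, trait_id, NA, NA, NA, n, "ols", note = "untestable"))
  }
  fit <- ols_core(x, yy)
  assoc_record(variant_id, trait_id, fit$beta, fit$se, fit$p, n, "ols")
}

assoc_record <- function(variant, trait, beta, se, p, n, model,
                         conditioning = "", note = "") {
  data.frame(variant = variant, trait = trait, beta = beta, se = se, p = p,
             n = n, model = model, conditioning = conditioning, note = note,
             stringsAsFactors = FALSE)
}

ols_core <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc^2)
  beta <- sum(xc * yc) / sxx
  rss <- sum(yc^2) - beta^2 * sxx
  se <- sqrt(max(rss, 0) / (n - 2) / sxx)
  tt <- beta / se
  list(beta = beta, se = se,
       p = 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE))
}

## Vectorized simple regression of y on every row of D (complete data).
## Optional prior rotation/weighting is handled by the callers.
scan_ols_matrix <- function(D, y) {
  n <- length(y)
  Dc <- D - rowMeans(D)
  yc <- y - mean(y)
  sxx <- rowSums(Dc^2)
  ok <- sxx > 0
  beta <- se <- p <- rep(NA_real_, nrow(D))
  sxy <- as.numeric(Dc %*% yc)
  beta[ok] <- sxy[ok] / sxx[ok]
  rss <- sum(yc^2) - beta[ok] * sxy[ok]
  se[ok] <- sqrt(pmax(rss, 0) / (n - 2) / sxx[ok])
  tt <- beta[ok] / se[ok]
  p[ok] <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  list(beta = beta, se = se, p = p, n = n, untestable = !ok)
}

#' Fit the null one-variance-component mixed model
#'
#' REML fit of `y ~ N(mu, sg2 * K + se2 * I)` by spectral decomposition of
#' the kinship matrix (the EMMA/EMMAX approach): eigendecompose `K` once,
#' rotate phenotype and intercept, and profile the restricted likelihood
#' over the variance ratio `lambda = sg2 / se2` on a log grid refined by
#' golden-section search. The fitted model carries the rotation and
#' per-eigenvalue weights, so each subsequent variant test is a single
#' weighted regression.
#'
#' @param y Phenotype (vector or [prepare_phenotype()] result), no missing
#'   values.
#' @param K Kinship matrix: symmetric positive semi-definite, unit
#'   diagonal convention (self 1, full sibs 0.5).
#' @param decomp Optional precomputed `eigen(K, symmetric = TRUE)`; pass it
#'   when refitting many phenotypes (e.g. permutations) on one kinship.
#' @return Object of class `null_mixed_model`: `sigma_g2`, `sigma_e2`,
#'   `h2` (= sg2/(sg2+se2)), `lambda`, rotation `U`, eigenvalues `d`,
#'   weights `w`, rotated phenotype/intercept, `boundary` flag when the
#'   genetic variance is pinned at zero.
#' @export
fit_null_mixed <- function(y, K, decomp = NULL) {
  yv <- pheno_values(y)
  if (anyNA(yv)) stop("missing phenotype values; subset before fitting")
  n <- length(yv)
  if (is.null(decomp)) {
    if (!isTRUE(all.equal(K, t(K), tolerance = 1e-8))) stop("kinship must be symmetric")
    if (nrow(K) != n) stop("kinship dimension does not match phenotype length")
    decomp <- eigen(K, symmetric = TRUE)
  }
  eg <- decomp
  if (min(eg$values) < -1e-6 * max(abs(eg$values))) {
    stop("kinship must be positive semi-definite")
  }
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- as.numeric(crossprod(U, yv))
  xt <- as.numeric(crossprod(U, rep(1, n)))

  reml_crit <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- 1 / (lam * d + 1)
    sxx <- sum(w * xt^2)
    b <- sum(w * xt * yt) / sxx
    r <- yt - b * xt
    rss <- sum(w * r^2)
    (n - 1) * log(rss) + sum(log(lam * d + 1)) + log(sxx)
  }
  grid <- seq(-8, 8, length.out = 33)
  vals <- vapply(grid, reml_crit, 0)
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(reml_crit, c(lo, hi))
  # accept the boundary if the criterion keeps decreasing toward lambda -> 0,
  # and call the variance ratio unidentifiable (0) when the criterion is flat
  # (e.g. an identity kinship, where the scale cancels)
  lambda <- exp(opt$minimum)
  if (i == 1 && vals[1] <= opt$objective) lambda <- 0
  if (diff(range(vals)) < 1e-8) lambda <- 0
  w <- 1 / (lambda * d + 1)
  sxx <- sum(w * xt^2)
  b <- sum(w * xt * yt) / sxx
  rss <- sum(w * (yt - b * xt)^2)
  sigma_e2 <- rss / (n - 1)
  sigma_g2 <- lambda * sigma_e2
  boundary <- lambda < 1e-6
  if (boundary) warning("genetic variance estimate at the zero boundary")
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 h2 = sigma_g2 / (sigma_g2 + sigma_e2), lambda = lambda,
                 U = U, d = d, w = w, yt = yt, xt = xt, n = n,
                 boundary = boundary),
            class = "null_mixed_model")
}

#' @method print null_mixed_model
#' @export
print.null_mixed_model <- function(x, ...) {
  cat(sprintf("null mixed model (n = %d): sigma_g2 = %.4f, sigma_e2 = %.4f, h2 = %.3f%s\n",
              x$n, x$sigma_g2, x$sigma_e2, x$h2,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Mixed-model single-variant test
#'
#' EMMAX-style score/Wald test: the dosage is rotated by the null model's
#' eigenvectors and regressed on the rotated phenotype under the
#' per-eigenvalue weights fixed at their null REML estimates. With an
#' identity kinship (or a zero genetic variance) this reduces exactly to
#' the OLS test.
#'
#' @param dosage Dosage vector on the same samples as the null model.
#' @param null A [fit_null_mixed()] result.
#' @param variant_id,trait_id Optional labels.
#' @return One-row association record (see [test_variant_ols()]), with
#'   `model = "mixed"`.
#' @export
test_variant_mixed <- function(dosage, null, variant_id = "v", trait_id = "t") {
  stopifnot(inherits(null, "null_mixed_model"))
  if (length(dosage) != null$n) stop("dosage length does not match null model")
  if (anyNA(dosage)) stop("missing dosages; subset before testing")
  if (stats::var(dosage) == 0) {
    return(assoc_record(variant_id, trait_id, NA, NA, NA, null$n, "mixed",
                        note = "untestable"))
  }
  gt <- as.numeric(crossprod(null$U, dosage))
  fit <- wls_two_col(null$xt, gt, null$yt, null$w)
  assoc_record(variant_id, trait_id, fit$beta, fit$se, fit$p, null$n, "mixed")
}

## weighted regression of y on (intercept-column x0, predictor x1);
## returns stats for x1. All inputs already rotated.
wls_two_col <- function(x0, x1, y, w) {
  n <- length(y)
  sw0 <- sum(w * x0^2)
  # project x1 and y off the rotated intercept under the weights
  x1p <- x1 - x0 * (sum(w * x0 * x1) / sw0)
  yp <- y - x0 * (sum(w * x0 * y) / sw0)
  sxx <- sum(w * x1p^2)
  beta <- sum(w * x1p * yp) / sxx
  rss <- sum(w * yp^2) - beta^2 * sxx
  se <- sqrt(max(rss, 0) / (n - 2) / sxx)
  tt <- beta / se
  list(beta = beta, se = se,
       p = 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE))
}

## vectorized mixed-model scan over the rows of D
scan_mixed_matrix <- function(D, null) {
  Gt <- D %*% null$U            # each row rotated
  w <- null$w
  x0 <- null$xt
  y <- null$yt
  n <- null$n
  sw0 <- sum(w * x0^2)
  wx0 <- w * x0
  yp <- y - x0 * (sum(wx0 * y) / sw0)
  proj <- as.numeric(Gt %*% wx0) / sw0
  X1p <- Gt - outer(proj, x0)
  sxx <- rowSums(sweep(X1p^2, 2, w, `*`))
  sxy <- as.numeric(sweep(X1p, 2, w, `*`) %*% yp)
  ok <- sxx > 1e-12
  beta <- se <- p <- rep(NA_real_, nrow(D))
  beta[ok] <- sxy[ok] / sxx[ok]
  rss <- sum(w * yp^2) - beta[ok] * sxy[ok]
  se[ok] <- sqrt(pmax(rss, 0) / (n - 2) / sxx[ok])
  tt <- beta[ok] / se[ok]
  p[ok] <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  list(beta = beta, se = se, p = p, n = n, untestable = !ok)
}

#' Cis window of an expression trait
#'
#' @param tss Transcription start position (1-based).
#' @param chrom Chromosome label.
#' @param flank Window half-width in bp (default 1 Mb).
#' @return List `chrom`, `start`, `end` (start clipped at 1).
#' @export
cis_window <- function(tss, chrom, flank = 1e6) {
  list(chrom = chrom, start = max(1, tss - flank), end = tss + flank)
}

#' Cis association scan for one expression trait
#'
#' Tests every variant of the dosage matrix lying within `tss` +/- `flank`
#' on the trait's chromosome, ranks results by p-value, and reports the
#' overall index variant and the best variant per MAF bin. Ties in p are
#' broken by larger absolute effect, then lower genomic position.
#'
#' @param y Prepared phenotype (vector or [prepare_phenotype()]).
#' @param dm A (filtered) [dosage_matrix()].
#' @param chrom,tss Trait annotation: chromosome and transcription start
#'   position.
#' @param trait_id Trait label.
#' @param flank Cis half-window (default 1 Mb).
#' @param model `"ols"` (default) or `"mixed"` (requires `null`).
#' @param null A [fit_null_mixed()] result when `model = "mixed"`.
#' @return Object of class `cis_scan`: list with `results` (data frame of
#'   all tests with variant metadata), `index` (row of the index variant or
#'   NULL), `index_by_bin` (named list with per-bin best rows) and
#'   `trait`.
#' @export
scan_cis <- function(y, dm, chrom, tss, trait_id = "trait", flank = 1e6,
                     model = c("ols", "mixed"), null = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(dm, "dosage_matrix"))
  win <- cis_window(tss, chrom, flank)
  sel <- which(dm$variants$chrom == win$chrom &
                 dm$variants$pos >= win$start & dm$variants$pos <= win$end)
  res <- scan_variants(y, dm, sel, trait_id, model, null)
  structure(list(results = res, trait = trait_id, window = win,
                 index = index_row(res),
                 index_by_bin = index_by_bin(res)),
            class = "cis_scan")
}

#' Genome-wide association scan for one trait
#'
#' As [scan_cis()] but without windowing; the default model is the mixed
#' model, appropriate for cohorts retaining related individuals.
#'
#' @inheritParams scan_cis
#' @return A `cis_scan`-shaped object with `window = NULL`.
#' @export
scan_genome <- function(y, dm, trait_id = "trait", model = c("mixed", "ols"),
                        null = NULL) {
  model <- match.arg(model)
  res <- scan_variants(y, dm, seq_len(nrow(dm$dosages)), trait_id, model, null)
  structure(list(results = res, trait = trait_id, window = NULL,
                 index = index_row(res),
                 index_by_bin = index_by_bin(res)),
            class = "cis_scan")
}

scan_variants <- function(y, dm, sel, trait_id, model, null) {
  yv <- pheno_values(y)
  meta_cols <- c("id", "chrom", "pos", "ref", "alt", "maf", "mac", "rsq")
  if (!length(sel)) {
    out <- dm$variants[integer(0), meta_cols]
    out$beta <- out$se <- out$p <- numeric(0)
    out$n <- integer(0); out$trait <- character(0); out$model <- character(0)
    return(out)
  }
  D <- dm$dosages[sel, , drop = FALSE]
  if (anyNA(D) || anyNA(yv)) {
    stop("missing values in dosages or phenotype; subset to complete data first")
  }
  fit <- if (model == "ols") {
    scan_ols_matrix(D, yv)
  } else {
    if (is.null(null)) stop("mixed model scan requires a fitted null model")
    scan_mixed_matrix(D, null)
  }
  out <- dm$variants[sel, meta_cols]
  out$beta <- fit$beta
  out$se <- fit$se
  out$p <- fit$p
  out$n <- fit$n
  out$trait <- trait_id
  out$model <- model
  out[order(out$p, -abs(out$beta), out$pos), ]
}

index_row <- function(res) {
  ok <- which(!is.na(res$p))
  if (!length(ok)) return(NULL)
  res[ok[1], ]   # results already ordered by (p, -|beta|, pos)
}

index_by_bin <- function(res) {
  ok <- res[!is.na(res$p) & res$maf > 0, ]
  if (!nrow(ok)) return(list(common = NULL, low_frequency = NULL))
  bins <- maf_bin(ok$maf)
  list(
    common = if (any(bins == "common")) ok[which(bins == "common")[1], ] else NULL,
    low_frequency = if (any(bins == "low_frequency")) {
      ok[which(bins == "low_frequency")[1], ]
    } else NULL
  )
}

#' @method print cis_scan
#' @export
print.cis_scan <- function(x, ...) {
  cat(sprintf("scan of trait '%s': %d variants tested\n", x$trait, nrow(x$results)))
  if (!is.null(x$index)) {
    cat(sprintf("  index: %s (MAF %.3f) beta = %.3f, p = %.3g\n",
                x$index$id, x$index$maf, x$index$beta, x$index$p))
  }
  invisible(x)
}

#' Write association results as TSV
#'
#' @param scan A [scan_cis()] / [scan_genome()] result or a results data
#'   frame.
#' @param path Output path.
#' @export
write_assoc_tsv <- function(scan, path) {
  res <- if (inherits(scan, "cis_scan")) scan$results else scan
  write_tsv_table(res, path)
}
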