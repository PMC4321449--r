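#' Rank-based inverse-normal transformation
#'
#' Maps values to normal quantiles of their ranks:
#' `qnorm((rank - c) / (n - 2c + 1))` with offset `c` (Blom's 3/8 by
#' default). Ties receive average ranks, so the transform is deterministic
#' and order-independent. Missing values stay missing and do not enter the
#' rank denominator.
#'
#' @param x Numeric vector with at least 3 non-missing values.
#' @param offset Quantile offset `c`; `3/8` (Blom, default), `0.5`
#'   (Hazen/Tukey-like) or `0` are common choices.
#' @param ties How tied values are ranked; passed to [rank()]'s
#'   `ties.method` (default `"average"`).
#' @return Numeric vector of the same length, approximately standard normal.
#' @examples
#' z <- inverse_normal(rexp(100))
#' round(c(mean(z), sd(z)), 2)
#' @export
inverse_normal <- function(x, offset = 3 / 8, ties = "average") {
  if (!is.numeric(x)) stop("x must be numeric")
  obs <- !is.na(x)
  n <- sum(obs)
  if (n < 3) stop("need at least 3 non-missing values")
  v <- x[obs]
  if (max(v) == min(v)) stop("all non-missing values are equal; ranks are degenerate")
  r <- rank(v, ties.method = ties)
  out <- rep(NA_real_, length(x))
  out[obs] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Double inverse-normalization with covariate residualization
#'
#' The standard quantitative-trait preparation for dosage-based association
#' scans: inverse-normalize the raw values, regress out covariates by least
#' squares, then inverse-normalize the residuals. The first transform tames
#' outliers before the linear adjustment; the second restores exact
#' normality of what the association tests consume. The final values are a
#' monotone function of the residual ranks, so the second transform never
#' reorders residuals.
#'
#' @param x Numeric vector of raw trait values.
#' @param covariates Optional data frame or matrix of covariates (rows
#'   matching `x`). Factors are expanded via [stats::model.matrix()].
#' @param offset,ties Passed to [inverse_normal()].
#' @return Object of class `prepared_phenotype`: list with `values` (the
#'   transformed vector), `covariates` (names regressed out), `offset`,
#'   `ties`, `n_complete`.
#' @export
prepare_phenotype <- function(x, covariates = NULL, offset = 3 / 8, ties = "average") {
  z <- inverse_normal(x, offset = offset, ties = ties)
  cov_names <- character(0)
  if (!is.null(covariates) && length(covariates) > 0) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(x)) stop("covariates must have one row per observation")
    cov_names <- names(covariates)
    mm <- stats::model.matrix(~., data = covariates)
    qrm <- qr(mm)
    if (qrm$rank < ncol(mm)) {
      drop_cols <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
      stop("rank-deficient covariates: ", paste(drop_cols, collapse = ", "))
    }
    keep <- !is.na(z) & stats::complete.cases(covariates)
    resid <- rep(NA_real_, length(z))
    fit <- stats::lm.fit(mm[keep, , drop = FALSE], z[keep])
    resid[keep] <- fit$residuals
    z <- inverse_normal(resid, offset = offset, ties = ties)
  }
  structure(
    list(values = z, covariates = cov_names, offset = offset, ties = ties,
         n_complete = sum(!is.na(z))),
    class = "prepared_phenotype"
  )
}

#' @method print prepared_phenotype
#' @export
print.prepared_phenotype <- function(x, ...) {
  cat("Prepared phenotype:", x$n_complete, "complete observations\n")
  if (length(x$covariates)) {
    cat("  covariates regressed out:", paste(x$covariates, collapse = ", "), "\n")
  } else {
    cat("  no covariates\n")
  }
  invisible(x)
}

## Numeric vector view used by the association engine.
pheno_values <- function(y) {
  if (inherits(y, "prepared_phenotype")) y$values else as.numeric(y)
}
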