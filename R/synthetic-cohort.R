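#' Allele-frequency spectrum specification
#'
#' Mixture spectrum for the simulated site-frequency distribution: with
#' probability `p_low` a variant's target frequency is drawn from a
#' Beta(`low_shape1`, `low_shape2`) concentrated near zero and truncated to
#' `[min_maf, 0.05)` (the low-frequency component); otherwise it is drawn
#' uniformly on `[0.05, 0.5]` (the common component). The default
#' `p_low = 0.5` emits roughly equal numbers of low-frequency and common
#' variants, mirroring deep call sets where the two classes are of
#' comparable size.
#'
#' @param p_low Probability a variant is drawn from the low-frequency
#'   component.
#' @param low_shape1,low_shape2 Beta shape parameters of the low-frequency
#'   component.
#' @param min_maf Lower truncation of the low-frequency component.
#' @return List of class `afs_spec`.
#' @export
afs_spec <- function(p_low = 0.5, low_shape1 = 1, low_shape2 = 30, min_maf = 0.004) {
  stopifnot(p_low >= 0, p_low <= 1, min_maf > 0, min_maf < 0.05)
  structure(list(p_low = p_low, low_shape1 = low_shape1, low_shape2 = low_shape2,
                 min_maf = min_maf), class = "afs_spec")
}

## draw n target frequencies from an afs_spec (inverse-CDF truncation)
draw_afs <- function(n, afs) {
  low <- stats::runif(n) < afs$p_low
  f <- numeric(n)
  if (any(low)) {
    lo <- stats::pbeta(afs$min_maf, afs$low_shape1, afs$low_shape2)
    hi <- stats::pbeta(0.05, afs$low_shape1, afs$low_shape2)
    u <- stats::runif(sum(low), lo, hi)
    f[low] <- stats::qbeta(u, afs$low_shape1, afs$low_shape2)
  }
  f[!low] <- stats::runif(sum(!low), 0.05, 0.5)
  f
}

#' Simulate a haplotype pool with block-structured LD
#'
#' Builds a pool of phased haplotypes whose variants sit on LD blocks.
#' Within each block every haplotype is assigned one of `n_founders`
#' founder lineages; variant alleles are laid out on founders (with
#' binomial thinning of one partially-carrying founder so any target
#' frequency is reachable), so variants within a block share carriers and
#' are correlated, while founder assignments are redrawn independently
#' across block boundaries, making across-block r-squared near zero.
#'
#' @param n_hap Number of haplotypes (>= 4).
#' @param n_variants Number of variants (>= 1).
#' @param afs An [afs_spec()] giving the target frequency spectrum.
#' @param block_len LD block length in bp (default 50 kb).
#' @param chrom Chromosome label.
#' @param spacing Mean spacing between adjacent variants in bp.
#' @param n_founders Founder lineages per block; fewer founders means
#'   stronger within-block LD.
#' @param reshuffle_prob Per-variant probability of laying alleles on an
#'   independent founder order instead of the block's shared order; raises
#'   allelic heterogeneity within blocks.
#' @param prop_indel Fraction of variants emitted as (label-only) indels.
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   pools.
#' @return Object of class `haplotype_pool`: list with `alleles`
#'   (haplotypes x variants 0/1 matrix), `variants` (metadata data frame
#'   with `block` index), `block_len`, `n_founders`.
#' @export
simulate_haplotype_pool <- function(n_hap, n_variants, afs = afs_spec(),
                                    block_len = 50000, chrom = "1",
                                    spacing = 400, n_founders = 8,
                                    reshuffle_prob = 0.3, prop_indel = 0.1,
                                    seed = 1) {
  if (n_hap < 4) stop("n_hap must be >= 4")
  if (n_variants < 1) stop("n_variants must be >= 1")
  set.seed(seed)
  pos <- cumsum(sample(seq_len(2 * spacing - 1), n_variants, replace = TRUE))
  block <- (pos - 1) %/% block_len + 1L
  n_blocks <- max(block)
  f_target <- draw_afs(n_variants, afs)

  alleles <- matrix(0L, nrow = n_hap, ncol = n_variants)
  for (b in seq_len(n_blocks)) {
    idx <- which(block == b)
    if (!length(idx)) next
    founder_of <- sample.int(n_founders, n_hap, replace = TRUE)
    block_order <- sample.int(n_founders)
    hap_by_founder <- split(seq_len(n_hap), founder_of)
    for (j in idx) {
      ord <- if (stats::runif(1) < reshuffle_prob) sample.int(n_founders) else block_order
      remaining <- f_target[j]
      carriers <- integer(0)
      for (k in ord) {
        haps <- hap_by_founder[[as.character(k)]]
        if (is.null(haps)) next
        share <- length(haps) / n_hap
        if (remaining <= 0) break
        if (remaining >= share) {
          carriers <- c(carriers, haps)
          remaining <- remaining - share
        } else {
          take <- haps[stats::runif(length(haps)) < remaining / share]
          carriers <- c(carriers, take)
          remaining <- 0
        }
      }
      alleles[carriers, j] <- 1L
    }
  }
  # keep every site polymorphic in the pool
  ac <- colSums(alleles)
  for (j in which(ac == 0L)) alleles[sample.int(n_hap, 1), j] <- 1L
  for (j in which(ac == n_hap)) alleles[sample.int(n_hap, 1), j] <- 0L

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_variants, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  is_indel <- stats::runif(n_variants) < prop_indel
  alt[is_indel] <- paste0(alt[is_indel], sample(bases, sum(is_indel), replace = TRUE))
  variants <- data.frame(
    chrom = chrom, pos = pos,
    id = sprintf("%s:%d", chrom, pos),
    ref = ref, alt = alt,
    kind = ifelse(is_indel, "indel", "SNP"),
    block = block,
    target_freq = f_target,
    freq = colSums(alleles) / n_hap,
    stringsAsFactors = FALSE
  )
  structure(list(alleles = alleles, variants = variants, block_len = block_len,
                 n_founders = n_founders),
            class = "haplotype_pool")
}

#' @method print haplotype_pool
#' @export
print.haplotype_pool <- function(x, ...) {
  maf <- pmin(x$variants$freq, 1 - x$variants$freq)
  cat(sprintf("haplotype_pool: %d haplotypes x %d variants, %d blocks\n",
              nrow(x$alleles), ncol(x$alleles), max(x$variants$block)))
  cat(sprintf("  fraction MAF < 5%%: %.3f\n", mean(maf < 0.05)))
  invisible(x)
}

#' Sample a diploid cohort from a haplotype pool
#'
#' Draws haplotype pairs without replacement to form diploid genotypes.
#' A sibship specification turns the first `n_sib_pairs` pairs of
#' individuals into full sibs: each pair shares four parental haplotypes,
#' every sib drawing one haplotype from each parent at random. The returned
#' kinship matrix is the pedigree expectation on the
#' coefficient-of-relationship scale (self 1, full sibs 0.5, otherwise 0),
#' which is the scale a one-variance-component mixed model consumes.
#'
#' @param pool A [simulate_haplotype_pool()] result.
#' @param n_ind Number of individuals (2 * n_ind haplotypes are consumed).
#' @param relatedness Optional list, e.g. `list(n_sib_pairs = 10)`.
#' @param seed Integer seed.
#' @return List with `genotypes` (variants x individuals 0/1/2 matrix),
#'   `kinship` (individuals x individuals), `variants` (pool metadata) and
#'   `samples`.
#' @export
sample_cohort <- function(pool, n_ind, relatedness = NULL, seed = 1) {
  stopifnot(inherits(pool, "haplotype_pool"))
  n_hap <- nrow(pool$alleles)
  if (2 * n_ind > n_hap) {
    stop("pool too small: need ", 2 * n_ind, " haplotypes, have ", n_hap)
  }
  set.seed(seed)
  samples <- if (n_ind > 0) sprintf("S%04d", seq_len(n_ind)) else character(0)
  n_var <- ncol(pool$alleles)
  G <- matrix(0L, nrow = n_var, ncol = n_ind,
              dimnames = list(pool$variants$id, samples))
  K <- diag(nrow = n_ind)
  dimnames(K) <- list(samples, samples)
  if (n_ind == 0) {
    return(list(genotypes = G, kinship = K, variants = pool$variants, samples = samples))
  }
  n_sib_pairs <- 0L
  if (!is.null(relatedness)) {
    n_sib_pairs <- as.integer(relatedness$n_sib_pairs %||% 0L)
    if (2 * n_sib_pairs > n_ind) stop("more sib-pair members than individuals")
  }
  draw <- sample.int(n_hap, 2 * n_ind)
  used <- 0L
  i <- 1L
  sp <- 0L
  while (sp < n_sib_pairs) {
    par_haps <- draw[used + 1:4]
    used <- used + 4L
    for (s in 0:1) {
      h1 <- par_haps[1:2][sample.int(2, 1)]
      h2 <- par_haps[3:4][sample.int(2, 1)]
      G[, i + s] <- pool$alleles[h1, ] + pool$alleles[h2, ]
    }
    K[i, i + 1L] <- K[i + 1L, i] <- 0.5
    i <- i + 2L
    sp <- sp + 1L
  }
  while (i <= n_ind) {
    h <- draw[used + 1:2]
    used <- used + 2L
    G[, i] <- pool$alleles[h[1], ] + pool$alleles[h[2], ]
    i <- i + 1L
  }
  list(genotypes = G, kinship = K, variants = pool$variants, samples = samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Degrade hard genotypes to imputation-style dosages
#'
#' Emulates the information loss of genotype imputation: for target quality
#' `q` the dosage is the genotype shrunk toward its Hardy-Weinberg mean
#' `2p` by factor `q`, plus Gaussian noise of variance `q(1-q)` times the
#' genotype variance, clipped to `[0, 2]`. Clipping removes variance, so
#' the pre-clip deviations are rescaled by a short fixed-point iteration
#' until the realized variance-ratio quality (the same estimator as
#' [estimate_imputation_quality()]) matches the target. With `q = 1`
#' dosages equal genotypes exactly.
#'
#' @param genotypes Integer matrix (variants x samples) with entries 0/1/2.
#' @param quality Target imputation r-squared in `(0, 1]`; scalar or one
#'   value per variant.
#' @param variants Optional variant metadata data frame (chrom, pos, ref,
#'   alt, ...); autogenerated if absent.
#' @param seed Integer seed.
#' @return A [dosage_matrix()] whose `rsq` metadata records the target
#'   quality, as an imputation tool would report it.
#' @export
degrade_to_dosages <- function(genotypes, quality, variants = NULL, seed = 1) {
  genotypes <- as.matrix(genotypes)
  if (!all(genotypes %in% c(0L, 1L, 2L))) stop("genotypes must be 0/1/2")
  n_var <- nrow(genotypes)
  quality <- rep_len(quality, n_var)
  if (any(quality <= 0 | quality > 1)) stop("quality must be in (0, 1]")
  set.seed(seed)
  n <- ncol(genotypes)
  d <- matrix(NA_real_, nrow = n_var, ncol = n)
  for (i in seq_len(n_var)) {
    g <- genotypes[i, ]
    q <- quality[i]
    if (q == 1) { d[i, ] <- g; next }
    mu <- mean(g)
    vg <- mean((g - mu)^2)
    dev <- q * (g - mu) + stats::rnorm(n, sd = sqrt(max(q * (1 - q) * vg, 0)))
    # clipping to [0, 2] shrinks variance and biases the mean upward at
    # rare sites; iterate a scale on the deviations and an offset on the
    # mean until the realized variance ratio hits the target
    a <- 1
    b <- 0
    di <- pmin(pmax(mu + dev, 0), 2)
    for (it in 1:12) {
      ph <- mean(di) / 2
      denom <- 2 * ph * (1 - ph)
      if (denom <= 0) break
      ratio <- mean((di - mean(di))^2) / denom
      if (ratio <= 0) break
      if (abs(ratio - q) < 0.002 && abs(mean(di) - mu) < 0.002) break
      a <- a * sqrt(q / ratio)
      b <- b + (mu - mean(di))
      di <- pmin(pmax(mu + b + a * dev, 0), 2)
    }
    d[i, ] <- di
  }
  if (is.null(variants)) {
    variants <- data.frame(
      chrom = "1", pos = seq_len(n_var),
      ref = "A", alt = "C", stringsAsFactors = FALSE
    )
    if (!is.null(rownames(genotypes))) variants$id <- rownames(genotypes)
  }
  variants$rsq <- quality
  dosage_matrix(d, variants,
                samples = colnames(genotypes) %||% sprintf("S%04d", seq_len(n)))
}

#' Truth table for simulated traits
#'
#' One row per trait: the causal variant, the variance explained `V`, and
#' the implied per-allele effect in phenotype-SD units,
#' `beta = sqrt(V / (2p(1-p)))` at the causal variant's cohort frequency.
#'
#' @param traits Data frame with columns `trait`, `causal_id` (matching
#'   genotype rownames) and `V` (each in `[0, 1)`).
#' @param genotypes Variants x samples genotype matrix (for cohort allele
#'   frequencies).
#' @return The input with added columns `p` (causal frequency) and
#'   `beta_sd`.
#' @export
make_truth_table <- function(traits, genotypes) {
  stopifnot(all(c("trait", "causal_id", "V") %in% names(traits)))
  if (any(traits$V < 0 | traits$V >= 1)) stop("V must be in [0, 1)")
  idx <- match(traits$causal_id, rownames(genotypes))
  if (anyNA(idx)) stop("causal variant(s) not in genotype matrix: ",
                       paste(traits$causal_id[is.na(idx)], collapse = ", "))
  p <- rowMeans(genotypes)[idx] / 2
  traits$p <- p
  traits$beta_sd <- ifelse(traits$V > 0, effect_from_variance(traits$V, p), 0)
  traits
}

#' Simulate quantitative traits with known causal architecture
#'
#' Each trait is `beta * g_causal + covariate effects + noise`, with `beta`
#' set from the truth table so the causal variant explains `V` of the trait
#' variance, covariate effects adding `sum(gamma^2)` (covariates are
#' standardized internally) and residual noise absorbing the rest; total
#' variance is 1 in expectation. Traits with `V = 0` are pure nulls.
#'
#' @param genotypes Variants x samples genotype matrix.
#' @param truth A [make_truth_table()] result.
#' @param covariates Optional data frame of numeric covariates (samples in
#'   rows).
#' @param covariate_effects Named numeric vector `gamma` of SD-unit effects
#'   per covariate column (recycled across traits).
#' @param seed Integer seed.
#' @return List with `phenotypes` (data frame: `sample_id`, one column per
#'   trait, covariate columns appended) and `truth` (the truth table).
#' @export
simulate_traits <- function(genotypes, truth, covariates = NULL,
                            covariate_effects = NULL, seed = 1) {
  set.seed(seed)
  n <- ncol(genotypes)
  gamma <- numeric(0)
  Cstd <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    if (is.null(covariate_effects)) covariate_effects <- numeric(0)
    gamma <- covariate_effects
    if (length(gamma) && is.null(names(gamma))) {
      stop("covariate_effects must be named after covariate columns")
    }
    Cstd <- scale(as.matrix(covariates[names(gamma)]))
  }
  v_cov <- sum(gamma^2)
  phen <- matrix(NA_real_, nrow = n, ncol = nrow(truth))
  colnames(phen) <- truth$trait
  for (k in seq_len(nrow(truth))) {
    V <- truth$V[k]
    if (V + v_cov >= 1) stop("total explained variance must be < 1 for trait ", truth$trait[k])
    g <- genotypes[truth$causal_id[k], ]
    y <- truth$beta_sd[k] * (g - mean(g))
    if (length(gamma)) y <- y + as.numeric(Cstd %*% gamma)
    y <- y + stats::rnorm(n, sd = sqrt(1 - V - v_cov))
    phen[, k] <- y
  }
  out <- data.frame(sample_id = colnames(genotypes) %||% sprintf("S%04d", seq_len(n)),
                    phen, check.names = FALSE)
  if (!is.null(covariates)) out <- cbind(out, covariates)
  list(phenotypes = out, truth = truth)
}

#' Write a phenotype/covariate table or truth table as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited phenotype/covariate table
#'
#' @param path Path to a TSV with a header row.
#' @return Data frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
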