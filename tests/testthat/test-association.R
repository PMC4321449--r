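test_that("OLS test recovers a perfect linear relationship", {
  set.seed(40)
  x <- rbinom(100, 2, 0.3)
  r <- test_variant_ols(x, x + 0)
  expect_equal(r$beta, 1)
  expect_lt(r$p, 1e-100)
  expect_equal(r$n, 100)
  # beta in SD units under a scaled phenotype
  r2 <- test_variant_ols(x, 2 * x)
  expect_equal(r2$beta, 2)
})

test_that("OLS preconditions and untestable dosages are handled", {
  set.seed(41)
  expect_error(test_variant_ols(rbinom(5, 2, 0.5), rnorm(5)), "10 complete")
  r <- test_variant_ols(rep(1, 50), rnorm(50))
  expect_equal(r$note, "untestable")
  expect_true(is.na(r$p))
})

test_that("OLS agrees with lm and holds its nominal type-I error", {
  set.seed(42)
  x <- runif(80, 0, 2)
  y <- rnorm(80)
  r <- test_variant_ols(x, y)
  ref <- summary(stats::lm(y ~ x))$coefficients["x", ]
  expect_equal(r$beta, unname(ref["Estimate"]))
  expect_equal(r$se, unname(ref["Std. Error"]))
  expect_equal(r$p, unname(ref["Pr(>|t|)"]))

  # permutation null: fraction p < 0.05 near nominal
  n <- 300
  x <- rbinom(n, 2, 0.2)
  perms <- matrix(rnorm(n * 2000), nrow = n)
  fit <- with(list(), {
    xc <- x - mean(x)
    yc <- sweep(perms, 2, colMeans(perms))
    r <- as.numeric(crossprod(yc, xc)) / sqrt(sum(xc^2) * colSums(yc^2))
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(abs(tt), n - 2, lower.tail = FALSE)
  })
  expect_lt(abs(mean(fit < 0.05) - 0.05), 0.015)
})

test_that("null p-values are uniform across a large scan", {
  set.seed(43)
  n <- 450
  D <- binom_genotypes(10000, n, maf = runif(10000, 0.02, 0.5), seed = 44)
  y <- rnorm(n)
  sc <- scan_genome(y, degrade_to_dosages(D, 1.0, seed = 45), model = "ols")
  p <- sc$results$p
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("mixed model with identity kinship reproduces OLS exactly", {
  set.seed(46)
  n <- 200
  y <- rnorm(n)
  x <- rbinom(n, 2, 0.3)
  nm <- suppressWarnings(fit_null_mixed(y, diag(n)))
  expect_true(nm$boundary)   # variance ratio unidentifiable under K = I
  rm_ <- test_variant_mixed(x, nm)
  ro <- test_variant_ols(x, y)
  expect_equal(rm_$p, ro$p, tolerance = 1e-6)
  expect_equal(rm_$beta, ro$beta, tolerance = 1e-6)
})

test_that("mixed model REML recovers simulated heritability with sib pairs", {
  # a sib-pair-only kinship is weakly informative about h2, so parameter
  # recovery is judged on the mean estimate over replicate cohorts
  set.seed(47)
  n <- 600
  K <- diag(n)
  for (i in seq(1, n - 1, by = 2)) K[i, i + 1] <- K[i + 1, i] <- 0.5
  h2 <- 0.4
  L <- chol(h2 * K + (1 - h2) * diag(n))
  eg <- eigen(K, symmetric = TRUE)
  est <- vapply(1:12, function(s) {
    set.seed(470 + s)
    y <- as.numeric(crossprod(L, rnorm(n)))
    suppressWarnings(fit_null_mixed(y, K, decomp = eg))$h2
  }, 0)
  expect_lt(abs(mean(est) - 0.4), 0.1)
  expect_error(fit_null_mixed(rnorm(10), matrix(-1, 10, 10)),
               "symmetric|semi-definite")
})

test_that("cis scan finds the planted causal variant and respects windows", {
  # a single causal variant among unlinked neighbours: the index should be
  # the causal variant itself in nearly every replicate at V = 0.10
  g <- binom_genotypes(60, 450, maf = runif(60, 0.05, 0.5), seed = 48)
  dm <- degrade_to_dosages(g, 1.0, seed = 50)
  dm$variants$pos <- seq(1e5, by = 2e4, length.out = 60)
  dm$variants$id <- sprintf("1:%d", dm$variants$pos)
  rownames(dm$dosages) <- dm$variants$id
  rownames(g) <- dm$variants$id
  causal <- dm$variants$id[30]
  tss <- dm$variants$pos[30]
  truth <- make_truth_table(
    data.frame(trait = "t", causal_id = causal, V = 0.10), g)

  hits <- 0
  n_reps <- 60
  for (rep in seq_len(n_reps)) {
    sim <- simulate_traits(g, truth, seed = 1000 + rep)
    y <- prepare_phenotype(sim$phenotypes$t)
    sc <- scan_cis(y, dm, chrom = "1", tss = tss, trait_id = "t")
    if (!is.null(sc$index) && sc$index$id == causal) hits <- hits + 1
  }
  expect_gte(hits, 52)   # ~95% recovery less binomial slack

  # windowing: all results inside the cis window; empty window is empty
  sim <- simulate_traits(g, truth, seed = 1)
  y <- prepare_phenotype(sim$phenotypes$t)
  sc <- scan_cis(y, dm, chrom = "1", tss = tss, flank = 1e5)
  expect_true(all(abs(sc$results$pos - tss) <= 1e5))
  sc0 <- scan_cis(y, dm, chrom = "99", tss = tss)
  expect_equal(nrow(sc0$results), 0)
  expect_null(sc0$index)

  # per-bin index variants live in their bins
  sc <- scan_cis(y, dm, chrom = "1", tss = tss)
  if (!is.null(sc$index_by_bin$common)) {
    expect_gte(sc$index_by_bin$common$maf, 0.05)
  }
  if (!is.null(sc$index_by_bin$low_frequency)) {
    expect_lt(sc$index_by_bin$low_frequency$maf, 0.05)
  }
})

test_that("scan results are independent across traits", {
  set.seed(51)
  g <- binom_genotypes(50, 200, maf = 0.3, seed = 52)
  dm <- degrade_to_dosages(g, 1.0, seed = 53)
  y1 <- rnorm(200); y2 <- rnorm(200)
  s1 <- scan_cis(y1, dm, chrom = "1", tss = 25, trait_id = "a", model = "ols")
  s12 <- scan_cis(y2, dm, chrom = "1", tss = 25, trait_id = "b", model = "ols")
  s1_again <- scan_cis(y1, dm, chrom = "1", tss = 25, trait_id = "a", model = "ols")
  expect_equal(s1$results, s1_again$results)
  expect_false(isTRUE(all.equal(s1$results$p, s12$results$p)))
})
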