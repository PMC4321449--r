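test_that("best opposing variant is the opposing-bin argmin with tie-breaks", {
  res <- data.frame(
    id = paste0("v", 1:4), chrom = "1", pos = c(100, 200, 300, 400),
    maf = c(0.3, 0.02, 0.03, 0.4), p = c(1e-8, 1e-3, 1e-8, 0.5)
  )
  # index is common: the best low-frequency variant wins
  best <- best_opposing_variant(res, "common")
  expect_equal(best$id, "v3")
  # tie in p: lower position
  res$p[2] <- 1e-8
  expect_equal(best_opposing_variant(res, "common")$id, "v2")
  # no opposing variants at all
  none <- best_opposing_variant(res[c(1, 4), ], "low_frequency")
  expect_equal(none$id, "v1")
  expect_null(best_opposing_variant(res[c(2, 3), ], "low_frequency"))
})

test_that("conditional test nests the unconditional one", {
  set.seed(80)
  n <- 450
  x <- rbinom(n, 2, 0.25)
  y <- 0.4 * x + rnorm(n)
  r0 <- test_variant_ols(x, y)
  r_empty <- conditional_test(y, x, NULL)
  expect_equal(r_empty$beta, r0$beta)
  expect_equal(r_empty$p, r0$p)
  expect_equal(r_empty$conditioning, "0")

  # conditioning on an exactly orthogonal covariate barely moves the p
  z <- rnorm(n)
  z <- z - x * sum(z * (x - mean(x))) / sum((x - mean(x))^2)  # r2 = 0 vs centered x
  z <- z - mean(z) + mean(x)
  rc <- conditional_test(y, x, matrix(z, nrow = 1))
  expect_lt(abs(log10(rc$p) - log10(r0$p)), 0.2)

  # matches lm partial coefficients
  w <- rbinom(n, 2, 0.4)
  rc2 <- conditional_test(y, x, matrix(w, nrow = 1))
  ref <- summary(stats::lm(y ~ w + x))$coefficients["x", ]
  expect_equal(rc2$beta, unname(ref["Estimate"]))
  expect_equal(rc2$p, unname(ref["Pr(>|t|)"]))
})

test_that("collinear indices are reported untestable, collinear conditioners dropped", {
  set.seed(81)
  n <- 200
  x <- rbinom(n, 2, 0.3)
  y <- rnorm(n)
  near_copy <- x + rnorm(n, sd = 1e-4)
  r <- conditional_test(y, x, matrix(near_copy, nrow = 1))
  expect_equal(r$note, "untestable_collinear")
  expect_true(is.na(r$p))

  z <- rbinom(n, 2, 0.4)
  C <- rbind(z, z)   # duplicated conditioner
  expect_warning(r2 <- conditional_test(y, x, C), "collinear")
  expect_equal(r2$conditioning, "1")
  expect_false(is.na(r2$p))
})

test_that("conditioning on the true causal kills its LD proxies", {
  set.seed(82)
  n <- 450
  hits <- 0
  n_reps <- 25
  for (rep in seq_len(n_reps)) {
    # haplotype construction with proxy r2 ~ 0.9 to the causal
    p_c <- 0.2
    hap_c <- matrix(rbinom(2 * n, 1, p_c), ncol = 2)
    flip <- matrix(rbinom(2 * n, 1, 0.025), ncol = 2)
    hap_p <- abs(hap_c - flip)
    g_causal <- rowSums(hap_c)
    g_proxy <- rowSums(hap_p)
    if (var(g_proxy) == 0) next
    y <- effect_from_variance(0.10, p_c) * g_causal + rnorm(n, sd = sqrt(0.90))
    rc <- conditional_test(y, g_proxy, matrix(g_causal, nrow = 1))
    if (!is.na(rc$p) && rc$p > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 20)   # >= ~90% less binomial slack
})

test_that("clumping matches the brute-force oracle and its degenerate cases", {
  set.seed(83)
  n <- 200
  x <- rbinom(n, 2, 0.3)
  D_same <- rbind(x, x, x)
  res_same <- data.frame(id = paste0("v", 1:3), pos = 1:3,
                         p = c(1e-8, 1e-6, 1e-5))
  cs <- clump(res_same, D_same)
  expect_equal(length(cs$index_rows), 1)
  expect_equal(cs$indices$id, "v1")

  D_ind <- binom_genotypes(2, n, maf = 0.3, seed = 84)
  res_ind <- data.frame(id = c("a", "b"), pos = 1:2, p = c(1e-8, 1e-6))
  expect_equal(length(clump(res_ind, D_ind)$index_rows), 2)

  # above p_max: excluded entirely
  res_ind$p <- c(1e-3, 0.5)
  expect_equal(length(clump(res_ind, D_ind)$index_rows), 0)

  for (case in 1:20) {
    m <- sample(3:15, 1)
    D <- matrix(rbinom(m * n, 2, runif(m, 0.1, 0.5)), nrow = m)
    for (i in seq_len(m)) {
      if (i > 1 && runif(1) < 0.4) {
        src <- sample(i - 1, 1)
        mix <- runif(n) < 0.3
        D[i, ] <- ifelse(mix, rbinom(n, 2, 0.3), D[src, ])
      }
    }
    keep <- apply(D, 1, var) > 0
    D <- D[keep, , drop = FALSE]
    if (nrow(D) < 2) next
    res <- data.frame(id = paste0("v", seq_len(nrow(D))),
                      pos = seq_len(nrow(D)),
                      p = 10^-runif(nrow(D), 0, 8))
    got <- clump(res, D, p_max = 1e-2, r2_max = 0.3)
    R2 <- suppressWarnings(cor(t(D)))^2
    want <- oracle_clump(res$p, res$pos, R2, p_max = 1e-2, r2_max = 0.3)
    expect_equal(got$index_rows, want)
    # survivors mutually below the r2 ceiling
    if (length(got$index_rows) > 1) {
      sub <- R2[got$index_rows, got$index_rows]
      expect_true(all(sub[upper.tri(sub)] < 0.3))
    }
  }
})

test_that("signal classification applies the threshold rules", {
  expect_equal(classify_signal(1e-8, 0.3, 1e-6), "fully_explained")
  expect_equal(classify_signal(1e-8, 1e-7, 1e-6), "retained")
  expect_equal(classify_signal(1e-8, 1e-3, 1e-6), "attenuated")
  expect_equal(classify_signal(1e-8, NA, 1e-6), "collinear")
  expect_error(classify_signal(NA, 0.5, 1e-6), "unconditional")
})

test_that("opposing-bin conditioning never conditions on the index itself", {
  set.seed(85)
  n <- 450
  g <- binom_genotypes(6, n, maf = c(0.3, 0.02, 0.03, 0.25, 0.4, 0.04), seed = 86)
  dm <- degrade_to_dosages(g, 1.0, seed = 87)
  y <- 0.5 * g[1, ] + rnorm(n)
  sc <- scan_cis(y, dm, chrom = "1", tss = 3, trait_id = "t", model = "ols")
  res <- sc$results[match(dm$variants$id, sc$results$id), ]
  idx_row <- which(res$id == sc$index$id)
  rec <- condition_on_opposing_bin(y, dm, res, idx_row,
                                   discovery_threshold = 1e-6, mode = "single")
  expect_false(rec$index_id %in% rec$conditioning_ids)
  expect_equal(length(rec$conditioning_ids), 1)
  expect_true(rec$classification %in%
                c("fully_explained", "retained", "attenuated", "no_opposing_variant"))
})

test_that("detection comparison across call sets has the right fixed points", {
  sig <- data.frame(trait = c("t1", "t2"), chrom = "1",
                    pos = c(1e6, 5e6), p = c(1e-9, 1e-7))
  resb <- data.frame(trait = rep(c("t1", "t2"), each = 2), chrom = "1",
                     pos = c(1e6, 1.1e6, 5e6, 5.05e6),
                     p = c(1e-9, 1e-3, 1e-7, 1e-8))
  # B = A: everything detected, nothing weaker
  cmp <- compare_detection(sig, resb, strict_threshold = 1e-6)
  expect_equal(cmp$frac_detected_strict, 1)
  expect_equal(cmp$frac_detected_loose, 1)
  expect_equal(cmp$frac_weaker_or_absent, 0)

  # B empty: nothing detected, everything absent
  cmp0 <- compare_detection(sig, resb[0, ], strict_threshold = 1e-6)
  expect_equal(cmp0$frac_detected_strict, 0)
  expect_equal(cmp0$frac_weaker_or_absent, 1)

  # proxy window: variants beyond 250 kb do not count
  far <- data.frame(trait = "t1", chrom = "1", pos = 2e6, p = 1e-12)
  cmp_far <- compare_detection(sig[1, ], far, strict_threshold = 1e-6)
  expect_equal(cmp_far$frac_detected_strict, 0)

  # missing trait counts as no proxy
  cmp_miss <- compare_detection(sig, resb[resb$trait == "t1", ],
                                strict_threshold = 1e-6)
  expect_equal(cmp_miss$per_signal$detected_strict, c(TRUE, FALSE))
})

test_that("degrading the causal sites lowers strict detection", {
  set.seed(88)
  n <- 450
  n_loci <- 12
  det <- matrix(NA, n_loci, 2)
  for (l in seq_len(n_loci)) {
    g <- binom_genotypes(8, n, maf = c(0.05, runif(7, 0.1, 0.4)),
                         seed = 880 + l)
    y <- effect_from_variance(0.12, mean(g[1, ]) / 2) * g[1, ] +
      rnorm(n, sd = sqrt(0.88))
    dmA <- degrade_to_dosages(g, 1.0, seed = 890 + l)
    dmB <- degrade_to_dosages(g, c(0.3, rep(1, 7)), seed = 890 + l)
    pA <- scan_cis(y, dmA, chrom = "1", tss = 4, trait_id = "t", model = "ols")$results
    pB <- scan_cis(y, dmB, chrom = "1", tss = 4, trait_id = "t", model = "ols")$results
    det[l, ] <- c(min(pA$p), min(pB$p))
  }
  strict <- 1e-6
  expect_gt(sum(det[, 1] < strict), sum(det[, 2] < strict))
})
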