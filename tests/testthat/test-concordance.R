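test_that("site overlap on toy sets gives hand-computed TP and FN", {
  cs <- toy_call_sets()
  # identical sets
  self <- site_overlap(cs$truth, cs$truth)
  expect_equal(self$tp_proportion, 1.0)
  expect_equal(self$fn_rate, 0.0)
  # 9 of 10 truth sites called, plus one novel call
  ov <- site_overlap(cs$query, cs$truth)
  expect_equal(ov$tp_proportion, 0.9)
  expect_equal(ov$fn_rate, 0.1)
})

test_that("mask, depth and biallelic filters apply in order to both sets", {
  cs <- toy_call_sets()
  # masking the novel query site makes the query perfect
  mask <- data.frame(chrom = "1", start = 4500, end = 5500)
  ov <- site_overlap(cs$query, cs$truth, mask = mask)
  expect_equal(ov$tp_proportion, 1.0)

  # a truth site with a genotype under 20x drops from both sets
  depth <- matrix(30, nrow = 10, ncol = 2)
  depth[3, 2] <- 10
  truth_d <- call_set(cs$truth$variants, cs$truth$genotypes, depth = depth,
                      samples = cs$truth$samples)
  ov2 <- site_overlap(cs$query, truth_d, min_truth_depth = 20)
  expect_equal(ov2$n_truth, 9)
  expect_equal(ov2$n_query, 9)     # shared site removed from query too
  expect_equal(ov2$fn_rate, 1 / 9)

  # non-biallelic sites leave their own set
  qv <- cs$query$variants
  qv$alt[1] <- "G,T"
  q_multi <- call_set(qv, cs$query$genotypes)
  ov3 <- site_overlap(q_multi, cs$truth)
  expect_equal(ov3$n_query, 9)

  empty_truth <- call_set(cs$truth$variants, cs$truth$genotypes)
  big_mask <- data.frame(chrom = "1", start = 0, end = 1e7)
  expect_error(site_overlap(cs$query, empty_truth, mask = big_mask), "empty")
})

test_that("genotype concordance counts a hand-checked toy matrix", {
  v <- toy_variants(pos = 1:5 * 10)
  truth_gt <- matrix(c(0, 1, 2, 1, 0,
                       0, 1, 1, 2, 2), ncol = 2,
                     dimnames = list(NULL, c("A", "B")))
  query_gt <- truth_gt
  query_gt[2, 1] <- 0      # one het called hom-ref
  truth <- call_set(v, truth_gt)
  query <- call_set(v, query_gt)
  rep <- genotype_concordance(query, truth)
  expect_equal(rep$overall, 9 / 10)
  expect_equal(rep$matrix["het", "hom_ref"], 1)
  expect_equal(sum(rep$matrix), 10)
  # row sums are per-truth-class totals
  expect_equal(as.vector(rowSums(rep$matrix)),
               as.vector(table(factor(truth_gt, levels = 0:2))))
  # non-reference concordance excludes the truth/query hom-ref cell
  expect_equal(rep$nonref, (9 - 3) / (10 - 3))
  # per-sample vector
  expect_equal(unname(rep$per_sample), c(4 / 5, 1))

  # identical sets: perfect
  perfect <- genotype_concordance(truth, truth)
  expect_equal(perfect$overall, 1.0)
  expect_equal(sum(perfect$matrix) - sum(diag(perfect$matrix)), 0)
})

test_that("swapping query and truth transposes the concordance matrix", {
  set.seed(90)
  v <- toy_variants(pos = 1:50 * 100)
  gt1 <- matrix(rbinom(150, 2, 0.3), ncol = 3, dimnames = list(NULL, c("A", "B", "C")))
  gt2 <- matrix(rbinom(150, 2, 0.3), ncol = 3, dimnames = list(NULL, c("A", "B", "C")))
  a <- call_set(v, gt1); b <- call_set(v, gt2)
  expect_equal(genotype_concordance(a, b)$matrix,
               t(genotype_concordance(b, a)$matrix), ignore_attr = TRUE)
})

test_that("all-hom-ref truth leaves non-reference concordance undefined", {
  v <- toy_variants(pos = 1:4 * 10)
  gt <- matrix(0L, nrow = 4, ncol = 2, dimnames = list(NULL, c("A", "B")))
  expect_warning(rep <- genotype_concordance(call_set(v, gt), call_set(v, gt)),
                 "non-reference")
  expect_true(is.na(rep$nonref))
  expect_equal(rep$overall, 1)
})

test_that("a known per-genotype error rate shows up as 1 - concordance", {
  set.seed(91)
  v <- toy_variants(pos = seq_len(2000))
  gt <- matrix(rbinom(2000 * 5, 2, 0.3), ncol = 5,
               dimnames = list(NULL, paste0("S", 1:5)))
  e <- 0.03
  noisy <- gt
  flip <- matrix(runif(length(gt)) < e, nrow = nrow(gt))
  noisy[flip] <- (gt[flip] + sample(1:2, sum(flip), TRUE)) %% 3
  rep <- genotype_concordance(call_set(v, noisy), call_set(v, gt))
  expect_equal(rep$overall, 1 - e, tolerance = 0.005)
})

test_that("Ti/Tv follows its definition and the simulator draw", {
  v <- data.frame(ref = c("A", "C", "A"), alt = c("G", "T", "C"))
  expect_equal(titv_ratio(v), 2)
  expect_error(titv_ratio(data.frame(ref = "A", alt = "G")), "undefined")
  expect_error(titv_ratio(data.frame(ref = "A", alt = "GT")), "SNPs only")

  set.seed(92)
  n <- 1e5
  is_ti <- runif(n) < 2.19 / 3.19
  ref <- ifelse(is_ti, "A", "A")
  alt <- ifelse(is_ti, "G", sample(c("C", "T"), n, TRUE))
  expect_equal(titv_ratio(data.frame(ref = ref, alt = alt)), 2.19,
               tolerance = 0.05 / 2.19)
})

test_that("sample-swap rule keeps high concordance and flags the swap band", {
  conc <- c(good = 0.99, boundary = 0.98, swap = 0.52, low = 0.75)
  flags <- detect_sample_swaps(conc)
  expect_true(flags$keep[flags$sample == "good"])
  expect_false(flags$keep[flags$sample == "boundary"])   # strict > 0.98
  expect_false(flags$keep[flags$sample == "swap"])
  expect_true(flags$swap_like[flags$sample == "swap"])
  expect_false(flags$swap_like[flags$sample == "low"])
  expect_error(detect_sample_swaps(c(a = 1.2)), "0, 1")
})
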