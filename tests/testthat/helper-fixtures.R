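# Shared fixture builders and independent brute-force oracles.

# Printed power/effect grid the analytic model is checked against:
# rows are MAF x (variance explained) blocks, sample size 450, alpha 1e-6.
table3_grid <- function() {
  maf <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.1, 0.2)
  eff1 <- matrix(c(1.59, 1.74, 1.88, 1.13, 1.24, 1.34, 0.93, 1.02, 1.10,
                   0.81, 0.88, 0.95, 0.73, 0.79, 0.86, 0.53, 0.58, 0.62,
                   0.40, 0.43, 0.47), byrow = TRUE, ncol = 3)
  eff2 <- matrix(c(2.01, 2.13, 2.25, 1.43, 1.52, 1.60, 1.17, 1.24, 1.31,
                   1.02, 1.08, 1.14, 0.92, 0.97, 1.03, 0.67, 0.71, 0.75,
                   0.50, 0.53, 0.56), byrow = TRUE, ncol = 3)
  data.frame(
    maf = rep(rep(maf, each = 3), 2),
    V = c(rep(c(0.05, 0.06, 0.07), 7), rep(c(0.08, 0.09, 0.10), 7)),
    power = c(rep(c(0.47, 0.65, 0.79), 7), rep(c(0.89, 0.95, 0.98), 7)),
    effect = c(as.vector(t(eff1)), as.vector(t(eff2)))
  )
}

# small diploid cohort drawn straight from binomial genotypes (no LD)
binom_genotypes <- function(n_var, n_ind, maf, seed = 1) {
  set.seed(seed)
  maf <- rep_len(maf, n_var)
  g <- t(vapply(maf, function(p) stats::rbinom(n_ind, 2L, p), integer(n_ind)))
  rownames(g) <- paste0("v", seq_len(n_var))
  colnames(g) <- sprintf("S%04d", seq_len(n_ind))
  g
}

toy_variants <- function(pos, chrom = "1", ref = "A", alt = "G") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# Brute-force re-implementation of greedy LD binning, straight from the
# rule: repeatedly pick the unbinned variant with most unbinned companions
# at r2 > threshold (ties: lowest position), bin it with its companions.
# Written over the r2 matrix, independently of the package code path.
oracle_ldselect_bins <- function(R2, pos, threshold) {
  m <- nrow(R2)
  unbinned <- rep(TRUE, m)
  bins <- list()
  while (any(unbinned)) {
    best <- NA
    best_count <- -1
    for (i in which(unbinned)) {
      count <- 0
      for (j in which(unbinned)) {
        if (j != i && R2[i, j] > threshold) count <- count + 1
      }
      if (count > best_count ||
          (count == best_count && pos[i] < pos[best])) {
        best <- i; best_count <- count
      }
    }
    members <- best
    for (j in which(unbinned)) {
      if (j != best && R2[best, j] > threshold) members <- c(members, j)
    }
    bins[[length(bins) + 1]] <- sort(members)
    unbinned[members] <- FALSE
  }
  bins
}

# Brute-force greedy clumping: ascending p (ties: lowest position), each
# surviving index removes later variants at r2 >= r2_max.
oracle_clump <- function(p, pos, R2, p_max, r2_max) {
  cand <- which(!is.na(p) & p < p_max)
  cand <- cand[order(p[cand], pos[cand])]
  surv <- integer(0)
  removed <- rep(FALSE, length(p))
  for (i in cand) {
    if (removed[i]) next
    surv <- c(surv, i)
    for (j in cand) {
      if (j != i && !removed[j] && R2[i, j] >= r2_max) removed[j] <- TRUE
    }
  }
  surv
}

# toy genotype call sets for concordance checks
toy_call_sets <- function() {
  truth_var <- toy_variants(pos = seq(100, 1000, by = 100))         # 10 sites
  query_var <- rbind(truth_var[1:9, ], toy_variants(pos = 5000))    # 9 shared + 1 novel
  gt_truth <- matrix(rep(c(0L, 1L), each = 10), ncol = 2,
                     dimnames = list(NULL, c("A", "B")))
  gt_query <- matrix(rep(c(0L, 1L), each = 10), ncol = 2,
                     dimnames = list(NULL, c("A", "B")))
  list(truth = call_set(truth_var, gt_truth),
       query = call_set(query_var, gt_query))
}
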