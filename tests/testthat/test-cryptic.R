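mk_table <- function(m, samples = paste0("h", seq_len(nrow(m))),
                     taxa = paste0("o", seq_len(ncol(m)))) {
  abundance_table(m, samples, taxa, mode = "count")
}

test_that("spearman_cooccurrence matches hand-ranked values and flags flat taxa", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(1, 2, 3, 4),
             d = c(1, 2, 2, 4), e = c(2, 1, 3, 4), f = c(5, 5, 5, 5))
  rho <- spearman_cooccurrence(mk_table(m, taxa = colnames(m)))
  expect_equal(rho["a", "c"], 1)
  expect_equal(rho["a", "b"], -1)
  # midrank oracle: Pearson correlation of average ranks
  r1 <- rank(m[, "d"]); r2 <- rank(m[, "e"])
  expect_equal(rho["d", "e"], cor(r1, r2), tolerance = 1e-12)
  expect_equal(attr(rho, "zero_variance"), "f")
  expect_true(all(is.na(rho["f", c("a", "b")])))
  expect_error(spearman_cooccurrence(mk_table(m[1:2, ])),
               "at least 3 samples")
})

test_that("fit_distance_cooccurrence recovers an exact linear relation", {
  g <- dm_from_lower(c(0.01, 0.03, 0.06, 0.02, 0.05, 0.04),
                     paste0("o", 1:4))
  cm <- 1 - 7 * unclass(g)
  diag(cm) <- 1
  cc <- structure(cm, class = c("cooccurrence_matrix", "matrix", "array"))
  fit <- fit_distance_cooccurrence(g, cc, n_permutations = 99, seed = 1)
  expect_equal(fit$slope, -7, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r, -1, tolerance = 1e-9)
  expect_equal(fit$n_pairs, 6L)
})

test_that("fit_distance_cooccurrence exhaustive p equals full enumeration", {
  set.seed(13)
  n <- 5L
  g <- dm_from_lower(runif(10, 0.01, 0.2), paste0("o", 1:n))
  cm <- matrix(0, n, n, dimnames = dimnames(g))
  cm[lower.tri(cm)] <- runif(10, -1, 1)
  cm <- cm + t(cm); diag(cm) <- 1
  cc <- structure(cm, class = c("cooccurrence_matrix", "matrix", "array"))
  fit <- fit_distance_cooccurrence(g, cc)
  lt <- lower.tri(unclass(g))
  r_obs <- cor(unclass(g)[lt], cm[lt])
  rstar <- sapply(perms_of(n), function(p) {
    cp <- cm[p, p]
    cor(unclass(g)[lt], cp[lt])
  })
  expect_equal(fit$p_permutation, mean(abs(rstar) >= abs(r_obs) - 1e-12))
})

test_that("fit_distance_cooccurrence p is uniform when structure is absent", {
  set.seed(29)
  n <- 10L
  g <- dm_from_lower(runif(n * (n - 1) / 2, 0.01, 0.2), paste0("o", 1:n))
  pvals <- replicate(200, {
    cm <- matrix(0, n, n, dimnames = dimnames(g))
    cm[lower.tri(cm)] <- runif(n * (n - 1) / 2, -1, 1)
    cm <- cm + t(cm); diag(cm) <- 1
    cc <- structure(cm, class = c("cooccurrence_matrix", "matrix", "array"))
    fit_distance_cooccurrence(g, cc, n_permutations = 99,
                              seed = sample.int(1e6, 1),
                              exhaustive = FALSE)$p_permutation
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("estimate_threshold picks the maximal-separation midpoint", {
  # 4 labels give 6 pairs: two close/high-correlation pairs, four
  # distant/negative ones; the only candidate inside the distance gap is
  # (0.02 + 0.10) / 2 and it must win the t-statistic scan
  g <- dm_from_lower(c(0.01, 0.02, 0.10, 0.12, 0.11, 0.13),
                     paste0("o", 1:4))
  # correlations matched so small distances pair with high correlation
  cm <- matrix(0, 4, 4, dimnames = dimnames(g))
  cm[lower.tri(cm)] <- c(0.9, 0.8, -0.3, -0.4, -0.35, -0.45)
  cm <- cm + t(cm); diag(cm) <- 1
  cc <- structure(cm, class = c("cooccurrence_matrix", "matrix", "array"))
  est <- estimate_threshold(g, cc)
  expect_equal(est$threshold, (0.02 + 0.10) / 2)
  expect_equal(est$n_below, 2L)
  # location invariance: adding a constant to all correlations
  cm2 <- cm + 0.05; diag(cm2) <- 1
  cc2 <- structure(cm2, class = c("cooccurrence_matrix", "matrix", "array"))
  expect_equal(estimate_threshold(g, cc2)$threshold, est$threshold)
  # no structure: near-zero separation statistic
  set.seed(3)
  cm3 <- matrix(0, 4, 4, dimnames = dimnames(g))
  cm3[lower.tri(cm3)] <- sample(c(0.9, -0.4, 0.85, -0.35, 0.8, -0.45))
  cm3 <- cm3 + t(cm3); diag(cm3) <- 1
  cc3 <- structure(cm3, class = c("cooccurrence_matrix", "matrix", "array"))
  est3 <- estimate_threshold(g, cc3)
  expect_lt(abs(est3$t_statistic), abs(est$t_statistic) / 3)
  expect_error(estimate_threshold(dm_from_lower(rep(0.1, 6), paste0("o", 1:4)),
                                  cc),
               "distinct distances")
})

test_that("estimate_threshold brute-force candidate scan on the 4-pair example", {
  # independent oracle: evaluate the pooled t at every midpoint directly
  dists <- c(0.01, 0.02, 0.10, 0.12)
  corrs <- c(0.9, 0.8, -0.3, -0.4)
  u <- sort(unique(dists))
  cands <- (u[-length(u)] + u[-1]) / 2
  tval <- sapply(cands, function(thr) {
    lo <- corrs[dists < thr]; hi <- corrs[dists >= thr]
    sp2 <- (sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) /
      (length(lo) + length(hi) - 2)
    (mean(lo) - mean(hi)) / sqrt(sp2 * (1 / length(lo) + 1 / length(hi)))
  })
  expect_equal(cands[which.max(tval)], 0.06)
})

test_that("cluster_below_threshold finds connected components with ordered groups", {
  labs <- paste0("o", 1:6)
  m <- matrix(0.2, 6, 6, dimnames = list(labs, labs))
  m[1:3, 1:3] <- 0.01; m[4:6, 4:6] <- 0.01
  diag(m) <- 0
  g <- distance_matrix(m, labs)
  grp <- cluster_below_threshold(g, 0.05)
  expect_equal(grp$n_groups, 2L)
  expect_equal(unname(grp$membership[1:3]), rep(1L, 3))
  expect_equal(unname(grp$membership[4:6]), rep(2L, 3))
  # all below -> one group; threshold below min -> all singletons
  expect_equal(cluster_below_threshold(g, 0.5)$n_groups, 1L)
  expect_equal(cluster_below_threshold(g, 0.005)$n_groups, 6L)
  expect_error(cluster_below_threshold(g, 0), "positive")
  # single-linkage chaining: a bridge merges the blocks
  m2 <- m; m2["o3", "o4"] <- m2["o4", "o3"] <- 0.01
  expect_equal(cluster_below_threshold(distance_matrix(m2, labs),
                                       0.05)$n_groups, 1L)
})

test_that("group count is non-increasing in threshold", {
  set.seed(17)
  g <- dm_from_lower(runif(45, 0.005, 0.2), paste0("o", 1:10))
  thresholds <- c(0.01, 0.03, 0.06, 0.1, 0.15, 0.25)
  counts <- sapply(thresholds, function(th)
    cluster_below_threshold(g, th)$n_groups)
  expect_true(all(diff(counts) <= 0))
})

test_that("coexclusion_test separates block structure and errors on singletons", {
  labs <- paste0("o", 1:6)
  cm <- matrix(-0.5, 6, 6, dimnames = list(labs, labs))
  cm[1:3, 1:3] <- 0.9; cm[4:6, 4:6] <- 0.9
  diag(cm) <- 1
  cc <- structure(cm, class = c("cooccurrence_matrix", "matrix", "array"))
  m <- matrix(0.2, 6, 6, dimnames = list(labs, labs))
  m[1:3, 1:3] <- 0.01; m[4:6, 4:6] <- 0.01; diag(m) <- 0
  grp <- cluster_below_threshold(distance_matrix(m, labs), 0.05, cc)
  expect_equal(grp$mean_within_correlation, 0.9)
  expect_equal(grp$mean_between_correlation, -0.5)
  res <- coexclusion_test(grp, cc, n_permutations = 199, seed = 1)
  expect_equal(res$difference, 1.4)
  # with two equal-size groups, relabelings reproducing the partition
  # (identity or label swap) are 2 of the 20 distinct arrangements, so the
  # attainable minimum p is near 0.1
  expect_lt(res$p, 0.16)
  # two singleton groups: no within pairs
  m1 <- matrix(c(0, 0.3, 0.3, 0), 2, 2,
               dimnames = list(c("o1", "o2"), c("o1", "o2")))
  grp2 <- cluster_below_threshold(distance_matrix(m1, c("o1", "o2")), 0.1)
  cc2 <- structure(cm[1:2, 1:2],
                   class = c("cooccurrence_matrix", "matrix", "array"))
  expect_error(coexclusion_test(grp2, cc2, n_permutations = 9),
               "within-group pairs")
  expect_error(coexclusion_test(grp, cc, n_permutations = 9, seed = 1),
               NA)
  one <- cluster_below_threshold(distance_matrix(m, labs), 0.5)
  expect_error(coexclusion_test(one, cc), "at least 2 groups")
})

test_that("coexclusion p is uniform for random groups on exchangeable correlations", {
  set.seed(23)
  labs <- paste0("o", 1:8)
  pvals <- replicate(200, {
    cm <- matrix(0, 8, 8, dimnames = list(labs, labs))
    cm[lower.tri(cm)] <- runif(28, -1, 1)
    cm <- cm + t(cm); diag(cm) <- 1
    cc <- structure(cm, class = c("cooccurrence_matrix", "matrix", "array"))
    grp <- structure(list(threshold = 0.05,
                          membership = setNames(rep(1:2, each = 4), labs),
                          n_groups = 2L,
                          mean_within_correlation = NA_real_,
                          mean_between_correlation = NA_real_),
                     class = "cryptic_groups")
    coexclusion_test(grp, cc, n_permutations = 99,
                     seed = sample.int(1e6, 1))$p
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("threshold and groups are recovered on generator output", {
  hits <- 0L
  n_rep <- 40L
  for (seed in seq_len(n_rep)) {
    ds <- simulate_dataset(seed = seed + 1000L)
    tr <- ds$truth$lineages
    foc <- tr$lineage[tr$morphospecies == tr$morphospecies[1]]
    g <- mcl_distance(ds$sequences[foc])
    cc <- spearman_cooccurrence(
      abundance_table(unclass(ds$metabarcoding)[, foc, drop = FALSE],
                      rownames(ds$metabarcoding), foc, mode = "count"))
    est <- estimate_threshold(g, cc)
    same <- outer(tr$group[match(foc, tr$lineage)],
                  tr$group[match(foc, tr$lineage)], "==")
    lt <- lower.tri(g)
    gap_lo <- max(unclass(g)[lt & same], na.rm = TRUE)
    gap_hi <- min(unclass(g)[lt & !same], na.rm = TRUE)
    grp <- cluster_below_threshold(g, est$threshold)
    ari <- adjusted_rand(grp$membership[foc],
                         tr$group[match(foc, tr$lineage)])
    if (est$threshold > gap_lo && est$threshold < gap_hi &&
        abs(ari - 1) < 1e-12) hits <- hits + 1L
  }
  # stated-world recovery rate: >= 95% of replicates (40 seeds here to
  # keep the default suite inside its time budget)
  expect_gte(hits / n_rep, 0.95)
})

test_that("fit slope is negative when co-occurrence decays with distance", {
  signs <- sapply(1:20, function(seed) {
    ds <- simulate_dataset(seed = seed + 2000L)
    tr <- ds$truth$lineages
    foc <- tr$lineage[tr$morphospecies == tr$morphospecies[1]]
    g <- mcl_distance(ds$sequences[foc])
    cc <- spearman_cooccurrence(
      abundance_table(unclass(ds$metabarcoding)[, foc, drop = FALSE],
                      rownames(ds$metabarcoding), foc, mode = "count"))
    fit_distance_cooccurrence(g, cc, n_permutations = 19,
                              seed = seed, exhaustive = FALSE)$slope
  })
  expect_true(all(signs < 0))
})
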