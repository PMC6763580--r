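test_that("HAZ group assignment respects the boundary and imputation", {
  meta <- screen_meta(haz_b = c(-1.5, -1.49, -2.3, 0.4), n_usa = 2)
  g <- assign_groups(meta)
  expect_setequal(g$group0, c("usa01", "usa02"))
  expect_true("bgd01" %in% g$group2)   # HAZ = -1.5 goes to group 2
  expect_true("bgd02" %in% g$group1)   # HAZ = -1.49 stays in group 1
  expect_equal(unname(g$haz[g$group0]), c(0, 0))
  meta$haz[4] <- NA
  expect_warning(g2 <- assign_groups(meta), "bgd02")
  expect_false("bgd02" %in% c(g2$group1, g2$group2))
})

test_that("event statistic matches a hand-computed pooled-SD oracle", {
  # group0 = {2,4}, group1 = {0,2}, group2 = {3,5}
  # var = 2 in every group, pooled sd = sqrt(2); diffs = 2/sqrt(2) = sqrt(2)
  ev <- event_statistic(c(2, 4), c(0, 2), c(3, 5), theta = 0.5)
  expect_equal(ev$d0, sqrt(2), tolerance = 1e-12)
  expect_equal(ev$d2, 3 / sqrt(2), tolerance = 1e-12)
  expect_true(ev$event)
  # mean-equal groups never fire for positive theta
  ev0 <- event_statistic(c(1, 2), c(1, 2), c(1, 2), theta = 0.1)
  expect_equal(ev0$d0, 0)
  expect_false(ev0$event)
  # vacuous threshold
  expect_true(event_statistic(c(1, 2), c(1, 2), c(1, 2), theta = -100)$event)
  # zero pooled SD is undefined
  expect_true(is.na(event_statistic(c(1, 1), c(1, 1), c(2, 2), 0)$event))
})

test_that("event criterion is translation-invariant and scale-equivariant", {
  set.seed(3)
  for (i in 1:10) {
    x0 <- rnorm(5); x1 <- rnorm(8); x2 <- rnorm(8)
    base <- event_statistic(x0, x1, x2, theta = 0.3)
    shift <- event_statistic(x0 + 7, x1 + 7, x2 + 7, theta = 0.3)
    scale <- event_statistic(3 * x0, 3 * x1, 3 * x2, theta = 0.3)
    expect_equal(base$d0, shift$d0, tolerance = 1e-12)
    expect_equal(base$d2, scale$d2, tolerance = 1e-12)
    expect_identical(base$event, shift$event)
    expect_identical(base$event, scale$event)
  }
})

test_that("condition filter removes planted mislabeled samples", {
  set.seed(14)
  n <- 20
  prof <- rbind(matrix(rnorm(10 * 6, 0), 10),    # unstim profile
                matrix(rnorm(10 * 6, 4), 10))    # stim profile
  rownames(prof) <- paste0("s", 1:n)
  cond <- rep(c("unstim", "stim"), each = 10)
  cond[3] <- "stim"                               # mislabeled sample
  kept <- condition_filter(prof, cond, seed = 5)
  expect_false("s3" %in% kept)
  expect_setequal(kept, setdiff(rownames(prof), "s3"))
  # consistent labels: nothing removed; determinism
  kept2 <- condition_filter(prof, rep(c("unstim", "stim"), each = 10),
                            seed = 5)
  expect_setequal(kept2, rownames(prof))
  expect_identical(condition_filter(prof, cond, seed = 5),
                   condition_filter(prof, cond, seed = 5))
  # degenerate identical vectors
  expect_warning(all_kept <- condition_filter(matrix(1, 6, 3),
                                              rep(c("a", "b"), 3), 1),
                 "degenerate")
  expect_equal(length(all_kept), 6L)
})

test_that("permutation screen is seed-stable and super-uniform under null", {
  sim <- simulate_feature_cohort(n_features = 30, effect_sd = 0, seed = 31)
  s1 <- permutation_screen(sim$features, sim$meta, theta_grid = c(0, 0.5, 1),
                           n_perm = 400, seed = 7)
  s2 <- permutation_screen(sim$features, sim$meta, theta_grid = c(0, 0.5, 1),
                           n_perm = 400, seed = 7)
  expect_identical(s1$per_theta$perm_p, s2$per_theta$perm_p)
  expect_true(all(s1$per_theta$perm_p > 0 & s1$per_theta$perm_p <= 1))
  expect_true(all(s1$per_theta$perm_fdr >= 0 & s1$per_theta$perm_fdr <= 1,
                  na.rm = TRUE))
  expect_warning(permutation_screen(sim$features[, 1:3], sim$meta,
                                    theta_grid = 0, n_perm = 50, seed = 1),
                 "unstable")
  # super-uniformity: the joint rate of an observed event with a small
  # permutation p is bounded by alpha (the event indicator is the test
  # statistic, so only observed-event features are ever declared)
  at0 <- s1$per_theta[s1$per_theta$theta == 0, ]
  expect_lte(mean(at0$event & at0$perm_p <= 0.1),
             0.1 + 3 * sqrt(0.1 * 0.9 / 30))
  expect_true(all(at0$perm_p >= 1 / 401))
})

test_that("exchangeable data pushes the FDR estimate toward one", {
  sim <- simulate_feature_cohort(n_features = 50, effect_sd = 0, seed = 77)
  s <- permutation_screen(sim$features, sim$meta, theta_grid = 0,
                          n_perm = 300, seed = 2)
  fdr <- unique(s$per_theta$perm_fdr)
  expect_gte(fdr, 0.5)  # null discoveries track observed ones
})

test_that("a planted U-shaped elevation is recovered as a candidate", {
  hits <- 0L
  for (seed in 1:5) {
    sim <- simulate_feature_cohort(n_features = 30, effect_sd = 2,
                                   seed = 100 + seed)
    s <- permutation_screen(sim$features, sim$meta,
                            theta_grid = seq(0, 2, 0.25),
                            n_perm = 500, seed = seed)
    if (sim$planted_feature %in% s$candidates$feature) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("PC1 validation reduces to a one-sided t-test for one column", {
  set.seed(41)
  x <- c(rnorm(8), rnorm(8, 1.5))
  stunted <- rep(c(FALSE, TRUE), each = 8)
  v <- validate_pc1(matrix(x, ncol = 1, dimnames = list(paste0("s", 1:16),
                                                        "pop1")), stunted)
  ref <- t.test(x[stunted], x[!stunted], alternative = "greater",
                var.equal = TRUE)
  expect_equal(v$p, ref$p.value, tolerance = 1e-12)
  expect_equal(v$pc1_share, 1)
  # perfectly correlated columns concentrate all variance on PC1
  m <- cbind(x, 2 * x, -x)
  rownames(m) <- paste0("s", 1:16)
  v3 <- validate_pc1(m, stunted)
  expect_equal(v3$pc1_share, 1, tolerance = 1e-12)
  # planted shift across 4 correlated columns is detected at n = 8 + 8
  set.seed(42)
  power_hits <- 0L
  for (i in 1:10) {
    base <- rnorm(16)
    m4 <- sapply(1:4, function(j) base + rnorm(16, sd = 0.5) +
                   2 * stunted)
    rownames(m4) <- paste0("s", 1:16)
    if (validate_pc1(m4, stunted)$p < 0.05) power_hits <- power_hits + 1L
  }
  expect_gte(power_hits, 9L)
})

test_that("Fisher combination matches the chi-square tail", {
  expect_equal(combine_pvalues(1, 1), 1)
  stat <- -2 * (log(0.05) + log(0.05))
  expect_equal(stat, 11.98, tolerance = 0.01)
  expect_equal(combine_pvalues(0.05, 0.05),
               pchisq(stat, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(combine_pvalues(0.05, 0.05), 0.0175, tolerance = 0.002)
  expect_warning(p0 <- combine_pvalues(0, 0.5), "clipped")
  expect_true(p0 >= 0)
  # uniform inputs stay uniform after combination
  set.seed(13)
  pc <- replicate(2000, combine_pvalues(runif(1), runif(1)))
  expect_gt(ks.test(pc, "punif")$p.value, 0.001)
})
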