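test_that("occupancy is the per-sample fraction and rows sum to one", {
  labels <- c(rep(1, 4), rep(2, 6),   # sample A: 10 cells, 4 in cluster 1
              rep(1, 2), rep(3, 2))   # sample B: 4 cells
  sids <- rep(c("A", "B"), c(10, 4))
  occ <- compute_occupancy(labels, sids, k = 3)
  expect_equal(occ["A", "cluster_1"], 0.4)
  expect_equal(occ["B", "cluster_3"], 0.5)
  expect_equal(rowSums(occ), c(A = 1, B = 1))
  # random labelings always normalize
  set.seed(4)
  for (i in 1:10) {
    l <- sample(5, 300, replace = TRUE)
    s <- sample(letters[1:6], 300, replace = TRUE)
    o <- compute_occupancy(l, s, k = 5)
    expect_equal(unname(rowSums(o)), rep(1, nrow(o)), tolerance = 1e-9)
    expect_true(all(o >= 0 & o <= 1))
  }
})

test_that("reference cells are excluded but their clusters keep columns", {
  labels <- c(rep(1, 5), rep(2, 5), rep(3, 10))
  sids <- c(rep("A", 5), rep("A", 5), rep("adult_ref", 10))
  occ <- compute_occupancy(labels, sids, exclude = "adult_ref", k = 3)
  expect_equal(rownames(occ), "A")
  expect_equal(occ["A", "cluster_3"], 0)
  expect_equal(ncol(occ), 3L)
})

test_that("occupancy ratios behave and detect a planted shift", {
  occ <- rbind(a1 = c(0.2, 0.8), a2 = c(0.2, 0.8),
               b1 = c(0.1, 0.9), b2 = c(0.1, 0.9))
  colnames(occ) <- c("cluster_1", "cluster_2")
  r <- occupancy_ratio(occ, c("a1", "a2"), c("b1", "b2"))
  expect_equal(unname(r[1]), 2)
  expect_equal(unname(occupancy_ratio(occ, c("a1", "a2"), c("a1", "a2"))),
               c(1, 1))
  expect_error(occupancy_ratio(occ, character(), "b1"), "nonempty")
  # planted 3x abundance shift in a simulated two-population cohort
  set.seed(6)
  n_s <- 12
  occ2 <- t(vapply(seq_len(n_s), function(i) {
    p1 <- if (i <= 6) 0.6 else 0.2     # 3x between cohorts
    x <- rbinom(1, 2000, p1) / 2000
    c(x, 1 - x)
  }, numeric(2)))
  rownames(occ2) <- paste0("s", seq_len(n_s))
  colnames(occ2) <- c("cluster_1", "cluster_2")
  r2 <- occupancy_ratio(occ2, paste0("s", 1:6), paste0("s", 7:12))
  expect_equal(unname(r2[1]), 3, tolerance = 0.15)
})

test_that("rank-sum p matches exact enumeration for small untied groups", {
  set.seed(2)
  for (i in 1:12) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    x <- rnorm(nx); y <- rnorm(ny, 0.5)
    occ <- matrix(c(x, y, 1 - c(x, y)), ncol = 2,
                  dimnames = list(paste0("s", seq_len(nx + ny)),
                                  c("cluster_1", "cluster_2")))
    meta <- data.frame(sample_id = rownames(occ),
                       location = rep(c("A", "B"), c(nx, ny)))
    res <- test_occupancy(occ, meta, group = "location", stratify = NULL)
    p1 <- res$p_value[res$cluster == "cluster_1"]
    expect_equal(p1, oracle_mw_exact(x, y), tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up definition", {
  # hand computation: p = (.01,.02,.03,.04), m = 4 -> all 0.04
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  expect_equal(oracle_bh(p), rep(0.04, 4))
  set.seed(3)
  for (i in 1:10) {
    p <- runif(sample(3:20, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # BH is applied within each stratum across clusters
  set.seed(9)
  occ <- matrix(runif(16 * 4), 16,
                dimnames = list(paste0("s", 1:16), paste0("cluster_", 1:4)))
  occ <- occ / rowSums(occ)
  meta <- data.frame(sample_id = rownames(occ),
                     location = rep(c("A", "B"), 8),
                     week = rep(c(53, 104), each = 8))
  res <- test_occupancy(occ, meta)
  for (st in unique(res$stratum)) {
    sub <- res[res$stratum == st, ]
    expect_equal(sub$fdr, p.adjust(sub$p_value, "BH"))
  }
})

test_that("singleton-group strata are skipped with a warning", {
  occ <- matrix(runif(5 * 2), 5,
                dimnames = list(paste0("s", 1:5), paste0("cluster_", 1:2)))
  occ <- occ / rowSums(occ)
  meta <- data.frame(sample_id = rownames(occ),
                     location = c("A", "A", "B", "B", "B"),
                     week = c(53, 53, 53, 53, 104))
  expect_warning(res <- test_occupancy(occ, meta), "skipped")
  expect_true(all(res$stratum == "53"))
})

test_that("rank-sum type-I error is nominal under the null", {
  set.seed(17)
  n_rep <- 2000
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    x <- rnorm(8); y <- rnorm(8)
    rej[i] <- suppressWarnings(wilcox.test(x, y)$p.value) <= 0.05
  }
  ci <- qbinom(c(0.025, 0.975), n_rep, 0.05) / n_rep
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
})

test_that("PCA retains all but the final dimension", {
  set.seed(5)
  occ <- matrix(runif(10 * 5), 10,
                dimnames = list(paste0("s", 1:10), paste0("c", 1:5)))
  occ <- occ / rowSums(occ)
  sc <- pca_occupancy(occ)
  expect_equal(ncol(sc), 3L)  # rank 4 (rows sum to 1) minus final dimension
  # duplicated samples get identical scores
  occ2 <- rbind(occ, occ[3, , drop = FALSE])
  rownames(occ2)[11] <- "dup"
  sc2 <- pca_occupancy(occ2)
  expect_equal(unname(sc2["dup", ]), unname(sc2["s3", ]), tolerance = 1e-10)
  # eigenvalue ordering: leading retained variance dominates any other set
  vs <- attr(sc, "var_share")
  expect_true(all(diff(vs) <= 1e-12))
})

test_that("MANOVA Pillai reduces to one-way ANOVA F in the univariate case", {
  set.seed(8)
  g <- rep(c("x", "y"), each = 10)
  yv <- rnorm(20) + (g == "y") * 0.8
  scores <- matrix(yv, ncol = 1, dimnames = list(paste0("s", 1:20), "PC1"))
  meta <- data.frame(sample_id = paste0("s", 1:20), grp = g)
  vp <- manova_partition(scores, meta, covariates = "grp")
  ref <- anova(lm(yv ~ g))
  expect_equal(vp$F_approx, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(vp$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  # and partial eta2 equals the univariate R^2 here (Pillai with s = 1)
  expect_equal(vp$partial_eta2,
               summary(lm(yv ~ g))$r.squared, tolerance = 1e-10)
})

test_that("null covariates give uniform p; planted effects dominate", {
  set.seed(21)
  n_rep <- 400
  pvals <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    scores <- matrix(rnorm(24 * 3), 24)
    rownames(scores) <- paste0("s", 1:24)
    meta <- data.frame(sample_id = paste0("s", 1:24),
                       grp = sample(rep(c("a", "b"), 12)))
    pvals[i] <- manova_partition(scores, meta, covariates = "grp")$p_value
  }
  rej <- mean(pvals <= 0.05)
  ci <- qbinom(c(0.025, 0.975), n_rep, 0.05) / n_rep
  expect_gte(rej, ci[1]); expect_lte(rej, ci[2])
  # planted location effect has the largest partial eta2 among covariates
  set.seed(22)
  loc <- rep(c("BGD", "USA"), c(14, 10))
  scores <- matrix(rnorm(24 * 3), 24) + cbind((loc == "BGD") * 3, 0, 0)
  rownames(scores) <- paste0("s", 1:24)
  meta <- data.frame(sample_id = paste0("s", 1:24), location = loc,
                     sex = sample(c("F", "M"), 24, TRUE),
                     batch_set = sample(c("set1", "set2"), 24, TRUE))
  vp <- manova_partition(scores, meta,
                         covariates = c("batch_set", "location", "sex"))
  expect_equal(vp$covariate[which.max(vp$partial_eta2)], "location")
  expect_true(all(vp$partial_eta2 >= 0 & vp$partial_eta2 <= 1))
})

test_that("collinear covariates are rejected by name", {
  set.seed(2)
  scores <- matrix(rnorm(12 * 2), 12)
  rownames(scores) <- paste0("s", 1:12)
  g <- rep(c("a", "b"), 6)
  meta <- data.frame(sample_id = paste0("s", 1:12), g1 = g, g2 = g)
  expect_error(manova_partition(scores, meta, covariates = c("g1", "g2")),
               "aliased|collinear")
})
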