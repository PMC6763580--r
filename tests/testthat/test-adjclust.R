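test_that("weighted distance matches its closed forms", {
  expect_equal(weighted_distance(c(1, 2), c(1, 2), c(3, 4)), 0)
  expect_equal(weighted_distance(c(1, 0), c(0, 0), c(4, 1)), 2)
  set.seed(1)
  for (i in 1:20) {
    p <- rnorm(6); q <- rnorm(6)
    expect_equal(weighted_distance(p, q, rep(1, 6)),
                 sqrt(sum((p - q)^2)), tolerance = 1e-12)
  }
  expect_error(weighted_distance(1:3, 1:2, 1:3), "length")
  expect_error(weighted_distance(1:2, 1:2, c(-1, 1)), ">= 0")
})

test_that("pairwise distances equal the elementwise double loop", {
  inst <- random_instance(20, n_markers = 4, seed = 2)
  d <- inst$d
  expect_true(isSymmetric(d))
  expect_equal(diag(d), rep(0, 20), ignore_attr = TRUE)
  for (i in 1:20) for (j in 1:20)
    expect_equal(d[i, j],
                 weighted_distance(inst$graph$expression[i, ],
                                   inst$graph$expression[j, ], inst$w),
                 tolerance = 1e-12)
  # zero-weight markers are inert
  w2 <- inst$w; w2[2] <- 0
  d2 <- pairwise_distances(inst$graph, w2)
  g_perturbed <- inst$graph
  g_perturbed$expression[, 2] <- rnorm(20)
  expect_equal(pairwise_distances(g_perturbed, w2), d2, tolerance = 1e-12)
})

test_that("two adjacent bins merge once at their distance", {
  g <- make_fixture_bingraph(q = c(0, 1), r = c(0, 0),
                             expression = rbind(c(0, 0), c(3, 4)))
  d <- pairwise_distances(g, c(1, 1))
  h <- constrained_complete_linkage(d, g)
  expect_equal(nrow(h), 1L)
  expect_equal(h$height, 5)
  expect_equal(h$phase, "constrained")
})

test_that("complete-graph adjacency reproduces standard complete linkage", {
  for (seed in 1:10) {
    n <- sample(8:40, 1)
    inst <- random_instance(n, seed = seed + 100)
    g <- complete_adjacency(inst$graph)
    h <- constrained_complete_linkage(inst$d, g)
    expect_true(all(h$phase == "constrained"))
    ref <- hclust(as.dist(inst$d), method = "complete")
    expect_equal(sort(h$height), sort(ref$height), tolerance = 1e-12)
    expect_true(all(diff(h$height) >= -1e-12))  # monotone when unconstrained
    for (k in c(1, 2, max(2, n %/% 2), n)) {
      ours <- cut_tree(h, k)$bin_cluster
      theirs <- cutree(ref, k)
      tab <- table(ours, theirs)
      expect_equal(sum(tab > 0), k)  # partitions identical up to labels
    }
  }
})

test_that("constrained linkage matches the brute-force rescan oracle", {
  for (seed in 1:12) {
    n <- sample(8:30, 1)
    inst <- random_instance(n, seed = seed)
    h <- constrained_complete_linkage(inst$d, inst$graph)
    oracle <- oracle_constrained_linkage(inst$d, adjacency_matrix(inst$graph))
    expect_equal(h$a, oracle$a)
    expect_equal(h$b, oracle$b)
    expect_equal(h$height, oracle$height, tolerance = 1e-12)
    expect_equal(h$phase, oracle$phase)
  }
})

test_that("constrained-phase clusters induce connected subgraphs", {
  inst <- random_instance(40, seed = 31)
  A <- adjacency_matrix(inst$graph)
  h <- constrained_complete_linkage(inst$d, inst$graph)
  n <- nrow(inst$d)
  members <- as.list(seq_len(n))
  for (s in seq_len(nrow(h))) {
    if (h$phase[s] != "constrained") break
    members[[h$a[s]]] <- c(members[[h$a[s]]], members[[h$b[s]]])
    members[[h$b[s]]] <- integer()
    cl <- members[[h$a[s]]]
    # BFS within the cluster over bin adjacency
    seen <- cl[1]
    repeat {
      nb <- which(apply(A[seen, , drop = FALSE], 2, any))
      new <- setdiff(intersect(nb, cl), seen)
      if (!length(new)) break
      seen <- c(seen, new)
    }
    expect_setequal(seen, cl)
  }
})

test_that("phase switches at most once and heights are sane", {
  # two disconnected patches: constrained phase must end with 2 clusters
  pos <- rbind(expand.grid(q = 0:1, r = 0:1), expand.grid(q = 20:21, r = 0:1))
  set.seed(9)
  g <- make_fixture_bingraph(pos$q, pos$r,
                             expression = matrix(rnorm(16), 8))
  # strip the fallback edge bridging the patches to keep them disconnected
  g$edges <- g$edges[g$edges$kind == "border", ]
  d <- pairwise_distances(g, c(1, 1))
  h <- constrained_complete_linkage(d, g)
  expect_equal(nrow(h), 7L)
  phase_flip <- rle(h$phase)
  expect_equal(phase_flip$values, c("constrained", "unconstrained"))
  expect_equal(phase_flip$lengths[2], 1L)  # exactly one cross-patch merge
})

test_that("merge-order cut matches the oracle replay and edge cases", {
  inst <- random_instance(12, seed = 77)
  h <- constrained_complete_linkage(inst$d, inst$graph)
  oracle <- oracle_constrained_linkage(inst$d, adjacency_matrix(inst$graph))
  for (k in c(1, 3, 12)) {
    ours <- cut_tree(h, k)$bin_cluster
    ref <- oracle_cut(oracle, 12, k)
    expect_identical(ours, ref)
  }
  expect_identical(cut_tree(h, 12)$bin_cluster, 1:12)
  expect_true(all(cut_tree(h, 1)$bin_cluster == 1L))
  expect_error(cut_tree(h, 0), "between")
  expect_error(cut_tree(h, 13), "between")
})

test_that("bin relabeling permutes the partition consistently", {
  inst <- random_instance(15, seed = 55)
  h <- constrained_complete_linkage(inst$d, inst$graph)
  lab <- cut_tree(h, 4)$bin_cluster
  perm <- sample(15)
  g2 <- inst$graph
  g2$bins <- g2$bins[perm, ]
  g2$bins$bin_id <- seq_len(15)
  g2$expression <- g2$expression[perm, , drop = FALSE]
  old_edges <- inst$graph$edges
  inv <- order(perm)
  g2$edges <- data.frame(a = pmin(inv[old_edges$a], inv[old_edges$b]),
                         b = pmax(inv[old_edges$a], inv[old_edges$b]),
                         kind = old_edges$kind)
  d2 <- pairwise_distances(g2, inst$w)
  h2 <- constrained_complete_linkage(d2, g2)
  lab2 <- cut_tree(h2, 4)$bin_cluster
  # same partition up to label names
  expect_equal(sum(table(lab[perm], lab2) > 0), 4)
})

test_that("minimum-size enforcement absorbs along the dendrogram", {
  # chain of 4 bins with cell counts: cut at k=3 leaves a tiny cluster
  g <- make_fixture_bingraph(q = 0:3, r = rep(0, 4),
                             expression = cbind(c(0, 1, 10, 11)),
                             counts = c(50, 3, 50, 50))
  d <- pairwise_distances(g, 1)
  h <- constrained_complete_linkage(d, g)
  a3 <- cut_tree(h, 3, graph = g)
  # no-op when everything is big enough
  same <- enforce_min_size(a3, h, min_cells = 1, d = d)
  expect_equal(same$k, 3L)
  # bin 2 (3 cells) joined bin 1 first in the history -> absorbed into it
  fixed <- enforce_min_size(a3, h, min_cells = 20, d = d)
  expect_true(all(fixed$cluster_cells >= 20))
  expect_equal(fixed$bin_cluster[1], fixed$bin_cluster[2])
  # pathological chain of tiny clusters terminates and respects the floor
  set.seed(12)
  inst <- random_instance(30, seed = 41)
  h2 <- constrained_complete_linkage(inst$d, inst$graph)
  a2 <- cut_tree(h2, 10, graph = inst$graph)
  for (floor_cells in c(10, 60, 200)) {
    f <- enforce_min_size(a2, h2, min_cells = floor_cells, d = inst$d)
    if (f$k > 1) expect_true(all(f$cluster_cells >= floor_cells))
    expect_equal(sum(f$cluster_cells), sum(inst$graph$bins$n_cells))
  }
  # warning when the total is below the floor
  expect_warning(one <- enforce_min_size(a3, h, min_cells = 1e6, d = d),
                 "single cluster")
  expect_equal(one$k, 1L)
})

test_that("cell propagation conserves counts and follows bins", {
  inst <- random_instance(25, seed = 19)
  h <- constrained_complete_linkage(inst$d, inst$graph)
  a <- propagate_to_cells(cut_tree(h, 5, graph = inst$graph), inst$graph)
  expect_equal(length(a$cell_cluster), sum(inst$graph$bins$n_cells))
  expect_equal(sum(a$cluster_cells), sum(inst$graph$bins$n_cells))
  # a bin's cells all carry the bin's label
  b7 <- which(inst$graph$cell_bin == 7)
  expect_true(all(a$cell_cluster[b7] == a$bin_cluster[7]))
})

test_that("newick export is well formed and covers all bins", {
  inst <- random_instance(8, seed = 3)
  h <- constrained_complete_linkage(inst$d, inst$graph)
  nwk <- merge_history_newick(h)
  tr <- ape::read.tree(text = nwk)
  expect_equal(sort(tr$tip.label), sort(paste0("bin", 1:8)))
  expect_equal(tr$Nnode, 7)
})
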