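# Independent reference implementations used as test oracles. These are
# deliberately naive (full rescans, exhaustive enumeration) and share no code
# with the package internals they check.

# Brute-force two-phase constrained complete linkage: rescan every cluster
# pair at every step. Clusters are identified by their smallest member bin;
# ties on distance break to the lexicographically smallest (a, b).
oracle_constrained_linkage <- function(d, A) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  out <- data.frame(step = integer(), a = integer(), b = integer(),
                    height = numeric(), phase = character())
  constrained <- TRUE
  step <- 0L
  while (length(clusters) > 1L) {
    reps <- vapply(clusters, min, integer(1))
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        adj <- any(A[clusters[[i]], clusters[[j]]])
        if (constrained && !adj) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        a <- min(reps[i], reps[j]); b <- max(reps[i], reps[j])
        if (is.null(best) || h < best$h ||
            (h == best$h && (a < best$a || (a == best$a && b < best$b))))
          best <- list(i = i, j = j, h = h, a = a, b = b)
      }
    }
    if (is.null(best)) {        # no adjacent pair left: switch phase
      constrained <- FALSE
      next
    }
    step <- step + 1L
    out <- rbind(out, data.frame(
      step = step, a = best$a, b = best$b, height = best$h,
      phase = if (constrained) "constrained" else "unconstrained"))
    clusters[[best$i]] <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters[[best$j]] <- NULL
  }
  out
}

# Partition from the oracle history replayed until k clusters remain.
oracle_cut <- function(history, n, k) {
  clusters <- as.list(seq_len(n))
  reps <- function() vapply(clusters, min, integer(1))
  for (s in seq_len(n - k)) {
    i <- which(vapply(clusters, function(cl) history$a[s] %in% cl,
                      logical(1)))
    j <- which(vapply(clusters, function(cl) history$b[s] %in% cl,
                      logical(1)))
    clusters[[i]] <- sort(c(clusters[[i]], clusters[[j]]))
    clusters[[j]] <- NULL
  }
  # renumber clusters 1..k by smallest member
  o <- order(vapply(clusters, min, integer(1)))
  lab2 <- integer(n)
  for (i in seq_along(o)) lab2[clusters[[o[i]]]] <- i
  lab2
}

# Random bin-graph instance on a hex lattice patch: sample n occupied
# positions from a side x side axial lattice (sparse occupancy gives sparse,
# possibly disconnected adjacency; fallback edges reconnect isolates).
random_instance <- function(n, side = NULL, n_markers = 3, seed = 1) {
  set.seed(seed)
  if (is.null(side)) side <- ceiling(sqrt(n * 2.5))
  all_pos <- expand.grid(q = seq_len(side), r = seq_len(side))
  pick <- sample(nrow(all_pos), n)
  g <- make_fixture_bingraph(all_pos$q[pick], all_pos$r[pick],
                             expression = matrix(rnorm(n * n_markers), n),
                             counts = sample(1:30, n, replace = TRUE))
  w <- runif(n_markers, 0.2, 2)
  list(graph = g, w = w, d = pairwise_distances(g, w))
}

# Same bin graph but with complete-graph adjacency (every pair adjacent).
complete_adjacency <- function(graph) {
  n <- nrow(graph$bins)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  graph$edges <- data.frame(a = pairs[, 1], b = pairs[, 2], kind = "border",
                            stringsAsFactors = FALSE)
  graph
}

adjacency_matrix <- function(graph) {
  n <- nrow(graph$bins)
  A <- matrix(FALSE, n, n)
  if (nrow(graph$edges)) {
    A[cbind(graph$edges$a, graph$edges$b)] <- TRUE
    A[cbind(graph$edges$b, graph$edges$a)] <- TRUE
  }
  A
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mw_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  combs <- utils::combn(n + m, n)
  u_all <- apply(combs, 2, function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(2 * min(p_lo, p_hi), 1)
}

# Benjamini-Hochberg step-up by the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# tiny deterministic metadata table for screen tests
screen_meta <- function(haz_b, n_usa = 5) {
  data.frame(
    sample_id = c(sprintf("usa%02d", seq_len(n_usa)),
                  sprintf("bgd%02d", seq_along(haz_b))),
    location = rep(c("USA", "Bangladesh"), c(n_usa, length(haz_b))),
    haz = c(rep(NA_real_, n_usa), haz_b),
    stringsAsFactors = FALSE)
}
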