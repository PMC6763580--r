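#' Adjacency-constrained complete-linkage clustering of bins
#'
#' Greedy agglomeration over the bin distance matrix in two phases. In the
#' constrained phase, the pair of clusters with the smallest complete-linkage
#' distance \emph{among pairs joined by at least one cross-cluster
#' bin-adjacency edge} is merged; border and nearest-fallback edges count
#' equally. When no adjacent pair remains (each adjacency component has
#' collapsed into one cluster) the remaining merges use standard,
#' unconstrained complete linkage. Distance ties break to the
#' lexicographically smallest pair of cluster ids, where a cluster's id is its
#' smallest member bin id.
#'
#' @param d symmetric (bins x bins) distance matrix, e.g. from
#'   \code{\link{pairwise_distances}}.
#' @param graph a \code{bin_graph} over the same bins, with adjacency edges
#'   (\code{\link{build_adjacency}}); no bin may be isolated.
#' @return A \code{merge_history} data frame with columns \code{step},
#'   \code{a}, \code{b} (representative bin ids, \code{a < b}), \code{height}
#'   (complete-linkage distance at the merge) and \code{phase}
#'   (\code{"constrained"}/\code{"unconstrained"}). Heights may be
#'   non-monotone within the constrained phase; within the unconstrained phase
#'   they are non-decreasing.
#' @export
constrained_complete_linkage <- function(d, graph) {
  stopifnot(inherits(graph, "bin_graph"))
  d <- as.matrix(d)
  n <- nrow(graph$bins)
  if (!all(dim(d) == n)) stop("distance matrix does not match bin count")
  if (n < 2L) {
    h <- data.frame(step = integer(), a = integer(), b = integer(),
                    height = numeric(), phase = character())
    return(structure(h, class = c("merge_history", "data.frame"),
                     n_bins = n))
  }
  A <- matrix(FALSE, n, n)
  if (nrow(graph$edges)) {
    A[cbind(graph$edges$a, graph$edges$b)] <- TRUE
    A[cbind(graph$edges$b, graph$edges$a)] <- TRUE
  }
  if (any(rowSums(A) == 0))
    stop("adjacency graph has isolated bins; run build_adjacency first")
  m <- constrained_linkage_cpp(d, A)
  h <- data.frame(step = seq_len(n - 1L),
                  a = as.integer(m[, 1]), b = as.integer(m[, 2]),
                  height = m[, 3],
                  phase = c("constrained", "unconstrained")[m[, 4]])
  structure(h, class = c("merge_history", "data.frame"), n_bins = n)
}

#' @export
print.merge_history <- function(x, ...) {
  nc <- sum(x$phase == "constrained")
  cat("<merge_history> ", nrow(x), " merges over ", attr(x, "n_bins"),
      " bins (", nc, " constrained, ", nrow(x) - nc, " unconstrained)\n",
      sep = "")
  invisible(x)
}

#' Cut a merge history to k clusters
#'
#' Constrained merges can be height-non-monotone, so the cut is defined by
#' merge order: the last \code{k - 1} merges are undone, i.e. only the first
#' \code{n_bins - k} merges are replayed. Clusters are renumbered 1..k in
#' order of their smallest member bin id.
#'
#' @param history a \code{merge_history}.
#' @param k desired number of clusters, between 1 and the number of bins.
#' @param graph optional \code{bin_graph}; when given, per-bin cell counts are
#'   attached so cluster cell sizes are available downstream.
#' @return A \code{cluster_assignment}: \code{bin_cluster} (one label per
#'   bin), \code{k}, and when \code{graph} was supplied \code{bin_cells} and
#'   \code{cluster_cells}.
#' @export
cut_tree <- function(history, k, graph = NULL) {
  stopifnot(inherits(history, "merge_history"))
  n <- attr(history, "n_bins")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n)
    stop("k must be between 1 and the number of bins (", n, ")")
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  n_replay <- n - as.integer(k)
  for (s in seq_len(n_replay)) {
    ra <- find(history$a[s]); rb <- find(history$b[s])
    parent[max(ra, rb)] <- min(ra, rb)
  }
  rep_of <- vapply(seq_len(n), find, integer(1))
  labels <- match(rep_of, sort(unique(rep_of)))
  assign <- structure(list(bin_cluster = labels, k = as.integer(k)),
                      class = "cluster_assignment")
  if (!is.null(graph)) {
    stopifnot(inherits(graph, "bin_graph"),
              nrow(graph$bins) == n)
    assign$bin_cells <- graph$bins$n_cells
    assign$cluster_cells <- as.vector(
      rowsum(graph$bins$n_cells, labels)[, 1])
  }
  assign
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", x$k, " clusters over ",
      length(x$bin_cluster), " bins", sep = "")
  if (!is.null(x$cluster_cells))
    cat("; cell sizes ", paste(x$cluster_cells, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Enforce a minimum cluster size in cells
#'
#' While any cluster holds fewer than \code{min_cells} cells, the smallest
#' offending cluster is merged into the cluster it joins next in the merge
#' history: the earliest merge step that unites one of its bins with an
#' outside bin identifies the partner, and the offender is absorbed into the
#' current cluster containing that partner bin. This walks the dendrogram
#' upward rather than re-cutting, so the tree topology is respected. If the
#' history cannot resolve a partner (degenerate input) the nearest cluster by
#' complete-linkage distance over \code{d} is used.
#'
#' @param assign a \code{cluster_assignment} carrying \code{bin_cells} (cut
#'   with \code{graph} supplied).
#' @param history the \code{merge_history} the assignment was cut from.
#' @param min_cells minimum cluster size in cells (default 1500).
#' @param d optional distance matrix for the nearest-cluster fallback.
#' @return A \code{cluster_assignment} in which every cluster has at least
#'   \code{min_cells} cells (or a single cluster, with a warning, when the
#'   total is below the floor).
#' @export
enforce_min_size <- function(assign, history, min_cells = 1500, d = NULL) {
  stopifnot(inherits(assign, "cluster_assignment"),
            inherits(history, "merge_history"))
  if (is.null(assign$bin_cells))
    stop("assignment lacks bin cell counts; cut_tree with graph = ...")
  n <- length(assign$bin_cluster)
  labels <- assign$bin_cluster
  bin_cells <- assign$bin_cells
  if (sum(bin_cells) < min_cells && length(unique(labels)) > 1L) {
    warning("total cells (", sum(bin_cells), ") below min_cells (",
            min_cells, "); returning a single cluster")
  }
  repeat {
    sizes <- rowsum(bin_cells, labels)[, 1]
    ids <- as.integer(rownames(rowsum(bin_cells, labels)))
    small <- ids[sizes < min_cells]
    if (!length(small) || length(ids) == 1L) break
    offender <- small[which.min(sizes[match(small, ids)])]
    inS <- labels == offender
    target <- next_merge_partner(history, inS, labels)
    if (is.na(target)) {
      if (!is.null(d)) {
        cand <- setdiff(ids, offender)
        cl_d <- vapply(cand, function(cc)
          max(d[inS, labels == cc, drop = FALSE]), numeric(1))
        target <- cand[which.min(cl_d)]
      } else {
        target <- setdiff(ids, offender)[1L]
      }
    }
    labels[inS] <- target
  }
  labels <- match(labels, sort(unique(labels)))
  out <- structure(list(bin_cluster = labels,
                        k = length(unique(labels)),
                        bin_cells = bin_cells,
                        cluster_cells = as.vector(
                          rowsum(bin_cells, labels)[, 1])),
                   class = "cluster_assignment")
  out
}

# Earliest history step uniting a bin of S with an outside bin; returns the
# current-partition label of the outside side's representative bin (NA if no
# such step exists). Until that step every replayed cluster is pure (all-S or
# all-outside), so the two sides of the qualifying merge are unambiguous.
next_merge_partner <- function(history, inS, labels) {
  n <- length(inS)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  has_s <- inS            # does the cluster rooted at i contain an S bin?
  for (s in seq_len(nrow(history))) {
    ra <- find(history$a[s]); rb <- find(history$b[s])
    if (ra == rb) next
    if (has_s[ra] != has_s[rb]) {
      # outside side's representative is its root (smallest member bin id)
      return(labels[if (has_s[ra]) rb else ra])
    }
    root <- min(ra, rb)
    parent[max(ra, rb)] <- root
    has_s[root] <- has_s[ra] || has_s[rb]
  }
  NA_integer_
}

#' Propagate bin cluster labels to cells
#'
#' Every cell inherits the cluster of its bin.
#'
#' @param assign a \code{cluster_assignment} over the bins of \code{graph}.
#' @param graph the \code{bin_graph} holding the cell-to-bin map.
#' @return The assignment with \code{cell_cluster} (one label per pooled
#'   cell), \code{cell_sample} and per-cluster cell counts filled in.
#' @export
propagate_to_cells <- function(assign, graph) {
  stopifnot(inherits(assign, "cluster_assignment"),
            inherits(graph, "bin_graph"))
  if (length(assign$bin_cluster) != nrow(graph$bins))
    stop("assignment does not cover the bin graph")
  assign$cell_cluster <- assign$bin_cluster[graph$cell_bin]
  assign$cell_sample <- graph$sample_id
  assign$cluster_cells <- tabulate(assign$cell_cluster, nbins = assign$k)
  assign$bin_cells <- graph$bins$n_cells
  assign
}

#' One-call clustering of a bin graph
#'
#' Convenience wrapper: weighted distances, constrained complete linkage,
#' merge-order cut at \code{k}, minimum-size enforcement, and propagation of
#' labels to cells.
#'
#' @param graph a \code{bin_graph} with adjacency edges.
#' @param panel a \code{marker_panel} (or weight vector) for the distances.
#' @param k number of clusters to cut.
#' @param min_cells minimum cluster size in cells (default 1500).
#' @return A list with \code{assignment} (a \code{cluster_assignment} with
#'   cell labels), \code{history} and \code{distances}.
#' @export
hex_adjclust <- function(graph, panel, k, min_cells = 1500) {
  d <- pairwise_distances(graph, panel)
  history <- constrained_complete_linkage(d, graph)
  assign <- cut_tree(history, k, graph = graph)
  assign <- enforce_min_size(assign, history, min_cells = min_cells, d = d)
  assign <- propagate_to_cells(assign, graph)
  list(assignment = assign, history = history, distances = d)
}

#' Export a merge history as a Newick tree string
#'
#' Branch lengths are differences of merge heights along the tree (truncated
#' at zero where constrained merges are non-monotone).
#'
#' @param history a \code{merge_history}.
#' @param labels optional tip labels (default \code{bin<id>}).
#' @return A single Newick string, terminated with ";".
#' @export
merge_history_newick <- function(history, labels = NULL) {
  stopifnot(inherits(history, "merge_history"))
  n <- attr(history, "n_bins")
  if (is.null(labels)) labels <- paste0("bin", seq_len(n))
  node <- as.list(labels)
  height <- rep(0, n)
  for (s in seq_len(nrow(history))) {
    a <- history$a[s]; b <- history$b[s]; h <- history$height[s]
    la <- max(h - height[a], 0); lb <- max(h - height[b], 0)
    node[[a]] <- paste0("(", node[[a]], ":", format(la), ",",
                        node[[b]], ":", format(lb), ")")
    height[a] <- h
  }
  paste0(node[[if (nrow(history)) history$a[nrow(history)] else 1L]], ";")
}
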