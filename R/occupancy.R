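#' Per-sample cluster occupancy
#'
#' Occupancy (s, c) is the fraction of sample s's cells falling in cluster c;
#' each row sums to one. Reference-pool cells (e.g. spiked-in adult controls)
#' are excluded from the sample rows via \code{exclude}, but every cluster
#' keeps a column even if only reference cells occupy it.
#'
#' @param cell_cluster integer cluster label per cell.
#' @param sample_ids sample identifier per cell.
#' @param exclude sample ids to drop from the rows (reference pools).
#' @param k number of clusters (default: max label observed).
#' @return A samples x clusters matrix of fractions with sample ids as row
#'   names and \code{cluster_<c>} column names.
#' @export
compute_occupancy <- function(cell_cluster, sample_ids,
                              exclude = character(), k = max(cell_cluster)) {
  if (length(cell_cluster) != length(sample_ids))
    stop("cell_cluster and sample_ids lengths differ")
  keep <- !(sample_ids %in% exclude)
  cell_cluster <- cell_cluster[keep]
  sample_ids <- sample_ids[keep]
  if (!length(sample_ids)) stop("no cells left after exclusion")
  samples <- unique(sample_ids)
  counts <- table(factor(sample_ids, levels = samples),
                  factor(cell_cluster, levels = seq_len(k)))
  counts <- matrix(counts, nrow = length(samples),
                   dimnames = list(samples, paste0("cluster_", seq_len(k))))
  totals <- rowSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    warning("samples with zero cells excluded: ",
            paste(samples[zero], collapse = ", "))
    counts <- counts[!zero, , drop = FALSE]
    totals <- totals[!zero]
  }
  counts / totals
}

#' Per-cluster occupancy ratio between two sample groups
#'
#' mean occupancy of group A divided by mean occupancy of group B per
#' cluster; 0/0 is undefined and reported as \code{NA}.
#'
#' @param occ occupancy matrix from \code{\link{compute_occupancy}}.
#' @param group_a,group_b character vectors of sample ids (row names).
#' @return Named numeric vector of ratios, one per cluster.
#' @export
occupancy_ratio <- function(occ, group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be nonempty")
  miss <- setdiff(c(group_a, group_b), rownames(occ))
  if (length(miss))
    stop("samples not in occupancy matrix: ", paste(miss, collapse = ", "))
  ma <- colMeans(occ[group_a, , drop = FALSE])
  mb <- colMeans(occ[group_b, , drop = FALSE])
  ratio <- ma / mb
  ratio[ma == 0 & mb == 0] <- NA_real_
  ratio
}

#' Stratified Mann-Whitney tests on cluster occupancy
#'
#' Within each stratum (e.g. timepoint week), a two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test compares the two groups' occupancies for every
#' cluster; the exact null distribution is used when both groups are small
#' and untied, otherwise the normal approximation with mid-ranks and
#' continuity correction. p-values are Benjamini-Hochberg adjusted within
#' each stratum across its clusters, matching the per-timepoint correction
#' scope of the figure legends this workflow reproduces.
#'
#' @param occ occupancy matrix.
#' @param meta data frame with \code{sample_id} plus grouping columns.
#' @param group name of the two-level grouping column (e.g.
#'   \code{"location"}).
#' @param stratify optional name of the stratification column (e.g.
#'   \code{"week"}); \code{NULL} for a single stratum.
#' @param sig_levels thresholds flagged in the output (default
#'   0.1/0.05/0.01/0.001).
#' @return Data frame with one row per stratum x cluster: group sizes, U
#'   statistic, ratio of group means, p, BH-adjusted fdr, and a significance
#'   flag column.
#' @export
test_occupancy <- function(occ, meta, group = "location", stratify = "week",
                           sig_levels = c(0.1, 0.05, 0.01, 0.001)) {
  stopifnot(is.data.frame(meta), "sample_id" %in% names(meta),
            group %in% names(meta))
  meta <- meta[meta$sample_id %in% rownames(occ), , drop = FALSE]
  glev <- sort(unique(as.character(meta[[group]])))
  if (length(glev) != 2L)
    stop("grouping column '", group, "' must have exactly 2 levels, got ",
         length(glev))
  strata <- if (is.null(stratify)) factor(rep("all", nrow(meta)))
            else factor(meta[[stratify]])
  out <- list()
  for (st in levels(strata)) {
    sm <- meta[strata == st, , drop = FALSE]
    ids_a <- sm$sample_id[sm[[group]] == glev[1]]
    ids_b <- sm$sample_id[sm[[group]] == glev[2]]
    if (length(ids_a) < 2L || length(ids_b) < 2L) {
      warning("stratum '", st, "' skipped: fewer than 2 samples in a group")
      next
    }
    res <- lapply(colnames(occ), function(cl) {
      xa <- occ[ids_a, cl]; xb <- occ[ids_b, cl]
      wt <- suppressWarnings(stats::wilcox.test(xa, xb, exact = NULL,
                                                correct = TRUE))
      data.frame(stratum = st, cluster = cl,
                 n_a = length(xa), n_b = length(xb),
                 U = unname(wt$statistic),
                 ratio = if (mean(xa) == 0 && mean(xb) == 0) NA_real_
                         else mean(xa) / mean(xb),
                 p_value = wt$p.value, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$fdr <- stats::p.adjust(res$p_value, method = "BH")
    out[[st]] <- res
  }
  if (!length(out)) stop("no stratum had >= 2 samples per group")
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$signif <- vapply(out$fdr, function(f) {
    hits <- sig_levels[f < sig_levels]
    if (length(hits)) paste0("fdr<", min(hits)) else ""
  }, character(1))
  attr(out, "groups") <- glev
  out
}
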