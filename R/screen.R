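#' Filter samples whose profile contradicts their stimulation label
#'
#' k-means with k = 2 on the sample-level feature vectors; each k-means
#' cluster is assigned the majority declared condition of its members, and
#' samples whose cluster majority disagrees with their own declared condition
#' are removed (e.g. a nominally unstimulated sample whose cytokine profile
#' clusters with the stimulated ones, as when a donor is responding to an
#' acute infection).
#'
#' @param feature_table samples x features numeric matrix (rows named).
#' @param condition_labels declared condition per sample, two levels (e.g.
#'   \code{"unstim"} / \code{"stim"}).
#' @param seed integer seed for the k-means starts.
#' @return Character vector of retained sample ids (row names).
#' @export
condition_filter <- function(feature_table, condition_labels, seed = 1L) {
  x <- as.matrix(feature_table)
  if (nrow(x) != length(condition_labels))
    stop("condition_labels length does not match sample count")
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  cond <- as.character(condition_labels)
  if (length(unique(cond)) != 2L)
    stop("condition_labels must have exactly two levels")
  if (all(apply(x, 2, stats::var) == 0)) {
    warning("degenerate identical feature vectors; retaining all samples")
    return(rownames(x))
  }
  km <- with_seed(seed, stats::kmeans(x, centers = 2L, nstart = 10L))
  majority <- vapply(1:2, function(cl) {
    names(which.max(table(cond[km$cluster == cl])))
  }, character(1))
  keep <- majority[km$cluster] == cond
  rownames(x)[keep]
}

#' Assign screen groups from location and HAZ
#'
#' Group 0: American samples, whose HAZ is imputed as 0 (well-nourished
#' reference); group 1: Bangladeshi samples with HAZ > threshold (less
#' stunted); group 2: Bangladeshi samples with HAZ <= threshold (more
#' stunted). The boundary value itself falls in group 2.
#'
#' @param meta data frame with \code{sample_id}, \code{location}
#'   (\code{"USA"} / \code{"Bangladesh"}) and \code{haz}.
#' @param haz_threshold stunting cut-off on the height-for-age z-score
#'   (default -1.5).
#' @return An object of class \code{haz_groups}: sample-id vectors
#'   \code{group0}, \code{group1}, \code{group2} and the (imputed) HAZ per
#'   sample.
#' @export
assign_groups <- function(meta, haz_threshold = -1.5) {
  stopifnot(is.data.frame(meta),
            all(c("sample_id", "location", "haz") %in% names(meta)))
  usa <- meta$location == "USA"
  bgd <- meta$location == "Bangladesh"
  miss <- bgd & is.na(meta$haz)
  if (any(miss)) {
    warning("Bangladeshi samples without HAZ excluded: ",
            paste(meta$sample_id[miss], collapse = ", "))
    bgd <- bgd & !is.na(meta$haz)
  }
  haz <- ifelse(usa, 0, meta$haz)
  names(haz) <- meta$sample_id
  structure(list(
    group0 = meta$sample_id[usa],
    group1 = meta$sample_id[bgd & meta$haz > haz_threshold],
    group2 = meta$sample_id[bgd & meta$haz <= haz_threshold],
    haz = haz, threshold = haz_threshold), class = "haz_groups")
}

#' @export
print.haz_groups <- function(x, ...) {
  cat("<haz_groups> group0 (American, HAZ=0): ", length(x$group0),
      " | group1 (HAZ > ", x$threshold, "): ", length(x$group1),
      " | group2 (HAZ <= ", x$threshold, "): ", length(x$group2), "\n",
      sep = "")
  invisible(x)
}

# df-weighted two-sample pooled SD
pooled_sd <- function(x, y) {
  na <- length(x); nb <- length(y)
  sqrt(((na - 1) * stats::var(x) + (nb - 1) * stats::var(y)) / (na + nb - 2))
}

#' Two-sided standardized event criterion for one feature
#'
#' The event holds at threshold theta when both the American group (0) and
#' the more-stunted group (2) exceed the less-stunted group (1) by at least
#' theta pooled standard deviations:
#' \eqn{(\mu_0-\mu_1)/s_0 \ge \theta} and \eqn{(\mu_2-\mu_1)/s_2 \ge \theta},
#' where \eqn{s_j} is the df-weighted pooled SD of group j with group 1.
#'
#' @param x0,x1,x2 feature values in groups 0, 1, 2 (each of length >= 2).
#' @param theta standardized threshold.
#' @return List with \code{d0}, \code{d2} (standardized differences) and
#'   \code{event} (logical; \code{NA} when a pooled SD is zero).
#' @export
event_statistic <- function(x0, x1, x2, theta) {
  if (length(x0) < 2L || length(x1) < 2L || length(x2) < 2L)
    stop("each group needs at least 2 samples")
  s0 <- pooled_sd(x0, x1)
  s2 <- pooled_sd(x2, x1)
  if (s0 == 0 || s2 == 0)
    return(list(d0 = NA_real_, d2 = NA_real_, event = NA))
  d0 <- (mean(x0) - mean(x1)) / s0
  d2 <- (mean(x2) - mean(x1)) / s2
  list(d0 = d0, d2 = d2, event = d0 >= theta && d2 >= theta)
}

# standardized differences for all features at once (columns = features)
event_diffs <- function(feat, i0, i1, i2) {
  cm <- function(i) colMeans(feat[i, , drop = FALSE])
  cv <- function(i, m) {
    n <- length(i)
    pmax((colSums(feat[i, , drop = FALSE]^2) - n * m^2) / (n - 1), 0)
  }
  m0 <- cm(i0); m1 <- cm(i1); m2 <- cm(i2)
  v0 <- cv(i0, m0); v1 <- cv(i1, m1); v2 <- cv(i2, m2)
  n0 <- length(i0); n1 <- length(i1); n2 <- length(i2)
  s0 <- sqrt(((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2))
  s2 <- sqrt(((n2 - 1) * v2 + (n1 - 1) * v1) / (n2 + n1 - 2))
  list(d0 = (m0 - m1) / s0, d2 = (m2 - m1) / s2)
}

#' Permutation screen for HAZ-associated functional features
#'
#' For each threshold theta in the grid, the observed event set (features
#' whose standardized group differences both reach theta; see
#' \code{\link{event_statistic}}) is compared against a permutation null:
#' HAZ scores are permuted among the Bangladeshi samples only (the American
#' group's HAZ is an imputed constant and stays fixed) and groups 1/2 are
#' re-derived from the permuted scores. The per-feature permutation p-value
#' at theta uses the add-one estimator (1 + B) / (1 + n_perm); the FDR
#' estimate at theta is the plug-in ratio of the mean null event count to the
#' observed event count, capped at 1.
#'
#' @param features samples x features numeric matrix, rows named by sample.
#' @param meta metadata with \code{sample_id}, \code{location}, \code{haz}.
#' @param theta_grid thresholds to sweep (default 0 to 2 by 0.1).
#' @param n_perm number of HAZ permutations (default 5000).
#' @param seed integer seed.
#' @param p_cut,fdr_cut candidate thresholds (defaults 0.05 and 0.2).
#' @param haz_threshold stunting cut-off passed to
#'   \code{\link{assign_groups}}.
#' @return An object of class \code{screen_result}: \code{per_theta} (a data
#'   frame of feature x theta event indicators, perm p and FDR),
#'   \code{candidates} (features passing both cuts at at least one theta,
#'   with their best theta), \code{groups} and the call parameters.
#' @export
permutation_screen <- function(features, meta, theta_grid = seq(0, 2, 0.1),
                               n_perm = 5000, seed = 1L,
                               p_cut = 0.05, fdr_cut = 0.2,
                               haz_threshold = -1.5) {
  feat <- as.matrix(features)
  if (is.null(rownames(feat))) stop("features must have sample row names")
  if (n_perm < 100)
    warning("n_perm < 100 gives unstable permutation estimates")
  groups <- assign_groups(meta, haz_threshold)
  ids <- rownames(feat)
  i0 <- match(groups$group0, ids)
  ib <- match(c(groups$group1, groups$group2), ids)
  if (any(is.na(c(i0, ib))))
    stop("metadata samples missing from feature table")
  haz_b <- groups$haz[c(groups$group1, groups$group2)]
  obs <- event_diffs(feat, i0,
                     match(groups$group1, ids), match(groups$group2, ids))
  nf <- ncol(feat)
  d0p <- matrix(NA_real_, nf, n_perm)
  d2p <- matrix(NA_real_, nf, n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample(haz_b)
      i1p <- ib[perm > haz_threshold]
      i2p <- ib[perm <= haz_threshold]
      d <- event_diffs(feat, i0, i1p, i2p)
      d0p[, b] <- d$d0
      d2p[, b] <- d$d2
    }
  })
  per_theta <- do.call(rbind, lapply(theta_grid, function(th) {
    ev_obs <- obs$d0 >= th & obs$d2 >= th
    ev_perm <- d0p >= th & d2p >= th           # features x perms
    hits <- rowSums(ev_perm, na.rm = TRUE)
    perm_p <- (1 + hits) / (1 + n_perm)
    n_obs <- sum(ev_obs, na.rm = TRUE)
    null_mean <- mean(colSums(ev_perm, na.rm = TRUE))
    fdr <- if (n_obs > 0) min(null_mean / n_obs, 1) else NA_real_
    data.frame(feature = colnames(feat), theta = th,
               d0 = obs$d0, d2 = obs$d2, event = ev_obs,
               perm_p = perm_p, perm_fdr = fdr,
               stringsAsFactors = FALSE)
  }))
  rownames(per_theta) <- NULL
  cand <- per_theta[per_theta$event & !is.na(per_theta$event) &
                      per_theta$perm_p <= p_cut &
                      !is.na(per_theta$perm_fdr) &
                      per_theta$perm_fdr <= fdr_cut, , drop = FALSE]
  candidates <- if (nrow(cand)) {
    best <- do.call(rbind, lapply(split(cand, cand$feature), function(df) {
      df[which.min(df$perm_p), , drop = FALSE]
    }))
    rownames(best) <- NULL
    best
  } else cand
  structure(list(per_theta = per_theta, candidates = candidates,
                 groups = groups,
                 params = list(theta_grid = theta_grid, n_perm = n_perm,
                               seed = seed, p_cut = p_cut,
                               fdr_cut = fdr_cut)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> ", length(unique(x$per_theta$feature)),
      " features x ", length(x$params$theta_grid), " thresholds, ",
      x$params$n_perm, " permutations; ",
      nrow(x$candidates), " candidate feature(s)\n", sep = "")
  if (nrow(x$candidates))
    cat("  ", paste(x$candidates$feature, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' PC1-based validation of a marker across correlated populations
#'
#' For one marker measured across several cell populations (columns), the
#' first principal component summarizes the shared signal; PC1 is oriented so
#' that larger marker frequencies give larger scores, then regressed on the
#' stunting indicator with a one-sided t-test in the direction "more stunted
#' implies higher".
#'
#' @param mat samples x populations matrix for one marker (rows named).
#' @param stunted logical (or 0/1) per sample: more-stunted indicator.
#' @return List with \code{pc1_share} (variance share of PC1), \code{p}
#'   (one-sided p-value) and \code{t} (the t statistic).
#' @export
validate_pc1 <- function(mat, stunted) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3L) stop("need at least 3 samples")
  stunted <- as.logical(stunted)
  if (length(stunted) != nrow(mat)) stop("stunted length mismatch")
  if (ncol(mat) == 1L) {
    pc1 <- mat[, 1]
    share <- 1
  } else {
    pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
    pc1 <- pc$x[, 1]
    share <- pc$sdev[1]^2 / sum(pc$sdev^2)
    # orient PC1 along the markers (sum of loadings positive)
    if (sum(pc$rotation[, 1]) < 0) pc1 <- -pc1
  }
  fit <- stats::lm(pc1 ~ stunted)
  tt <- summary(fit)$coefficients["stuntedTRUE", ]
  p <- stats::pt(tt["t value"], df = fit$df.residual, lower.tail = FALSE)
  list(pc1_share = unname(share), p = unname(p), t = unname(tt["t value"]))
}

#' Combine two one-sided p-values with Fisher's method
#'
#' \eqn{X = -2(\log p_1 + \log p_2) \sim \chi^2_4} under the null.
#'
#' @param p_train,p_valid p-values in (0, 1].
#' @return The combined p-value.
#' @export
combine_pvalues <- function(p_train, p_valid) {
  p <- c(p_train, p_valid)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-value of 0 clipped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  stats::pchisq(-2 * sum(log(p)), df = 4, lower.tail = FALSE)
}
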