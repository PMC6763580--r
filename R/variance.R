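#' PCA scores of an occupancy matrix
#'
#' Centered (unscaled) principal components of the samples x clusters
#' occupancy matrix. Because occupancy rows sum to one the final dimension is
#' redundant, so all but the final non-degenerate dimension are retained,
#' i.e. the first (rank - 1) components.
#'
#' @param occ occupancy matrix (or any samples x features matrix).
#' @return Matrix of PC scores (samples x retained components), with the
#'   per-component variance share in \code{attr(, "var_share")}.
#' @export
pca_occupancy <- function(occ) {
  occ <- as.matrix(occ)
  if (nrow(occ) < 2L || ncol(occ) < 2L)
    stop("need at least 2 samples and 2 clusters")
  pc <- stats::prcomp(occ, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  retain <- rank - 1L
  if (retain < 1L) {
    warning("rank-deficient input: retaining the available component(s)")
    retain <- max(rank, 1L)
  }
  scores <- pc$x[, seq_len(retain), drop = FALSE]
  attr(scores, "var_share") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(retain)]
  scores
}

#' Type-II MANOVA variance partition over clinical covariates
#'
#' Models the retained principal components as a multivariate linear function
#' of the covariates and performs a type-II MANOVA (\code{car::Anova}) with
#' the Pillai test statistic; per-term Pillai traces are computed from the
#' type-II hypothesis and error SSP matrices, and the p-value uses the usual
#' Pillai F approximation. The partial variance share (partial eta^2) of a
#' covariate is its Pillai trace normalised by s = min(df_term, n_responses),
#' the trace's attainable maximum, so it lies in [0, 1].
#'
#' @param scores samples x components score matrix (rows named by sample).
#' @param meta data frame with \code{sample_id} and the covariate columns.
#' @param covariates character vector of covariate column names (default:
#'   batch set, week, location, ethnicity, sex, CMV status).
#' @return Data frame with one row per covariate: Pillai trace,
#'   \code{partial_eta2}, approximate F, degrees of freedom and p-value.
#' @export
manova_partition <- function(scores, meta,
                             covariates = c("batch_set", "week", "location",
                                            "ethnicity", "sex",
                                            "cmv_status")) {
  scores <- as.matrix(scores)
  stopifnot(is.data.frame(meta), "sample_id" %in% names(meta))
  missing_cov <- setdiff(covariates, names(meta))
  if (length(missing_cov))
    stop("covariates absent from metadata: ",
         paste(missing_cov, collapse = ", "))
  m <- meta[match(rownames(scores), meta$sample_id), , drop = FALSE]
  if (any(is.na(m$sample_id)))
    stop("metadata missing for samples: ",
         paste(setdiff(rownames(scores), meta$sample_id), collapse = ", "))
  dat <- m[, covariates, drop = FALSE]
  # categorical coding throughout; week is binned sampling, not continuous age
  for (j in seq_along(dat)) if (!is.numeric(dat[[j]]))
    dat[[j]] <- factor(dat[[j]])
  dat <- droplevels(dat)
  use <- vapply(dat, function(x)
    if (is.factor(x)) nlevels(x) > 1L else stats::var(x) > 0, logical(1))
  if (any(!use))
    warning("dropping constant covariates: ",
            paste(covariates[!use], collapse = ", "))
  dat <- dat[, use, drop = FALSE]
  if (!ncol(dat)) stop("no usable covariates")
  form <- stats::as.formula(paste("scores ~", paste(names(dat),
                                                    collapse = " + ")))
  fit <- stats::lm(form, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- unique(rownames(which(is.na(stats::coef(fit)), arr.ind = TRUE)))
    stop("collinear covariates (aliased terms): ",
         paste(bad, collapse = ", "))
  }
  p_resp <- ncol(scores)
  if (p_resp == 1L) {
    # single response: the Pillai test collapses to the type-II ANOVA F,
    # and the trace (= partial eta^2 with s = 1) is SSH / (SSH + SSE)
    av1 <- car::Anova(fit, type = "II")
    ss <- av1[["Sum Sq"]]
    terms_ <- rownames(av1)
    resid_row <- terms_ == "Residuals"
    sse <- ss[resid_row]
    out <- data.frame(covariate = terms_[!resid_row],
                      pillai = ss[!resid_row] / (ss[!resid_row] + sse),
                      partial_eta2 = ss[!resid_row] / (ss[!resid_row] + sse),
                      df = av1$Df[!resid_row],
                      F_approx = av1[["F value"]][!resid_row],
                      df1 = av1$Df[!resid_row],
                      df2 = av1$Df[resid_row],
                      p_value = av1[["Pr(>F)"]][!resid_row],
                      stringsAsFactors = FALSE)
    return(out)
  }
  av <- car::Anova(fit, type = "II", test.statistic = "Pillai")
  E <- av$SSPE
  rows <- lapply(seq_along(av$terms), function(i) {
    term <- av$terms[i]
    H <- av$SSP[[term]]
    df_h <- av$df[i]
    df_e <- av$error.df
    s <- min(df_h, p_resp)
    ev <- Re(eigen(H %*% solve(H + E), only.values = TRUE)$values)
    pillai <- sum(pmax(pmin(ev, 1), 0))
    mm <- 0.5 * (abs(p_resp - df_h) - 1)
    nn <- 0.5 * (df_e - p_resp - 1)
    df1 <- s * (2 * mm + s + 1)
    df2 <- s * (2 * nn + s + 1)
    Fval <- (pillai / (s - pillai)) * (df2 / df1)
    data.frame(covariate = term, pillai = pillai,
               partial_eta2 = pillai / s, df = df_h,
               F_approx = Fval, df1 = df1, df2 = df2,
               p_value = stats::pf(Fval, df1, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
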