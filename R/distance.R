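#' Weighted Euclidean distance between two bin-expression vectors
#'
#' \eqn{d(p,q) = \sqrt{\sum_i w_i (p_i - q_i)^2}}, where \eqn{w_i} is the
#' manually assigned clustering weight of marker \eqn{i}. A zero weight makes
#' a marker inert; weights of one recover the ordinary Euclidean distance.
#'
#' @param p,q numeric vectors of equal length.
#' @param w nonnegative weights of the same length.
#' @return A single nonnegative number.
#' @export
weighted_distance <- function(p, q, w) {
  if (length(p) != length(q) || length(p) != length(w))
    stop("p, q and w must have equal lengths")
  if (any(w < 0)) stop("weights must be >= 0")
  sqrt(sum(w * (p - q)^2))
}

#' Pairwise weighted distances between all non-empty bins
#'
#' Scales each expression column by \code{sqrt(w_i)} and takes Euclidean
#' distances, which is algebraically identical to applying
#' \code{\link{weighted_distance}} to every pair.
#'
#' @param graph a \code{bin_graph}.
#' @param panel a \code{marker_panel} aligned to the expression columns, or a
#'   numeric weight vector.
#' @return A symmetric (bins x bins) distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(graph, panel) {
  stopifnot(inherits(graph, "bin_graph"))
  w <- if (inherits(panel, "marker_panel")) {
    if (!identical(panel$markers, colnames(graph$expression)))
      stop("panel markers do not match bin expression columns")
    unname(panel$weights)
  } else as.numeric(panel)
  if (length(w) != ncol(graph$expression))
    stop("weight length does not match expression columns")
  if (any(w < 0)) stop("weights must be >= 0")
  x <- sweep(graph$expression, 2, sqrt(w), `*`)
  as.matrix(stats::dist(x))
}
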