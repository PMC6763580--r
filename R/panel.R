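#' Marker panel with clustering weights
#'
#' A marker panel names the channels used for clustering, carries one
#' nonnegative clustering weight per marker (the \eqn{w_i} of the weighted
#' bin-distance \eqn{d(p,q)=\sqrt{\sum_i w_i (p_i-q_i)^2}}), the asinh
#' cofactor used for transformation, and a role tag per marker
#' (\code{"phenotype"} or \code{"function"}).
#'
#' @param markers character vector of channel labels (unique, non-empty).
#' @param weights numeric vector of nonnegative weights, recycled from a
#'   scalar; at least one weight must be positive.
#' @param cofactor positive scalar for the asinh transform (default 5, the
#'   community standard for CyTOF).
#' @param roles character vector of \code{"phenotype"}/\code{"function"}
#'   tags, recycled from a scalar.
#' @return An object of class \code{marker_panel}.
#' @export
marker_panel <- function(markers, weights = 1, cofactor = 5,
                         roles = "phenotype") {
  markers <- as.character(markers)
  if (length(markers) == 0L || anyDuplicated(markers) || any(!nzchar(markers)))
    stop("markers must be a non-empty set of unique, non-empty labels")
  if (length(weights) == 1L) weights <- rep(weights, length(markers))
  if (length(weights) != length(markers))
    stop("weights length (", length(weights),
         ") does not match marker count (", length(markers), ")")
  weights <- as.numeric(weights)
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("all weights must be finite and >= 0")
  if (all(weights == 0)) stop("at least one weight must be > 0")
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0)
    stop("cofactor must be a single positive number")
  if (length(roles) == 1L) roles <- rep(roles, length(markers))
  if (length(roles) != length(markers))
    stop("roles length does not match marker count")
  if (!all(roles %in% c("phenotype", "function")))
    stop("roles must be 'phenotype' or 'function'")
  structure(list(markers = markers,
                 weights = stats::setNames(weights, markers),
                 cofactor = as.numeric(cofactor),
                 roles = stats::setNames(roles, markers)),
            class = "marker_panel")
}

#' Restrict a panel to a marker subset
#'
#' @param panel a \code{marker_panel}.
#' @param subset character vector of marker names, a subset of the panel.
#' @return A \code{marker_panel} restricted and reordered to \code{subset}.
#' @export
subset_panel <- function(panel, subset) {
  stopifnot(inherits(panel, "marker_panel"))
  missing <- setdiff(subset, panel$markers)
  if (length(missing))
    stop("markers not in panel: ", paste(missing, collapse = ", "))
  marker_panel(subset,
               weights = unname(panel$weights[subset]),
               cofactor = panel$cofactor,
               roles = unname(panel$roles[subset]))
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel> ", length(x$markers), " markers, cofactor ",
      x$cofactor, "\n", sep = "")
  cat("  phenotype: ", sum(x$roles == "phenotype"),
      " | function: ", sum(x$roles == "function"), "\n", sep = "")
  invisible(x)
}
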