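# Hexagonal binning of a 2-D embedding.
#
# Flat-top hexagons on an axial lattice (q, r): center(q, r) =
# origin + (1.5*R*q, sqrt(3)*R*(r + q/2)) with R the center-to-vertex radius.
# Point-to-bin assignment converts to fractional axial coordinates and applies
# cube rounding, which returns the lattice cell whose center is nearest - the
# hexagonal Voronoi assignment, with boundary ties resolved deterministically
# by the rounding rule.

#' Build a hexagonal grid over an embedding
#'
#' The hexagon radius is chosen so that the number of lattice positions of a
#' flat-top tiling covering the (padded) bounding box is as close as possible
#' to \code{target_bins}; the bounding box is padded by one radius so boundary
#' points fall strictly inside a hexagon. Only the sizing rule depends on the
#' bounding box; assignment itself works on the infinite lattice.
#'
#' @param emb an \code{embedding}.
#' @param target_bins approximate number of tiling positions (default 10000).
#' @return An object of class \code{hex_grid} with the radius, origin,
#'   per-cell axial assignment, and the realized tiling size
#'   (\code{n_positions}).
#' @export
build_hexgrid <- function(emb, target_bins = 10000) {
  stopifnot(inherits(emb, "embedding"))
  if (!is.numeric(target_bins) || length(target_bins) != 1L || target_bins < 1)
    stop("target_bins must be a positive integer")
  xy <- emb$coords
  w <- diff(range(xy[, 1])); h <- diff(range(xy[, 2]))
  if (w == 0 && h == 0) {
    warning("all points identical; degenerate single-bin grid")
    radius <- 1
  } else {
    # positions tile at horizontal pitch 1.5 R and vertical pitch sqrt(3) R,
    # i.e. one position per 1.5*sqrt(3) R^2; solve for R over the padded box
    # (padding depends on R, so refine the fixpoint a few times)
    w <- max(w, 1e-8); h <- max(h, 1e-8)
    radius <- sqrt((w * h) / (1.5 * sqrt(3) * target_bins))
    for (it in 1:3)
      radius <- sqrt(((w + 2 * radius) * (h + 2 * radius)) /
                       (1.5 * sqrt(3) * target_bins))
  }
  origin <- c(min(xy[, 1]), min(xy[, 2]))
  ax <- hex_axial(xy, origin, radius)
  grid <- structure(list(hex_radius = radius, origin = origin,
                         orientation = "flat-top",
                         cell_q = ax[, 1], cell_r = ax[, 2],
                         bbox = c(xmin = min(xy[, 1]), xmax = max(xy[, 1]),
                                  ymin = min(xy[, 2]), ymax = max(xy[, 2]))),
                    class = "hex_grid")
  grid$n_positions <- hex_count_positions(grid)
  grid
}

# fractional axial coords -> cube rounding (nearest hex center)
hex_axial <- function(xy, origin, radius) {
  px <- (xy[, 1] - origin[1]) / radius
  py <- (xy[, 2] - origin[2]) / radius
  qf <- (2 / 3) * px
  rf <- (-1 / 3) * px + (sqrt(3) / 3) * py
  cube_round(qf, rf)
}

cube_round <- function(qf, rf) {
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  cbind(q = as.integer(rx), r = as.integer(rz))
}

#' Centers of hexagonal bins
#' @param grid a \code{hex_grid}.
#' @param q,r integer axial coordinates.
#' @return Two-column matrix of center coordinates.
#' @export
hex_center <- function(grid, q, r) {
  cbind(x = grid$origin[1] + 1.5 * grid$hex_radius * q,
        y = grid$origin[2] + sqrt(3) * grid$hex_radius * (r + q / 2))
}

# number of lattice positions whose center lies in the bbox padded by R
hex_count_positions <- function(grid) {
  R <- grid$hex_radius; b <- grid$bbox
  xlo <- b["xmin"] - R; xhi <- b["xmax"] + R
  ylo <- b["ymin"] - R; yhi <- b["ymax"] + R
  qs <- seq(ceiling((xlo - grid$origin[1]) / (1.5 * R)),
            floor((xhi - grid$origin[1]) / (1.5 * R)))
  total <- 0L
  for (q in qs) {
    # center y = origin_y + sqrt(3) R (r + q/2) in [ylo, yhi]
    lo <- ceiling((ylo - grid$origin[2]) / (sqrt(3) * R) - q / 2)
    hi <- floor((yhi - grid$origin[2]) / (sqrt(3) * R) - q / 2)
    if (hi >= lo) total <- total + (hi - lo + 1L)
  }
  as.integer(total)
}

#' @export
print.hex_grid <- function(x, ...) {
  cat("<hex_grid> flat-top, radius ", signif(x$hex_radius, 4), ", ",
      x$n_positions, " tiling positions, ",
      length(unique(paste(x$cell_q, x$cell_r))), " occupied\n", sep = "")
  invisible(x)
}

#' Collapse a grid assignment into a bin graph
#'
#' Keeps only non-empty bins (bins without cells are dropped), computes each
#' bin's expression as the unweighted arithmetic mean of its member cells'
#' marker vectors, and records bin centers and sizes. Bin ids are assigned in
#' sorted (q, r) order, so they are deterministic.
#'
#' @param grid a \code{hex_grid} whose assignment covers all cells of
#'   \code{table}.
#' @param table the pooled \code{cell_table} the grid was built from.
#' @return An object of class \code{bin_graph} (edges empty until
#'   \code{\link{build_adjacency}}).
#' @export
compute_bin_graph <- function(grid, table) {
  stopifnot(inherits(grid, "hex_grid"), inherits(table, "cell_table"))
  if (length(grid$cell_q) != n_cells(table))
    stop("grid assignment does not cover the cell table")
  key <- paste(grid$cell_q, grid$cell_r, sep = ",")
  ord_keys <- unique(key)
  qr <- do.call(rbind, strsplit(ord_keys, ",", fixed = TRUE))
  qr <- cbind(as.integer(qr[, 1]), as.integer(qr[, 2]))
  o <- order(qr[, 1], qr[, 2])
  qr <- qr[o, , drop = FALSE]
  ord_keys <- ord_keys[o]
  bin_of_cell <- match(key, ord_keys)
  counts <- tabulate(bin_of_cell, nbins = length(ord_keys))
  sums <- rowsum(table$values, bin_of_cell, reorder = TRUE)
  expr <- sums / counts
  centers <- hex_center(grid, qr[, 1], qr[, 2])
  structure(list(
    bins = data.frame(bin_id = seq_along(ord_keys), q = qr[, 1], r = qr[, 2],
                      cx = centers[, 1], cy = centers[, 2], n_cells = counts),
    expression = expr,
    cell_bin = bin_of_cell,
    sample_id = table$sample_id,
    hex_radius = grid$hex_radius,
    edges = data.frame(a = integer(), b = integer(), kind = character())),
    class = "bin_graph")
}

#' @export
print.bin_graph <- function(x, ...) {
  cat("<bin_graph> ", nrow(x$bins), " non-empty bins, ",
      sum(x$bins$n_cells), " cells, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Build the bin adjacency graph
#'
#' Two non-empty bins are adjacent if their hexagons share a border (lattice
#' neighbors). A non-empty bin with no non-empty border neighbor gains exactly
#' one nearest-fallback edge to the closest non-empty bin by center distance
#' (ties broken by lowest bin id), so no bin is isolated.
#'
#' @param graph a \code{bin_graph} from \code{\link{compute_bin_graph}}.
#' @return The \code{bin_graph} with its undirected edge list filled in
#'   (columns \code{a < b}, \code{kind} in \code{border},
#'   \code{nearest-fallback}).
#' @export
build_adjacency <- function(graph) {
  stopifnot(inherits(graph, "bin_graph"))
  b <- graph$bins
  n <- nrow(b)
  if (n <= 1L) {
    if (n == 1L) warning("single-bin graph has no edges")
    graph$edges <- data.frame(a = integer(), b = integer(),
                              kind = character())
    return(graph)
  }
  key <- paste(b$q, b$r, sep = ",")
  idx <- stats::setNames(seq_len(n), key)
  # six flat-top axial neighbor offsets
  off <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1), c(-1, 1))
  ea <- integer(0); eb <- integer(0)
  for (k in seq_len(nrow(off))) {
    nb_key <- paste(b$q + off[k, 1], b$r + off[k, 2], sep = ",")
    j <- idx[nb_key]
    hit <- !is.na(j)
    ea <- c(ea, which(hit)); eb <- c(eb, unname(j[hit]))
  }
  keep <- ea < eb
  edges <- unique(data.frame(a = ea[keep], b = eb[keep],
                             kind = rep("border", sum(keep)),
                             stringsAsFactors = FALSE))
  deg <- tabulate(c(edges$a, edges$b), nbins = n)
  for (i in which(deg == 0L)) {
    d2 <- (b$cx - b$cx[i])^2 + (b$cy - b$cy[i])^2
    d2[i] <- Inf
    j <- which(d2 == min(d2))[1L]  # tie -> lowest bin id
    edges <- rbind(edges, data.frame(a = min(i, j), b = max(i, j),
                                     kind = "nearest-fallback",
                                     stringsAsFactors = FALSE))
  }
  edges <- unique(edges)
  graph$edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(graph$edges) <- NULL
  graph
}

#' Export a bin graph as two TSVs
#'
#' @param graph a \code{bin_graph}.
#' @param bins_path,edges_path destination TSVs for the bin table (id,
#'   center, size, expression columns) and the edge list.
#' @return Invisibly, the two paths.
#' @export
write_bin_graph <- function(graph, bins_path, edges_path) {
  stopifnot(inherits(graph, "bin_graph"))
  df <- cbind(graph$bins, as.data.frame(graph$expression))
  utils::write.table(df, bins_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(graph$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bins_path, edges_path))
}
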