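#' Embed pooled cells in 2-D with Barnes-Hut t-SNE
#'
#' Thin wrapper around \code{Rtsne::Rtsne} run single-threaded on the raw
#' (asinh-transformed) marker matrix, recording the parameters used. The
#' embedding is pluggable downstream: any (cells x 2) coordinate matrix can be
#' wrapped with \code{\link{embedding}} or imported with
#' \code{\link{read_embedding}}, since later stages depend only on
#' coordinates.
#'
#' @param table a transformed \code{cell_table}.
#' @param perplexity t-SNE perplexity (default 60).
#' @param theta Barnes-Hut accuracy trade-off (default 0.5; 0 = exact).
#' @param iterations number of gradient iterations (default 2000).
#' @param seed integer seed; the same seed reproduces the embedding exactly.
#' @return An \code{embedding} object: \code{coords} (cells x 2) and
#'   \code{params}.
#' @export
run_tsne <- function(table, perplexity = 60, theta = 0.5, iterations = 2000,
                     seed = 1L) {
  stopifnot(inherits(table, "cell_table"))
  if (!table$transformed)
    warning("embedding untransformed intensities; asinh_transform first?")
  n <- n_cells(table)
  if (n - 1 < 3 * perplexity)
    stop("too few cells (", n, ") for perplexity ", perplexity,
         "; need > 3*perplexity + 1 cells or a smaller perplexity")
  fit <- with_seed(seed, Rtsne::Rtsne(
    table$values, dims = 2L, perplexity = perplexity, theta = theta,
    max_iter = as.integer(iterations), pca = FALSE, check_duplicates = FALSE,
    num_threads = 1L, verbose = FALSE))
  embedding(fit$Y, params = list(perplexity = perplexity, theta = theta,
                                 iterations = as.integer(iterations),
                                 seed = as.integer(seed)))
}

#' Wrap a coordinate matrix as an embedding
#'
#' @param coords numeric matrix with two columns (x, y), one row per cell.
#' @param params optional named list of parameters to record.
#' @return An object of class \code{embedding}.
#' @export
embedding <- function(coords, params = list()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L) stop("embedding coords must have exactly 2 columns")
  if (any(!is.finite(coords))) stop("embedding coords must be finite")
  colnames(coords) <- c("x", "y")
  structure(list(coords = coords, params = params), class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat("<embedding> ", nrow(x$coords), " cells",
      if (length(x$params)) paste0(" (",
        paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
        ")"), "\n", sep = "")
  invisible(x)
}

#' Read / write an embedding as TSV (cell_id, x, y)
#' @param path TSV file.
#' @return \code{read_embedding}: an \code{embedding};
#'   \code{write_embedding}: \code{path}, invisibly.
#' @export
read_embedding <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("x", "y") %in% names(df)))
    stop("embedding file must have columns x and y")
  embedding(cbind(df$x, df$y))
}

#' @rdname read_embedding
#' @param emb an \code{embedding}.
#' @export
write_embedding <- function(emb, path) {
  stopifnot(inherits(emb, "embedding"))
  utils::write.table(
    data.frame(cell_id = seq_len(nrow(emb$coords)),
               x = emb$coords[, 1], y = emb$coords[, 2]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
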