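#' Per-sample cell-by-marker table
#'
#' The basic container for single-cell intensities: a numeric matrix with one
#' row per cell and one named column per marker, a per-cell sample identifier,
#' and a flag recording whether the asinh transform has been applied.
#'
#' @param values numeric matrix (cells x markers) with column names.
#' @param sample_id character vector of per-cell sample identifiers, recycled
#'   from a scalar.
#' @param transformed logical flag; \code{FALSE} for raw intensities.
#' @return An object of class \code{cell_table}.
#' @export
cell_table <- function(values, sample_id, transformed = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)) || any(!nzchar(colnames(values))))
    stop("values must have marker names as column names")
  if (anyDuplicated(colnames(values))) stop("duplicated marker names")
  if (any(!is.finite(values))) stop("values must be finite with no missing entries")
  if (length(sample_id) == 1L) sample_id <- rep(sample_id, nrow(values))
  if (length(sample_id) != nrow(values))
    stop("sample_id length does not match cell count")
  structure(list(values = values,
                 sample_id = as.character(sample_id),
                 transformed = isTRUE(transformed)),
            class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat("<cell_table> ", nrow(x$values), " cells x ", ncol(x$values),
      " markers (", length(unique(x$sample_id)), " sample",
      if (length(unique(x$sample_id)) != 1) "s", "; ",
      if (x$transformed) "asinh-transformed" else "raw", ")\n", sep = "")
  invisible(x)
}

#' Number of cells in a cell table
#' @param table a \code{cell_table}.
#' @return Integer cell count.
#' @export
n_cells <- function(table) {
  stopifnot(inherits(table, "cell_table"))
  nrow(table$values)
}

#' Read single-cell data from FCS or delimited text
#'
#' Tabular input is delimited text (TSV or CSV, sniffed from the extension)
#' with one header row of marker names; a column named \code{sample_id}, if
#' present, supplies per-cell sample identifiers. FCS input must be FCS 3.0 or
#' 3.1 with float (\code{$DATATYPE F}) list-mode data, as written by
#' \code{\link{write_cells}}.
#'
#' @param path file to read.
#' @param format \code{"auto"} (by extension), \code{"fcs"} or
#'   \code{"tabular"}.
#' @param panel optional \code{marker_panel}; if given, all panel markers must
#'   be present and the columns are checked (but not subset).
#' @param sample_id identifier used when the file carries none (default: the
#'   file name without extension).
#' @return A \code{cell_table} with \code{transformed = FALSE}.
#' @export
read_cells <- function(path, format = c("auto", "fcs", "tabular"),
                       panel = NULL, sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "tabular"
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  tab <- if (format == "fcs") {
    read_fcs(path, sample_id = sample_id)
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- tryCatch(utils::read.table(path, header = TRUE, sep = sep,
                                     check.names = FALSE,
                                     stringsAsFactors = FALSE),
                   error = function(e) stop("cannot parse '", path, "': ",
                                            conditionMessage(e)))
    sid <- if ("sample_id" %in% names(df)) {
      s <- as.character(df[["sample_id"]])
      df[["sample_id"]] <- NULL
      s
    } else sample_id
    cell_table(as.matrix(df), sid, transformed = FALSE)
  }
  if (!is.null(panel)) {
    absent <- setdiff(panel$markers, colnames(tab$values))
    if (length(absent))
      stop("file '", path, "' is missing panel markers: ",
           paste(absent, collapse = ", "))
  }
  tab
}

#' Write single-cell data to FCS or delimited text
#'
#' @param table a \code{cell_table}.
#' @param path destination file.
#' @param format \code{"auto"}, \code{"fcs"} or \code{"tabular"}.
#' @return \code{path}, invisibly.
#' @export
write_cells <- function(table, path, format = c("auto", "fcs", "tabular")) {
  stopifnot(inherits(table, "cell_table"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "tabular"
  if (format == "fcs") {
    write_fcs(table, path)
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- data.frame(sample_id = table$sample_id, table$values,
                     check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Apply the asinh transform
#'
#' Replaces every intensity x with asinh(x / cofactor), the standard
#' variance-stabilizing transform for mass cytometry.
#'
#' @param table an untransformed \code{cell_table}.
#' @param panel a \code{marker_panel} supplying the cofactor, or a single
#'   positive cofactor.
#' @return The transformed \code{cell_table}.
#' @export
asinh_transform <- function(table, panel = 5) {
  stopifnot(inherits(table, "cell_table"))
  if (table$transformed)
    stop("cell_table is already asinh-transformed; refusing to apply twice")
  cofactor <- if (inherits(panel, "marker_panel")) panel$cofactor else panel
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0)
    stop("cofactor must be a single positive number")
  table$values <- asinh(table$values / cofactor)
  table$transformed <- TRUE
  table
}

#' Sample quality-control decision
#'
#' Samples with fewer than \code{min_cells} (post-gating) cells are discarded,
#' strictly-less-than: a sample at exactly the threshold is kept.
#'
#' @param table a \code{cell_table}.
#' @param min_cells integer threshold (default 3000).
#' @return A list with \code{keep} (logical), \code{n_cells} and
#'   \code{min_cells}.
#' @export
qc_filter <- function(table, min_cells = 3000) {
  stopifnot(inherits(table, "cell_table"))
  n <- n_cells(table)
  list(keep = n >= min_cells, n_cells = n, min_cells = as.integer(min_cells))
}

#' Downsample cells uniformly without replacement
#'
#' @param table a \code{cell_table}.
#' @param n number of cells to draw (default 6000). If the table holds fewer
#'   than \code{n} cells all cells are retained with a warning.
#' @param seed integer seed making the draw reproducible.
#' @return A \code{cell_table} with at most \code{n} cells, in original order.
#' @export
downsample <- function(table, n = 6000, seed = 1L) {
  stopifnot(inherits(table, "cell_table"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive integer")
  total <- n_cells(table)
  if (total <= n) {
    if (total < n)
      warning("only ", total, " cells available; requested ", n,
              " - keeping all cells")
    return(table)
  }
  idx <- sort(with_seed(seed, sample.int(total, n)))
  table$values <- table$values[idx, , drop = FALSE]
  table$sample_id <- table$sample_id[idx]
  table
}

#' Pool sample cells with an optional reference draw
#'
#' Concatenates the per-sample tables and, when a reference pool (e.g. healthy
#' adult controls) is supplied, appends \code{n_reference} cells drawn
#' uniformly from it so that rare, age-depleted populations still seed bins.
#'
#' @param samples list of \code{cell_table}s sharing markers and transform
#'   state.
#' @param reference optional \code{cell_table} to draw reference cells from.
#' @param n_reference number of reference cells to draw (default 30000).
#' @param seed integer seed for the reference draw.
#' @return One pooled \code{cell_table}; per-cell \code{sample_id} is kept.
#' @export
pool_cells <- function(samples, reference = NULL, n_reference = 30000,
                       seed = 1L) {
  if (inherits(samples, "cell_table")) samples <- list(samples)
  stopifnot(length(samples) >= 1L, all(vapply(samples, inherits, TRUE,
                                              "cell_table")))
  ref_markers <- colnames(samples[[1L]]$values)
  ref_state <- samples[[1L]]$transformed
  all_tabs <- samples
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "cell_table"))
    all_tabs <- c(samples, list(suppressWarnings(
      downsample(reference, n_reference, seed = seed))))
  }
  for (t in all_tabs) {
    if (!identical(colnames(t$values), ref_markers))
      stop("cell tables do not share an identical marker panel")
    if (!identical(t$transformed, ref_state))
      stop("cell tables mix transformed and untransformed values")
  }
  cell_table(do.call(rbind, lapply(all_tabs, `[[`, "values")),
             unlist(lapply(all_tabs, `[[`, "sample_id"), use.names = FALSE),
             transformed = ref_state)
}

#' Restrict a cell table to a marker subset
#'
#' @param table a \code{cell_table}.
#' @param panel the \code{marker_panel} the table conforms to.
#' @param subset marker names to keep, in the desired order; must all belong
#'   to the panel.
#' @return A list with the restricted \code{table} and the matching restricted
#'   \code{panel} (weights subset alongside the columns).
#' @export
select_markers <- function(table, panel, subset) {
  stopifnot(inherits(table, "cell_table"), inherits(panel, "marker_panel"))
  unknown <- setdiff(subset, panel$markers)
  if (length(unknown))
    stop("unknown markers: ", paste(unknown, collapse = ", "))
  absent <- setdiff(subset, colnames(table$values))
  if (length(absent))
    stop("markers absent from table: ", paste(absent, collapse = ", "))
  table$values <- table$values[, subset, drop = FALSE]
  list(table = table, panel = subset_panel(panel, subset))
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
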