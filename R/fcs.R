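# Minimal FCS 3.1 list-mode I/O (float data, little-endian).
# Covers the subset of the standard this package writes and reads back:
# one dataset, $DATATYPE F, $MODE L, $BYTEORD 1,2,3,4, 32-bit parameters.

#' Read an FCS 3.0/3.1 file
#'
#' @param path FCS file with float list-mode data.
#' @param sample_id identifier to attach to all cells.
#' @return A \code{cell_table} with \code{transformed = FALSE}.
#' @export
read_fcs <- function(path, sample_id = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58L))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("cannot read '", path, "': not an FCS 3.0/3.1 file")
  off <- suppressWarnings(as.integer(substring(
    header, seq(11, 51, by = 8), seq(18, 58, by = 8))))
  if (any(is.na(off[1:4]))) stop("cannot read '", path, "': bad FCS header offsets")
  text_start <- off[1]; text_end <- off[2]
  seek(con, text_start)
  text <- rawToChar(readBin(con, "raw", text_end - text_start + 1L))
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        toupper(trimws(parts[seq(1, length(parts), 2)])))
  need <- c("$TOT", "$PAR", "$DATATYPE", "$BYTEORD")
  if (any(!need %in% names(kw)))
    stop("FCS text segment missing keywords: ",
         paste(setdiff(need, names(kw)), collapse = ", "))
  if (toupper(kw["$DATATYPE"]) != "F")
    stop("unsupported $DATATYPE '", kw["$DATATYPE"], "' (only F supported)")
  endian <- if (kw["$BYTEORD"] %in% c("1,2,3,4")) "little" else "big"
  tot <- as.integer(kw["$TOT"]); par <- as.integer(kw["$PAR"])
  data_start <- off[3]
  if (data_start == 0 && "$BEGINDATA" %in% names(kw))
    data_start <- as.integer(kw["$BEGINDATA"])
  labels <- vapply(seq_len(par), function(i) {
    key <- paste0("$P", i, "N")
    if (key %in% names(kw)) kw[[key]] else paste0("P", i)
  }, character(1))
  seek(con, data_start)
  vals <- readBin(con, "numeric", n = tot * par, size = 4L, endian = endian)
  m <- matrix(vals, nrow = tot, ncol = par, byrow = TRUE,
              dimnames = list(NULL, labels))
  cell_table(m, sample_id, transformed = FALSE)
}

#' Write a cell table as FCS 3.1
#'
#' Values are stored as 32-bit floats, so a write/read round trip preserves
#' intensities to single precision only.
#'
#' @param table a \code{cell_table}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
write_fcs <- function(table, path) {
  stopifnot(inherits(table, "cell_table"))
  m <- table$values
  tot <- nrow(m); par <- ncol(m)
  delim <- "/"
  kv <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$NEXTDATA", "0", "$TOT", format(tot, scientific = FALSE),
          "$PAR", format(par, scientific = FALSE),
          "$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0")
  for (i in seq_len(par)) {
    rng <- max(1, ceiling(max(abs(m[, i]), 1)))
    kv <- c(kv, paste0("$P", i, "N"), colnames(m)[i],
            paste0("$P", i, "B"), "32", paste0("$P", i, "E"), "0,0",
            paste0("$P", i, "R"), format(rng, scientific = FALSE))
  }
  # begin/end data offsets depend on the text length; pad them to fixed width
  data_len <- tot * par * 4L
  fmt10 <- function(x) formatC(x, width = 10, flag = "0", format = "d")
  build_text <- function(b, e) {
    paste0(delim, paste(c(kv, "$BEGINDATA", fmt10(b), "$ENDDATA", fmt10(e)),
                        collapse = delim), delim)
  }
  probe <- build_text(0, 0)
  text_start <- 58L
  text_end <- text_start + nchar(probe, type = "bytes") - 1L
  data_start <- text_end + 1L
  data_end <- data_start + data_len - 1L
  text <- build_text(data_start, data_end)
  hdr_off <- function(x) formatC(x, width = 8, format = "d")
  header <- paste0("FCS3.1    ", hdr_off(text_start), hdr_off(text_end),
                   hdr_off(data_start), hdr_off(data_end),
                   hdr_off(0), hdr_off(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  invisible(path)
}
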