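# Cleavage-site tables: one row per observed proteolytic event, holding the
# enzyme label, the parent protein identifier, the 1-based index of the P1
# residue in the parent, and the fixed-length residue window centred on the
# scissile bond.

new_cleavage_table <- function(df, window_width) {
  structure(df, window_width = as.integer(window_width),
            class = c("cleavage_table", "data.frame"))
}

validate_windows <- function(windows, window_width, what) {
  bad_len <- which(nchar(windows) != 2L * window_width)
  if (length(bad_len) > 0L) {
    stop("window of wrong length (expected ", 2L * window_width, ") in ",
         what[bad_len[1]], call. = FALSE)
  }
  ok <- grepl(paste0("^[", paste(WINDOW_ALPHABET, collapse = ""), "]+$"),
              windows)
  if (!all(ok)) {
    stop("illegal residue character in ", what[which(!ok)[1]],
         " (allowed: 20 standard amino acids and 'X')", call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a cleavage-site table from vectors
#'
#' @param enzyme enzyme label (recycled if length 1); must be nonempty.
#' @param protein_id parent protein identifiers.
#' @param p1_index 1-based index of the P1 residue in the parent protein.
#' @param window residue windows of length `2 * window_width` over the
#'   alphabet of 20 standard amino acids plus `'X'`.
#' @param window_width half-width W of the windows.
#' @return A `cleavage_table` (a data.frame with columns `enzyme`,
#'   `protein_id`, `p1_index`, `window` and a `window_width` attribute).
#' @export
cleavage_table <- function(enzyme, protein_id, p1_index, window,
                           window_width = 15) {
  n <- length(window)
  if (length(enzyme) == 1L) enzyme <- rep(enzyme, n)
  stopifnot(length(enzyme) == n, length(protein_id) == n,
            length(p1_index) == n)
  if (any(!nzchar(enzyme))) stop("enzyme labels must be nonempty")
  if (any(p1_index < 1 | p1_index != round(p1_index))) {
    stop("p1_index must be a positive integer")
  }
  validate_windows(window, window_width,
                   paste0("record ", seq_len(n), " (", protein_id, ")"))
  new_cleavage_table(
    data.frame(enzyme = as.character(enzyme),
               protein_id = as.character(protein_id),
               p1_index = as.integer(p1_index),
               window = as.character(window)),
    window_width)
}

#' Read a cleavage-site table from TSV
#'
#' The file is UTF-8, tab-separated, with `'#'` comment lines ignored and a
#' header naming (at least) the columns `enzyme`, `protein_id`, `p1_index`
#' and `window`.  Every record is validated against the window invariants;
#' malformed rows are reported with their line number.
#'
#' @param path file path.
#' @param window_width half-width W of the windows (default 15, i.e. windows
#'   span P15-P15').
#' @param quiet suppress the parsed-row count message.
#' @return A `cleavage_table`, rows in file order.
#' @export
read_cleavage_table <- function(path, window_width = 15, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 1L) stop("no header line in ", path, call. = FALSE)

  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  required <- c("enzyme", "protein_id", "p1_index", "window")
  missing <- setdiff(required, header)
  if (length(missing) > 0L) {
    stop("header of ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  body <- lines[-1]
  body_lineno <- lineno[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < length(header))
  if (length(bad) > 0L) {
    stop("malformed row at line ", body_lineno[bad[1]], " of ", path,
         ": expected ", length(header), " fields, found ", nf[bad[1]],
         call. = FALSE)
  }
  col <- function(name) {
    i <- match(name, header)
    vapply(fields, `[[`, character(1), i)
  }
  p1 <- suppressWarnings(as.integer(col("p1_index")))
  bad_p1 <- which(is.na(p1) | p1 < 1L)
  if (length(bad_p1) > 0L) {
    stop("invalid p1_index at line ", body_lineno[bad_p1[1]], " of ", path,
         call. = FALSE)
  }
  enzyme <- col("enzyme")
  if (any(!nzchar(enzyme))) {
    stop("empty enzyme label at line ",
         body_lineno[which(!nzchar(enzyme))[1]], " of ", path, call. = FALSE)
  }
  windows <- col("window")
  validate_windows(windows, window_width,
                   paste0("record at line ", body_lineno, " (",
                          col("protein_id"), ")"))
  tab <- new_cleavage_table(
    data.frame(enzyme = enzyme, protein_id = col("protein_id"),
               p1_index = p1, window = windows),
    window_width)
  if (!quiet) message("parsed ", nrow(tab), " cleavage records from ", path)
  tab
}

#' Write a cleavage-site table as TSV
#'
#' Inverse of [read_cleavage_table()]: write-then-read round-trips any table.
#'
#' @param records a `cleavage_table`.
#' @param path output file path.
#' @export
write_cleavage_table <- function(records, path) {
  stopifnot(inherits(records, "cleavage_table"))
  utils::write.table(
    records[, c("enzyme", "protein_id", "p1_index", "window")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Drop records whose selected span contains the terminus placeholder 'X'
#'
#' Retained records are the default elsewhere; this filter supports
#' sensitivity checks.
#'
#' @param records a `cleavage_table`.
#' @param span a [subsite_span()].
#' @return The filtered `cleavage_table`.
#' @export
drop_x_records <- function(records, span) {
  stopifnot(inherits(records, "cleavage_table"))
  sub <- extract_subsites(records, span)
  keep <- !grepl("X", sub, fixed = TRUE)
  new_cleavage_table(records[keep, , drop = FALSE],
                     attr(records, "window_width"))
}

#' @export
print.cleavage_table <- function(x, ...) {
  cat(sprintf("cleavage_table: %d records, window half-width %d, enzymes: %s\n",
              nrow(x), attr(x, "window_width"),
              paste(unique(x$enzyme), collapse = ", ")))
  NextMethod()
}
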