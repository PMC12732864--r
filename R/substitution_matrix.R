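# NCBI-format substitution matrix files (as distributed with BLAST):
# '#'-prefixed comments, a header row of residue symbols, then one scored row
# per symbol.

#' Load a substitution matrix in NCBI text format
#'
#' Parses a BLOSUM/PAM-style matrix file, checks that every header symbol has
#' a row, that the score table is symmetric, and that an `'X'` row/column is
#' present (needed to score terminus placeholders).
#'
#' @param path file path; [blosum62_path()] gives the packaged BLOSUM62.
#' @return A `substitution_matrix`: an integer matrix with the file's symbols
#'   as dimnames.
#' @examples
#' m <- load_substitution_matrix(blosum62_path())
#' m["A", "A"]  # 4
#' @export
load_substitution_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a matrix file: ", path, call. = FALSE)
  symbols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- length(symbols)
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  row_names <- vapply(rows, `[[`, character(1), 1L)
  missing <- setdiff(symbols, row_names)
  if (length(missing) > 0L) {
    stop("missing matrix row(s) for symbol(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(lengths(rows) != n + 1L)
  if (length(bad) > 0L) {
    stop("matrix row for '", row_names[bad[1]], "' has ",
         lengths(rows)[bad[1]] - 1L, " scores; expected ", n, call. = FALSE)
  }
  scores <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  if (anyNA(scores)) stop("non-numeric score in ", path, call. = FALSE)
  m <- scores[match(symbols, row_names), , drop = FALSE]
  dimnames(m) <- list(symbols, symbols)
  asym <- which(m != t(m), arr.ind = TRUE)
  if (nrow(asym) > 0L) {
    i <- asym[1, ]
    stop("asymmetric substitution matrix: score(", symbols[i[1]], ",",
         symbols[i[2]], ") = ", m[i[1], i[2]], " but score(", symbols[i[2]],
         ",", symbols[i[1]], ") = ", m[i[2], i[1]], call. = FALSE)
  }
  if (!all(c(STANDARD_AA, "X") %in% symbols)) {
    stop("matrix must cover the 20 standard amino acids and 'X'",
         call. = FALSE)
  }
  structure(m, class = c("substitution_matrix", "matrix", "array"))
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat(sprintf("substitution_matrix over %d symbols: %s\n", ncol(x),
              paste(colnames(x), collapse = " ")))
  print(unclass(x), ...)
  invisible(x)
}
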