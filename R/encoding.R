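# BLOSUM62 featurisation: each residue of a subsite string becomes its full
# 20-score substitution row, so a span of length L encodes as 20*L numeric
# features.  The pairwise score of any two residues at a position is then one
# coordinate of the row, which is what makes this the parameter-free reading
# of substitution-score encoding.

#' Encode a residue string as BLOSUM substitution-row features
#'
#' @param residues residue string (e.g. a subsite span extract); `'X'`
#'   encodes through the matrix's X row.
#' @param matrix a [load_substitution_matrix()] result.
#' @return Numeric vector of length `20 * nchar(residues)`; block *i* holds
#'   the matrix row of residue *i* against the 20 standard amino acids in
#'   fixed (NCBI) order.
#' @examples
#' m <- load_substitution_matrix(blosum62_path())
#' encode_window("A", m)[1]  # score(A, A) = 4
#' @export
encode_window <- function(residues, matrix) {
  stopifnot(is.character(residues), length(residues) == 1L)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  unknown <- which(!chars %in% rownames(matrix))
  if (length(unknown) > 0L) {
    stop("unknown residue '", chars[unknown[1]], "' at position ",
         unknown[1], call. = FALSE)
  }
  as.vector(t(matrix[chars, STANDARD_AA, drop = FALSE]))
}

encode_window_matrix <- function(subs, matrix) {
  L <- unique(nchar(subs))
  stopifnot(length(L) == 1L)
  feats <- t(vapply(subs, encode_window, numeric(20L * L), matrix = matrix,
                    USE.NAMES = FALSE))
  feats
}

#' Assemble a labeled two-class BLOSUM-encoded dataset
#'
#' Records of `datasetA` are the positive class (label 1), records of
#' `datasetB` the negative class (label 0); row order follows input order
#' (positives first).
#'
#' @param datasetA,datasetB nonempty `cleavage_table`s.
#' @param span a [subsite_span()].
#' @param matrix a substitution matrix.
#' @param drop_x drop records whose span residues contain `'X'` (default
#'   keeps them; X scores come from the matrix's X row).
#' @return An `encoded_dataset`: list with `features`
#'   (`(nA + nB) x (20 * L)` numeric matrix, columns named
#'   `<subsite>.<residue>`), `labels` (1/0 vector), `provenance` (enzyme
#'   label per class), `span`, and `meta` (per-row enzyme/protein_id/window).
#' @export
encode_pair <- function(datasetA, datasetB, span, matrix, drop_x = FALSE) {
  stopifnot(inherits(datasetA, "cleavage_table"),
            inherits(datasetB, "cleavage_table"),
            nrow(datasetA) > 0, nrow(datasetB) > 0)
  if (drop_x) {
    datasetA <- drop_x_records(datasetA, span)
    datasetB <- drop_x_records(datasetB, span)
    if (nrow(datasetA) == 0 || nrow(datasetB) == 0) {
      stop("drop_x removed every record of one class", call. = FALSE)
    }
  }
  enzA <- unique(datasetA$enzyme)[1]
  enzB <- unique(datasetB$enzyme)[1]
  subs <- c(extract_subsites(datasetA, span), extract_subsites(datasetB, span))
  feats <- encode_window_matrix(subs, matrix)
  colnames(feats) <- as.vector(t(outer(span$labels, STANDARD_AA, paste,
                                       sep = ".")))
  meta <- rbind(
    data.frame(enzyme = datasetA$enzyme, protein_id = datasetA$protein_id,
               window = datasetA$window),
    data.frame(enzyme = datasetB$enzyme, protein_id = datasetB$protein_id,
               window = datasetB$window))
  structure(
    list(features = feats,
         labels = c(rep(1L, nrow(datasetA)), rep(0L, nrow(datasetB))),
         provenance = c(positive = enzA, negative = enzB),
         span = span, meta = meta),
    class = "encoded_dataset")
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat(sprintf(
    "encoded_dataset: %d x %d features, span %s-%s, %d positive (%s), %d negative (%s)\n",
    nrow(x$features), ncol(x$features), x$span$start, x$span$end,
    sum(x$labels == 1), x$provenance[["positive"]],
    sum(x$labels == 0), x$provenance[["negative"]]))
  invisible(x)
}

#' Write an encoded feature matrix as TSV for audit
#'
#' @param encoded an `encoded_dataset`.
#' @param path output file path.
#' @export
write_encoded_dataset <- function(encoded, path) {
  stopifnot(inherits(encoded, "encoded_dataset"))
  df <- data.frame(label = encoded$labels, enzyme = encoded$meta$enzyme,
                   encoded$features, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
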