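# Ward hierarchical clustering of BLOSUM-encoded cleavage windows from two
# enzymes, and extraction of the enzyme-specific (single-enzyme) clusters.
# Ward linkage requires Euclidean geometry, so the substitution matrix enters
# through the feature encoding, not through a custom dissimilarity.

#' Ward clustering of an encoded two-enzyme dataset
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances over the
#' substitution-score features) with the dendrogram cut at
#' `min(max_clusters, n_records)` clusters.  Deterministic given input order.
#'
#' @param encoded an [encode_pair()] result holding the combined records of
#'   the two enzymes.
#' @param max_clusters cut level cap (default 400).
#' @return A `cluster_result`: `assignments` (cluster id per record),
#'   `summaries` (data.frame: cluster_id, size, purity, majority enzyme and
#'   per-enzyme counts), `enzymes` (enzyme label per record), `meta`,
#'   `parameters`.
#' @export
ward_cluster <- function(encoded, max_clusters = 400) {
  stopifnot(inherits(encoded, "encoded_dataset"))
  if (max_clusters < 1) stop("max_clusters must be >= 1", call. = FALSE)
  x <- encoded$features
  if (!all(is.finite(x))) stop("features must be finite", call. = FALSE)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 records to cluster", call. = FALSE)
  enzymes <- encoded$meta$enzyme
  h <- stats::hclust(stats::dist(x), method = "ward.D2")
  k <- min(max_clusters, n)
  assignments <- stats::cutree(h, k = k)
  comp <- table(cluster = assignments, enzyme = enzymes)
  sizes <- rowSums(comp)
  purity <- apply(comp, 1, max) / sizes
  majority <- colnames(comp)[apply(comp, 1, which.max)]
  summaries <- data.frame(cluster_id = as.integer(rownames(comp)),
                          size = as.integer(sizes), purity = purity,
                          enzyme = majority)
  summaries <- cbind(summaries, as.data.frame.matrix(comp))
  rownames(summaries) <- NULL
  structure(list(assignments = assignments, summaries = summaries,
                 enzymes = enzymes, meta = encoded$meta,
                 parameters = list(max_clusters = max_clusters, k = k)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d records in %d clusters (cut at %d)\n",
              length(x$assignments), nrow(x$summaries), x$parameters$k))
  invisible(x)
}

#' Extract enzyme-specific clusters
#'
#' Returns the clusters whose members all carry one enzyme label (purity
#' 1.0) and that hold at least `min_size` records, sorted by size
#' descending.  Per-enzyme totals (number of specific clusters and of the
#' substrates they contain) are attached as the `totals` attribute.
#'
#' @param result a [ward_cluster()] result.
#' @param min_size minimum cluster size (default 2, excluding singletons).
#' @return Data.frame of cluster summaries (subset of `result$summaries`)
#'   with attribute `totals`.
#' @export
enzyme_specific_clusters <- function(result, min_size = 2) {
  stopifnot(inherits(result, "cluster_result"), min_size >= 1)
  s <- result$summaries
  spec <- s[s$purity == 1 & s$size >= min_size, , drop = FALSE]
  spec <- spec[order(-spec$size, spec$cluster_id), , drop = FALSE]
  rownames(spec) <- NULL
  totals <- if (nrow(spec) > 0) {
    agg <- stats::aggregate(spec$size, by = list(enzyme = spec$enzyme),
                            FUN = function(v) c(clusters = length(v),
                                                substrates = sum(v)))
    data.frame(enzyme = agg$enzyme, clusters = agg$x[, "clusters"],
               substrates = agg$x[, "substrates"])
  } else {
    data.frame(enzyme = character(0), clusters = integer(0),
               substrates = integer(0))
  }
  attr(spec, "totals") <- totals
  attr(spec, "min_size") <- min_size
  spec
}

#' Member record indices of one cluster
#'
#' @param result a `cluster_result`.
#' @param cluster_id cluster identifier.
#' @return Integer vector of record indices (row order of the encoded
#'   dataset).
#' @export
cluster_members <- function(result, cluster_id) {
  which(result$assignments == cluster_id)
}

#' Write a cluster report as TSV plus a summary JSON
#'
#' The TSV lists cluster_id, size, per-enzyme counts, purity and the member
#' protein ids and windows; the JSON mirrors the per-enzyme specific-cluster
#' totals.
#'
#' @param result a [ward_cluster()] result.
#' @param path output TSV path; the JSON is written next to it with
#'   extension `.json`.
#' @param min_size minimum size for the specific-cluster totals.
#' @export
write_cluster_report <- function(result, path, min_size = 2) {
  stopifnot(inherits(result, "cluster_result"))
  s <- result$summaries
  members <- vapply(s$cluster_id, function(id) {
    i <- cluster_members(result, id)
    paste(result$meta$protein_id[i], collapse = ",")
  }, character(1))
  windows <- vapply(s$cluster_id, function(id) {
    i <- cluster_members(result, id)
    paste(result$meta$window[i], collapse = ",")
  }, character(1))
  utils::write.table(cbind(s, members = members, windows = windows), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  spec <- enzyme_specific_clusters(result, min_size)
  payload <- list(
    n_records = length(result$assignments),
    n_clusters = nrow(s), cut = result$parameters$k,
    min_size = min_size,
    specific_clusters = nrow(spec),
    specific_substrates = sum(spec$size),
    per_enzyme = attr(spec, "totals"))
  jsonlite::write_json(payload, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
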