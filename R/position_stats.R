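# Per-subsite residue usage and the Anderson-Darling heterogeneity
# classification.  A subsite is "heterogeneous" when one or two residues
# dominate its usage; this shows up as a strongly right-skewed, non-normal
# vector of per-residue relative frequencies, which is what the
# Anderson-Darling normality test is applied to (see ad_sample_frequencies).

#' Per-subsite residue counts over a span
#'
#' @param records a `cleavage_table` (nonempty, uniform window width).
#' @param span a [subsite_span()].
#' @return A `residue_frequency_table`: list with `counts` (positions x
#'   21 residues, rows named by subsite label), `span`, and `n_records`.
#'   Each row sums to `n_records`.
#' @export
residue_frequencies <- function(records, span) {
  stopifnot(inherits(span, "subsite_span"))
  windows <- if (inherits(records, "cleavage_table")) records$window
             else as.character(records)
  if (length(windows) == 0L) stop("empty record list", call. = FALSE)
  sub <- extract_subsites(windows, span)
  chars <- matrix(unlist(strsplit(sub, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(sub), byrow = TRUE)
  counts <- t(apply(chars, 2, function(col) {
    table(factor(col, levels = WINDOW_ALPHABET))
  }))
  dimnames(counts) <- list(span$labels, WINDOW_ALPHABET)
  structure(list(counts = counts, span = span, n_records = length(sub)),
            class = "residue_frequency_table")
}

#' @export
print.residue_frequency_table <- function(x, ...) {
  cat(sprintf("residue_frequency_table: span %s-%s, %d records\n",
              x$span$start, x$span$end, x$n_records))
  print(x$counts, ...)
  invisible(x)
}

# Strategy point: the sample handed to the Anderson-Darling test for one
# subsite position.  Default: the 20 per-residue relative frequencies over
# the standard amino acids, 'X' excluded from numerator and denominator.
ad_sample_frequencies <- function(counts_row) {
  cnt <- counts_row[STANDARD_AA]
  tot <- sum(cnt)
  if (tot == 0) return(NULL)
  cnt / tot
}

classify_heterogeneity <- function(p) {
  ifelse(p <= 0.05, "heterogeneous", ifelse(p <= 0.08, "borderline", "normal"))
}

#' Anderson-Darling heterogeneity of subsite residue usage
#'
#' For each position of the span, the 20 per-residue relative frequencies are
#' tested for normality with the Anderson-Darling test
#' ([nortest::ad.test()]).  Positions are classified `heterogeneous`
#' (p <= 0.05), `borderline` (0.05 < p <= 0.08) or `normal` (p > 0.08).
#' A position whose counts sit entirely in one residue is flagged degenerate
#' and reported at the smallest p-value the test's tail approximation
#' supports.
#'
#' @param table a [residue_frequencies()] result.
#' @return A `heterogeneity_report`: data.frame with columns `position`,
#'   `ad_statistic`, `p_value`, `klass`, `degenerate`, rows in N-to-C order.
#' @export
anderson_darling_heterogeneity <- function(table) {
  stopifnot(inherits(table, "residue_frequency_table"))
  if (table$n_records < 20) {
    warning("only ", table$n_records,
            " records; heterogeneity p-values are unreliable below 20")
  }
  rows <- lapply(rownames(table$counts), function(pos) {
    freq <- ad_sample_frequencies(table$counts[pos, ])
    degenerate <- is.null(freq) || max(freq) == 1 || stats::sd(freq) == 0
    if (is.null(freq)) {
      return(data.frame(position = pos, ad_statistic = NA_real_,
                        p_value = NA_real_, klass = NA_character_,
                        degenerate = TRUE))
    }
    res <- tryCatch(nortest::ad.test(freq), error = function(e) NULL)
    if (is.null(res)) {
      stat <- Inf
      p <- .Machine$double.xmin
      degenerate <- TRUE
    } else {
      stat <- unname(res$statistic)
      p <- unname(res$p.value)
      if (!is.finite(p) || p <= 0) p <- .Machine$double.xmin
    }
    data.frame(position = pos, ad_statistic = stat, p_value = p,
               klass = classify_heterogeneity(p), degenerate = degenerate)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(report, span = table$span, n_records = table$n_records,
            class = c("heterogeneity_report", "data.frame"))
}

#' Select specific (heterogeneous) subsite positions
#'
#' @param report a [anderson_darling_heterogeneity()] report.
#' @param threshold p-value cutoff (default 0.05).
#' @return Character vector of subsite labels with `p <= threshold`, in
#'   N-to-C order.
#' @export
select_specific_positions <- function(report, threshold = 0.05) {
  stopifnot(inherits(report, "heterogeneity_report"), nrow(report) > 0)
  report$position[!is.na(report$p_value) & report$p_value <= threshold]
}

#' Write a heterogeneity report as TSV
#'
#' Columns position, statistic, p, klass mirror the three-level circle
#' encoding used to visualise subsite heterogeneity (red / light gray /
#' dark gray).
#'
#' @param report a `heterogeneity_report`.
#' @param path output file path.
#' @export
write_heterogeneity_report <- function(report, path) {
  stopifnot(inherits(report, "heterogeneity_report"))
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
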