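# Schechter-Berger subsite indexing.
#
# A window of width 2*W covers subsites P_W ... P1 | P1' ... P_W' with the
# scissile bond between window positions W and W+1.  Non-primed labels count
# away from the bond towards the N terminus, primed labels towards the C
# terminus.

#' Subsite labels of a cleavage window
#'
#' @param window_width half-width W of the window; the window has `2 * W`
#'   positions.
#' @return Character vector of length `2 * window_width`: `"P15" ... "P1"`,
#'   then `"P1'" ... "P15'"` (for the default `W = 15`).
#' @export
subsite_labels <- function(window_width = 15) {
  stopifnot(is.numeric(window_width), window_width >= 1)
  c(paste0("P", window_width:1), paste0("P", seq_len(window_width), "'"))
}

#' Parse a single subsite label
#'
#' Accepts `"P3"`, `"P4'"` and the shell-safe spelling `"P4p"` for primed
#' subsites.
#'
#' @param label a subsite label.
#' @return List with elements `k` (subsite number) and `primed` (logical).
#' @export
parse_subsite_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  m <- regmatches(label, regexec("^P([0-9]+)(['p]?)$", label))[[1]]
  if (length(m) == 0L) {
    stop("invalid subsite label: '", label,
         "' (expected e.g. 'P3', \"P4'\" or 'P4p')", call. = FALSE)
  }
  k <- as.integer(m[2])
  if (k < 1L) stop("invalid subsite label: '", label, "'", call. = FALSE)
  list(k = k, primed = nzchar(m[3]))
}

subsite_index <- function(label, window_width) {
  p <- parse_subsite_label(label)
  if (p$k > window_width) {
    stop("subsite ", label, " outside a window of half-width ",
         window_width, call. = FALSE)
  }
  if (p$primed) window_width + p$k else window_width - p$k + 1L
}

#' Define a contiguous span of subsites
#'
#' @param start,end subsite labels bounding the span, in N-to-C order
#'   (e.g. `"P3"`, `"P4'"`).
#' @param window_width half-width W of the windows the span will index.
#' @return An object of class `subsite_span`: the resolved window indices and
#'   their labels.
#' @examples
#' subsite_span("P3", "P4'")           # the 7 positions flanking the bond
#' subsite_span("P15", "P15'")         # the full default window
#' @export
subsite_span <- function(start, end, window_width = 15) {
  i <- subsite_index(start, window_width)
  j <- subsite_index(end, window_width)
  if (i > j) {
    stop("span ", start, "-", end, " is empty or reversed: labels must be ",
         "given in N-to-C order", call. = FALSE)
  }
  idx <- i:j
  structure(
    list(start = start, end = end, indices = idx,
         labels = subsite_labels(window_width)[idx],
         window_width = as.integer(window_width)),
    class = "subsite_span")
}

#' @export
length.subsite_span <- function(x) length(x$indices)

#' @export
print.subsite_span <- function(x, ...) {
  cat(sprintf("subsite span %s-%s (%d positions, window half-width %d)\n",
              x$start, x$end, length(x$indices), x$window_width))
  invisible(x)
}

#' Extract the residues of a subsite span from cleavage windows
#'
#' @param x a `cleavage_table`, or a character vector of windows.
#' @param span a [subsite_span()]; its `window_width` must match the windows.
#' @return Character vector of the span residues, N-to-C, one element per
#'   window.
#' @export
extract_subsites <- function(x, span) {
  stopifnot(inherits(span, "subsite_span"))
  windows <- if (inherits(x, "cleavage_table")) x$window else as.character(x)
  if (length(windows) == 0L) return(character(0))
  wlen <- unique(nchar(windows))
  if (length(wlen) != 1L || wlen != 2L * span$window_width) {
    stop("span of window half-width ", span$window_width,
         " cannot index windows of length ",
         paste(wlen, collapse = ", "), call. = FALSE)
  }
  substring(windows, min(span$indices), max(span$indices))
}
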