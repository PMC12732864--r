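# Pairwise discriminability of two cleavage-site datasets, measured as the
# AUC-ROC of an SVM trained to separate them.  AUC ~ 0.5 means the two
# specificities are indistinguishable; AUC -> 1 means fully distinct.
# Validation is Monte-Carlo ("jackknife") cross-validation: repeated
# stratified random hold-out of a fixed fraction, decision scores on the
# held-out records feeding the ROC.  The reported AUC is the maximum over
# repetitions (optimistically biased; mean and sd are also returned).

#' Cross-validation / SVM configuration
#'
#' Defaults are the optimum of the reference grid search: RBF kernel,
#' `gamma = "scale"`, `C = 0.001`, balanced class weights, 25% hold-out,
#' tolerance 1e-4.
#'
#' @param kernel one of `"linear"`, `"rbf"`, `"poly"`, `"sigmoid"`.
#' @param C regularization parameter (> 0).
#' @param gamma_mode `"scale"` (1 / (p * var(features))) or `"auto"` (1 / p).
#' @param class_weight `"balanced"` (weights inversely proportional to class
#'   size) or `"none"`.
#' @param jackknife fraction of each class held out for testing, in (0, 1).
#' @param repetitions number of random splits (default 25).
#' @param max_iterations advisory cap on training iterations.
#' @param tolerance optimizer termination tolerance.
#' @param seed master seed; repetition r uses seed + r - 1.
#' @return A `cv_config` list.
#' @export
cv_config <- function(kernel = "rbf", C = 0.001, gamma_mode = "scale",
                      class_weight = "balanced", jackknife = 0.25,
                      repetitions = 25, max_iterations = 200000,
                      tolerance = 1e-4, seed = 1) {
  kernel <- match.arg(kernel, c("linear", "rbf", "poly", "sigmoid"))
  gamma_mode <- match.arg(gamma_mode, c("scale", "auto"))
  class_weight <- match.arg(class_weight, c("balanced", "none"))
  stopifnot(C > 0, jackknife > 0, jackknife < 1, repetitions >= 1,
            max_iterations >= 1, tolerance > 0)
  structure(list(kernel = kernel, C = C, gamma_mode = gamma_mode,
                 class_weight = class_weight, jackknife = jackknife,
                 repetitions = as.integer(repetitions),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, decision_shape = "ovo",
                 seed = as.integer(seed)),
            class = "cv_config")
}

svm_gamma <- function(x, mode) {
  p <- ncol(x)
  if (mode == "auto") return(1 / p)
  v <- mean((x - mean(x))^2)
  if (v == 0) 1 / p else 1 / (p * v)
}

# One stratified random split; returns test indices for each class.
stratified_holdout <- function(labels, fraction) {
  idx1 <- which(labels == 1L)
  idx0 <- which(labels == 0L)
  n1 <- max(1L, round(fraction * length(idx1)))
  n0 <- max(1L, round(fraction * length(idx0)))
  c(sample(idx1, n1), sample(idx0, n0))
}

# Train an SVM and score held-out rows; scores oriented so that larger means
# "more like the positive class".
svm_decision_scores <- function(xtr, ytr, xte, config) {
  y <- factor(ytr, levels = c("0", "1"))
  weights <- NULL
  if (config$class_weight == "balanced") {
    tab <- table(y)
    weights <- as.numeric(length(y) / (2 * tab))
    names(weights) <- names(tab)
  }
  gamma <- svm_gamma(xtr, config$gamma_mode)
  e1071_kernel <- c(linear = "linear", rbf = "radial", poly = "polynomial",
                    sigmoid = "sigmoid")[[config$kernel]]
  fit <- e1071::svm(x = xtr, y = y, scale = FALSE, kernel = e1071_kernel,
                    cost = config$C, gamma = gamma,
                    class.weights = weights, tolerance = config$tolerance)
  pred <- stats::predict(fit, xte, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (first == "1") dv[, 1] else -dv[, 1]
}

auc_from_scores <- function(labels, scores) {
  r <- pROC::roc(response = factor(labels, levels = c("0", "1")),
                 predictor = scores, levels = c("0", "1"),
                 direction = "<", quiet = TRUE)
  list(auc = as.numeric(pROC::auc(r)),
       points = data.frame(fpr = rev(1 - r$specificities),
                           tpr = rev(r$sensitivities)))
}

#' Discriminability of a two-class encoded dataset as cross-validated SVM AUC
#'
#' For each repetition a stratified random `jackknife` fraction of each class
#' is held out, the SVM is trained on the remainder, and the AUC is computed
#' from the held-out decision scores.  The reported AUC is the maximum over
#' repetitions.
#'
#' @param encoded an [encode_pair()] result; both classes need >= 8 records.
#' @param config a [cv_config()].
#' @return A `discrimination_result`: `auc_per_repetition`, `auc_reported`
#'   (the maximum), `auc_mean`, `auc_sd`, `roc_points` (from the best
#'   repetition), `config`, `n_pos`, `n_neg`.
#' @export
pairwise_auc <- function(encoded, config = cv_config()) {
  stopifnot(inherits(encoded, "encoded_dataset"), inherits(config, "cv_config"))
  n_pos <- sum(encoded$labels == 1L)
  n_neg <- sum(encoded$labels == 0L)
  if (n_pos < 8 || n_neg < 8) {
    stop("each class needs >= 8 records (have ", n_pos, " / ", n_neg, ")",
         call. = FALSE)
  }
  x <- encoded$features
  labels <- encoded$labels

  one_rep <- function(r) {
    withr::with_seed(config$seed + r - 1L, {
      test <- stratified_holdout(labels, config$jackknife)
      yte <- labels[test]
      ytr <- labels[-test]
      if (min(table(factor(ytr, levels = c(0, 1)))) < 2 ||
          min(table(factor(yte, levels = c(0, 1)))) < 1) {
        test <- stratified_holdout(labels, config$jackknife)
        yte <- labels[test]
        ytr <- labels[-test]
        if (min(table(factor(ytr, levels = c(0, 1)))) < 2) {
          stop("a class has < 2 training members even after reshuffling",
               call. = FALSE)
        }
      }
      scores <- svm_decision_scores(x[-test, , drop = FALSE], ytr,
                                    x[test, , drop = FALSE], config)
      auc_from_scores(yte, scores)
    })
  }

  reps <- lapply(seq_len(config$repetitions), one_rep)
  aucs <- vapply(reps, `[[`, numeric(1), "auc")
  best <- which.max(aucs)
  structure(
    list(auc_per_repetition = aucs, auc_reported = aucs[best],
         auc_mean = mean(aucs), auc_sd = stats::sd(aucs),
         roc_points = reps[[best]]$points, config = config,
         n_pos = n_pos, n_neg = n_neg, provenance = encoded$provenance),
    class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf(
    "discrimination_result: %s vs %s, AUC = %.3f (max of %d reps; mean %.3f +/- %.3f)\n",
    x$provenance[["positive"]], x$provenance[["negative"]], x$auc_reported,
    length(x$auc_per_repetition), x$auc_mean, x$auc_sd))
  invisible(x)
}

#' The reference hyperparameter grid
#'
#' @return Named list of grid ranges: C in \{0.001, 0.01, 0.1, 1\}, the four
#'   kernels, gamma scale/auto, class weight balanced/none, hold-out fraction
#'   in \{0.10, 0.25\}.
#' @export
default_grid <- function() {
  list(C = c(0.001, 0.01, 0.1, 1),
       kernel = c("linear", "rbf", "poly", "sigmoid"),
       gamma_mode = c("scale", "auto"),
       class_weight = c("balanced", "none"),
       jackknife = c(0.10, 0.25))
}

#' Grid search over SVM hyperparameters
#'
#' Evaluates [pairwise_auc()] on every grid cell and returns the
#' configuration with the highest reported AUC.  Ties are broken by smaller
#' C, then by kernel order linear, rbf, poly, sigmoid.  Failing cells are
#' skipped with a warning; an error is raised only if all cells fail.
#'
#' @param encoded an [encode_pair()] result.
#' @param grid named list of ranges for `C`, `kernel`, `gamma_mode`,
#'   `class_weight`, `jackknife` (missing entries fall back to `base`'s
#'   value); default [default_grid()].
#' @param base a [cv_config()] supplying the non-searched fields (seed,
#'   repetitions, tolerance, ...).
#' @return List with elements `best_config`, `best_result`, and `table`
#'   (one row per evaluated cell).
#' @export
grid_search <- function(encoded, grid = default_grid(), base = cv_config()) {
  stopifnot(is.list(grid), length(grid) > 0)
  fields <- c("C", "kernel", "gamma_mode", "class_weight", "jackknife")
  ranges <- lapply(fields, function(f) {
    if (!is.null(grid[[f]])) grid[[f]] else base[[f]]
  })
  names(ranges) <- fields
  cells <- expand.grid(ranges, stringsAsFactors = FALSE)

  results <- vector("list", nrow(cells))
  aucs <- rep(NA_real_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- cv_config(kernel = cells$kernel[i], C = cells$C[i],
                     gamma_mode = cells$gamma_mode[i],
                     class_weight = cells$class_weight[i],
                     jackknife = cells$jackknife[i],
                     repetitions = base$repetitions,
                     max_iterations = base$max_iterations,
                     tolerance = base$tolerance, seed = base$seed)
    res <- tryCatch(pairwise_auc(encoded, cfg), error = function(e) {
      warning("grid cell ", i, " failed: ", conditionMessage(e))
      NULL
    })
    results[[i]] <- res
    if (!is.null(res)) aucs[i] <- res$auc_reported
  }
  if (all(is.na(aucs))) stop("every grid cell failed", call. = FALSE)
  kernel_order <- c("linear", "rbf", "poly", "sigmoid")
  ord <- order(-aucs, cells$C, match(cells$kernel, kernel_order),
               na.last = TRUE)
  best <- ord[1]
  list(best_config = results[[best]]$config,
       best_result = results[[best]],
       table = cbind(cells, auc_reported = aucs))
}

#' All-pairs AUC similarity matrix of cleavage-site datasets
#'
#' Each unordered pair of datasets is encoded over `span` and scored once
#' with [pairwise_auc()]; the matrix is symmetric by construction with an
#' undefined diagonal.  AUC bins (0.5-0.6 most similar ... 0.9-1.0 most
#' distinct) annotate each pair.
#'
#' @param datasets named list of >= 2 `cleavage_table`s; names are the
#'   enzyme labels.
#' @param span a [subsite_span()].
#' @param matrix a substitution matrix.
#' @param config a [cv_config()].
#' @return A `similarity_matrix`: list with `auc` (symmetric matrix, NA
#'   diagonal), `bin` (matrix of bin labels), `pairs` (per-pair
#'   `discrimination_result`s), `span`.
#' @export
similarity_matrix <- function(datasets, span, matrix, config = cv_config()) {
  stopifnot(is.list(datasets), length(datasets) >= 2,
            !is.null(names(datasets)), all(nzchar(names(datasets))))
  labs <- names(datasets)
  m <- stats::setNames(
    as.data.frame(matrix(NA_real_, length(labs), length(labs))), labs)
  m <- as.matrix(m)
  rownames(m) <- labs
  pairs <- list()
  combos <- utils::combn(labs, 2)
  for (j in seq_len(ncol(combos))) {
    a <- combos[1, j]; b <- combos[2, j]
    enc <- encode_pair(datasets[[a]], datasets[[b]], span, matrix)
    res <- pairwise_auc(enc, config)
    m[a, b] <- m[b, a] <- res$auc_reported
    pairs[[paste(a, b, sep = " vs ")]] <- res
  }
  bins <- cut(m, breaks = c(0, 0.5, 0.6, 0.7, 0.8, 0.9, 1),
              labels = c("<0.5", "0.5-0.6", "0.6-0.7", "0.7-0.8",
                         "0.8-0.9", "0.9-1.0"),
              include.lowest = TRUE)
  bin_m <- matrix(as.character(bins), nrow(m), dimnames = dimnames(m))
  structure(list(auc = m, bin = bin_m, pairs = pairs, span = span),
            class = "similarity_matrix")
}

#' Write a similarity matrix as TSV (enzyme labels as header row/column)
#'
#' @param sim a [similarity_matrix()] result.
#' @param path output file path.
#' @export
write_similarity_matrix <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  df <- data.frame(enzyme = rownames(sim$auc), sim$auc, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize one pair comparison as a JSON report
#'
#' @param result a `discrimination_result`.
#' @param path output file path.
#' @export
write_discrimination_report <- function(result, path) {
  stopifnot(inherits(result, "discrimination_result"))
  payload <- list(
    positive = unname(result$provenance[["positive"]]),
    negative = unname(result$provenance[["negative"]]),
    n_pos = result$n_pos, n_neg = result$n_neg,
    auc_reported = result$auc_reported, auc_mean = result$auc_mean,
    auc_sd = result$auc_sd, auc_per_repetition = result$auc_per_repetition,
    config = unclass(result$config), roc_points = result$roc_points)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
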