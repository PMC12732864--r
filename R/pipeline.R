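# Orchestration: file-in / file-out wrappers tying the analysis stages
# together.  Each writes its outputs plus a machine-readable summary JSON and
# a config record into `out_dir`, and reruns with the same inputs, config and
# seed overwrite the outputs with identical content.  A thin command-line
# dispatcher over these functions ships in `inst/cli/cleavkin.R`.

span_from_string <- function(span, window_width) {
  parts <- strsplit(span, "[:-]")[[1]]
  if (length(parts) != 2) {
    stop("span must be of the form 'P3:P4p' or 'P3-P4''", call. = FALSE)
  }
  subsite_span(parts[1], parts[2], window_width)
}

write_run_config <- function(out_dir, config) {
  jsonlite::write_json(config, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

ensure_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Subsite heterogeneity analysis of one cleavage dataset
#'
#' Reads a cleavage TSV, computes per-subsite residue frequencies over the
#' span and the Anderson-Darling heterogeneity report, and writes
#' `heterogeneity.tsv` (position, statistic, p, klass) plus a summary JSON.
#'
#' @param input cleavage TSV path.
#' @param out_dir output directory (created if needed).
#' @param span span string, e.g. `"P3:P4p"` (default).
#' @param window_width window half-width (default 15).
#' @param threshold p-value cutoff for the specific-position list.
#' @return The `heterogeneity_report`, invisibly.
#' @export
run_positions <- function(input, out_dir, span = "P3:P4p",
                          window_width = 15, threshold = 0.05) {
  ensure_out_dir(out_dir)
  sp <- span_from_string(span, window_width)
  records <- read_cleavage_table(input, window_width)
  if (nrow(records) == 0) stop("no records in ", input, call. = FALSE)
  report <- anderson_darling_heterogeneity(residue_frequencies(records, sp))
  write_heterogeneity_report(report, file.path(out_dir, "heterogeneity.tsv"))
  specific <- select_specific_positions(report, threshold)
  jsonlite::write_json(
    list(input = input, n_records = nrow(records), span = span,
         threshold = threshold, specific_positions = specific,
         n_heterogeneous = sum(report$klass == "heterogeneous")),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_run_config(out_dir, list(subcommand = "positions", input = input,
                                 span = span, window_width = window_width,
                                 threshold = threshold))
  invisible(report)
}

#' Pairwise discrimination of two cleavage datasets
#'
#' Encodes the two datasets over the span with BLOSUM62 and reports the
#' cross-validated SVM AUC (`pair_report.json`), optionally after a
#' hyperparameter grid search.
#'
#' @param pos_input,neg_input cleavage TSV paths (positive / negative class).
#' @param out_dir output directory.
#' @param span span string (default `"P3:P4p"`).
#' @param seed master seed.
#' @param grid run the reference grid search instead of the default config.
#' @param matrix_path substitution matrix file (default: packaged BLOSUM62).
#' @param window_width window half-width.
#' @param config a [cv_config()]; its seed is replaced by `seed`.
#' @return The `discrimination_result`, invisibly.
#' @export
run_discriminate <- function(pos_input, neg_input, out_dir, span = "P3:P4p",
                             seed = 1, grid = FALSE,
                             matrix_path = blosum62_path(),
                             window_width = 15, config = cv_config()) {
  ensure_out_dir(out_dir)
  sp <- span_from_string(span, window_width)
  m <- load_substitution_matrix(matrix_path)
  config$seed <- as.integer(seed)
  enc <- encode_pair(read_cleavage_table(pos_input, window_width),
                     read_cleavage_table(neg_input, window_width), sp, m)
  result <- if (grid) {
    gs <- grid_search(enc, base = config)
    gs$best_result
  } else {
    pairwise_auc(enc, config)
  }
  write_discrimination_report(result, file.path(out_dir, "pair_report.json"))
  write_run_config(out_dir, list(subcommand = "discriminate",
                                 pos_input = pos_input,
                                 neg_input = neg_input, span = span,
                                 seed = seed, grid = grid,
                                 matrix = matrix_path))
  invisible(result)
}

#' All-pairs AUC similarity matrix of several cleavage datasets
#'
#' @param inputs named character vector of cleavage TSV paths; names become
#'   the matrix labels (unnamed inputs are labeled by each file's enzyme
#'   column).
#' @param out_dir output directory.
#' @param span span string.
#' @param seed master seed.
#' @param matrix_path substitution matrix file.
#' @param window_width window half-width.
#' @param config a [cv_config()].
#' @return The `similarity_matrix`, invisibly.
#' @export
run_matrix <- function(inputs, out_dir, span = "P3:P4p", seed = 1,
                       matrix_path = blosum62_path(), window_width = 15,
                       config = cv_config()) {
  ensure_out_dir(out_dir)
  sp <- span_from_string(span, window_width)
  m <- load_substitution_matrix(matrix_path)
  config$seed <- as.integer(seed)
  datasets <- lapply(inputs, read_cleavage_table,
                     window_width = window_width)
  if (is.null(names(inputs)) || any(!nzchar(names(inputs)))) {
    names(datasets) <- vapply(datasets,
                              function(d) unique(d$enzyme)[1], character(1))
  }
  sim <- similarity_matrix(datasets, sp, m, config)
  write_similarity_matrix(sim, file.path(out_dir, "similarity.tsv"))
  for (nm in names(sim$pairs)) {
    write_discrimination_report(
      sim$pairs[[nm]],
      file.path(out_dir, paste0("pair_", gsub("[^A-Za-z0-9]+", "_", nm),
                                ".json")))
  }
  write_run_config(out_dir, list(subcommand = "matrix",
                                 inputs = as.list(inputs), span = span,
                                 seed = seed, matrix = matrix_path))
  invisible(sim)
}

#' Ward clustering of a combined two-enzyme dataset
#'
#' @param inputs two cleavage TSV paths (one per enzyme).
#' @param out_dir output directory.
#' @param span span string (default `"P3:P4p"`).
#' @param max_clusters dendrogram cut cap (default 400).
#' @param min_size minimum size of an enzyme-specific cluster (default 2).
#' @param matrix_path substitution matrix file.
#' @param window_width window half-width.
#' @return The `cluster_result`, invisibly.
#' @export
run_cluster <- function(inputs, out_dir, span = "P3:P4p",
                        max_clusters = 400, min_size = 2,
                        matrix_path = blosum62_path(), window_width = 15) {
  stopifnot(length(inputs) == 2)
  ensure_out_dir(out_dir)
  sp <- span_from_string(span, window_width)
  m <- load_substitution_matrix(matrix_path)
  enc <- encode_pair(read_cleavage_table(inputs[[1]], window_width),
                     read_cleavage_table(inputs[[2]], window_width), sp, m)
  result <- ward_cluster(enc, max_clusters)
  write_cluster_report(result, file.path(out_dir, "clusters.tsv"), min_size)
  write_run_config(out_dir, list(subcommand = "cluster",
                                 inputs = as.list(inputs), span = span,
                                 max_clusters = max_clusters,
                                 min_size = min_size, matrix = matrix_path))
  invisible(result)
}

#' Kinetic analyses: specific velocity plot or depletion-aware Ki fit
#'
#' `mode = "svp"` runs [specific_velocity_analysis()] on a rate TSV and
#' writes the estimates plus primary/secondary line coordinates as plot-data
#' TSVs; `mode = "fit_ki"` runs [fit_ki()].  For SPR rate constants use
#' [spr_kd()] directly.
#'
#' @param input rate TSV path (header `S_uM`, `I_nM`, `v`).
#' @param out_dir output directory.
#' @param mode `"svp"` or `"fit_ki"`.
#' @param km substrate Michaelis constant (uM; default 547.7, the value for
#'   z-RR-AMC on mouse cathepsin B).
#' @param et total enzyme concentration (nM, default 1).
#' @param params_init optional [modifier_params()] initial values for
#'   `fit_ki`; defaults to the specific-velocity estimates computed from the
#'   same file when it contains multiple substrate concentrations, else
#'   generic starting values.
#' @param free free parameters for `fit_ki`.
#' @return The analysis object, invisibly.
#' @export
run_kinetics <- function(input, out_dir, mode = c("svp", "fit_ki"),
                         km = 547.7, et = 1.0, params_init = NULL,
                         free = c("Ki", "v0_scale")) {
  mode <- match.arg(mode)
  ensure_out_dir(out_dir)
  points <- read_rate_table(input)
  if (mode == "svp") {
    ana <- specific_velocity_analysis(points, Km = km, Et = et)
    jsonlite::write_json(
      list(estimates = ana$estimates, excluded_It = ana$excluded_It,
           Km = km),
      file.path(out_dir, "svp_estimates.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    utils::write.table(ana$primary, file.path(out_dir, "svp_primary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sec <- data.frame(
      It = ana$primary$It[ana$usable],
      inv_It = 1 / ana$primary$It[ana$usable],
      inv_a1_minus_1 = 1 / (ana$primary$a1[ana$usable] - 1),
      inv_a0_minus_1 = 1 / (ana$primary$a0[ana$usable] - 1))
    utils::write.table(sec, file.path(out_dir, "svp_secondary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out <- ana
  } else {
    if (is.null(params_init)) {
      params_init <- modifier_params(Km = km, Ki = max(points$It) / 10,
                                     alpha = 1.5, beta = 0.05,
                                     v0_scale = max(points$v) * 2)
    }
    fit <- fit_ki(points, Et = et, params_init = params_init, free = free)
    jsonlite::write_json(
      list(estimates = fit$estimates, config = fit$config,
           residuals = fit$residuals,
           params = unclass(fit$params)),
      file.path(out_dir, "ki_fit.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    out <- fit
  }
  write_run_config(out_dir, list(subcommand = "kinetics", mode = mode,
                                 input = input, km = km, et = et))
  invisible(out)
}
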