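# Synthetic inputs with controlled statistics: cleavage windows drawn from
# position-specific residue distributions (with a tunable divergence between
# two pseudo-enzymes) and initial-rate data drawn from the modifier model
# with multiplicative Gaussian noise.  Everything is deterministic given a
# seed; RNG state is isolated with withr::with_seed.

#' Position-specific residue model for cleavage windows
#'
#' @param window_width half-width W; windows have `2 * W` positions.
#' @param probs optional `(2*W) x 20` matrix of per-position residue
#'   probabilities (columns in [STANDARD_AA] order, rows summing to 1);
#'   default is uniform residue usage at every position.
#' @return A `position_specific_model`.
#' @export
position_specific_model <- function(window_width = 15, probs = NULL) {
  L <- 2L * as.integer(window_width)
  if (is.null(probs)) {
    probs <- matrix(1 / 20, nrow = L, ncol = 20)
  }
  stopifnot(is.matrix(probs), nrow(probs) == L, ncol(probs) == 20,
            all(probs >= 0))
  if (any(abs(rowSums(probs) - 1) > 1e-12)) {
    stop("each position's probability vector must sum to 1", call. = FALSE)
  }
  dimnames(probs) <- list(subsite_labels(window_width), STANDARD_AA)
  structure(list(window_width = as.integer(window_width), probs = probs),
            class = "position_specific_model")
}

#' Cathepsin-like position-specific preset
#'
#' A stylised papain-family specificity profile for simulation studies:
#' strong preference for bulky hydrophobic residues at P2 (the dominant
#' specificity determinant of this family), basic residues favoured at P1,
#' small residues at P1', and near-uniform usage elsewhere.
#'
#' @param window_width half-width W (default 15).
#' @return A [position_specific_model()].
#' @export
cathepsin_like_model <- function(window_width = 15) {
  model <- position_specific_model(window_width)
  probs <- model$probs
  bias <- function(favoured, weight) {
    p <- rep((1 - weight) / (20 - length(favoured)), 20)
    names(p) <- STANDARD_AA
    p[favoured] <- weight / length(favoured)
    p
  }
  span <- function(label) subsite_index(label, window_width)
  probs[span("P2"), ] <- bias(c("F", "L", "V", "Y", "W"), 0.6)
  probs[span("P1"), ] <- bias(c("R", "K"), 0.45)
  probs[span("P1'"), ] <- bias(c("G", "A", "S"), 0.4)
  position_specific_model(window_width, probs)
}

#' Sample a synthetic cleavage-site dataset
#'
#' Windows are drawn i.i.d. across records and independently per position
#' from the model's probability vectors.
#'
#' @param model a [position_specific_model()].
#' @param n number of records (>= 1).
#' @param enzyme_label enzyme label for every record.
#' @param seed RNG seed; identical seeds give identical datasets.
#' @return A `cleavage_table` with synthesized protein ids and
#'   `p1_index = W + 1` of the synthetic parent.
#' @export
sample_cleavage_dataset <- function(model, n, enzyme_label, seed) {
  stopifnot(inherits(model, "position_specific_model"), n >= 1)
  W <- model$window_width
  windows <- withr::with_seed(as.integer(seed), {
    cols <- apply(model$probs, 1, function(p) {
      sample(STANDARD_AA, n, replace = TRUE, prob = p)
    })
    if (n == 1L) cols <- matrix(cols, nrow = 1)
    apply(cols, 1, paste, collapse = "")
  })
  cleavage_table(enzyme = enzyme_label,
                 protein_id = sprintf("SYN_%s_%05d", enzyme_label, seq_len(n)),
                 p1_index = rep(W + 1L, n),
                 window = windows, window_width = W)
}

#' Divergence specification for a pseudo-enzyme pair
#'
#' @param delta mixing weight in \[0, 1\]; 0 leaves the model unchanged, 1
#'   makes each affected position deterministic at its target residue.
#' @param positions subsite labels (or window indices) to perturb.
#' @param seed seed for the per-position choice of target residue.
#' @return A `divergence_spec`.
#' @export
divergence_spec <- function(delta, positions, seed = 1) {
  stopifnot(delta >= 0, delta <= 1, length(positions) >= 1)
  structure(list(delta = delta, positions = positions,
                 seed = as.integer(seed)),
            class = "divergence_spec")
}

#' Derive a divergent pseudo-enzyme pair from a base model
#'
#' Model A is the base; model B mixes each affected position's probability
#' vector as `(1 - delta) * base + delta * shifted`, where `shifted` is a
#' point mass on a seeded, randomly chosen residue distinct from the base
#' vector's mode.
#'
#' @param base a [position_specific_model()].
#' @param spec a [divergence_spec()].
#' @return List with elements `A`, `B` (models) and `targets` (the shifted
#'   residue per affected position).
#' @export
make_divergent_pair <- function(base, spec) {
  stopifnot(inherits(base, "position_specific_model"),
            inherits(spec, "divergence_spec"))
  W <- base$window_width
  idx <- if (is.character(spec$positions)) {
    vapply(spec$positions, subsite_index, integer(1), window_width = W)
  } else {
    as.integer(spec$positions)
  }
  if (any(idx < 1 | idx > 2L * W)) {
    stop("affected positions outside the window", call. = FALSE)
  }
  probsB <- base$probs
  targets <- withr::with_seed(spec$seed, {
    vapply(idx, function(i) {
      mode <- STANDARD_AA[which.max(base$probs[i, ])]
      sample(setdiff(STANDARD_AA, mode), 1)
    }, character(1))
  })
  for (j in seq_along(idx)) {
    shifted <- as.numeric(STANDARD_AA == targets[j])
    probsB[idx[j], ] <- (1 - spec$delta) * base$probs[idx[j], ] +
      spec$delta * shifted
  }
  list(A = base, B = position_specific_model(W, probsB),
       targets = stats::setNames(targets, rownames(base$probs)[idx]))
}

#' Simulate initial-rate data from the modifier model
#'
#' Velocities are `velocity_with_depletion * (1 + eps)` with
#' `eps ~ Normal(0, noise_cv)`, independent per point and clipped at
#' `v >= 0`.
#'
#' @param S_grid substrate concentrations (uM).
#' @param It_grid total inhibitor concentrations (nM); include 0 to obtain
#'   an uninhibited series.
#' @param Et total enzyme concentration (nM).
#' @param params a [modifier_params()].
#' @param noise_cv multiplicative noise coefficient of variation (>= 0).
#' @param seed RNG seed.
#' @return Data.frame with columns `S`, `It`, `v` over the full grid.
#' @export
simulate_rate_data <- function(S_grid, It_grid, Et, params, noise_cv = 0,
                               seed = 1) {
  stopifnot(length(S_grid) >= 1, length(It_grid) >= 1, noise_cv >= 0)
  grid <- expand.grid(S = S_grid, It = It_grid)
  v_model <- velocity_with_depletion(grid$S, grid$It, Et, params)
  v <- withr::with_seed(as.integer(seed), {
    pmax(0, v_model * (1 + stats::rnorm(nrow(grid), 0, noise_cv)))
  })
  data.frame(S = grid$S, It = grid$It, v = v)
}
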