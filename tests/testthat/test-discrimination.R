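# Smaller sample sizes and repetition counts than the defaults are used here
# to keep the unit suite fast; the full-size null/power checks live in the
# acceptance tests.

enc_cached <- local({
  cache <- new.env()
  function(nA, nB, delta = 0, seedA = 11, seedB = 12) {
    key <- paste(nA, nB, delta, seedA, seedB, sep = "_")
    if (is.null(cache[[key]])) {
      base <- position_specific_model()
      pair <- make_divergent_pair(base,
                                  divergence_spec(delta, c("P2", "P1", "P1'"),
                                                  seed = 3))
      A <- sample_cleavage_dataset(pair$A, nA, "enzA", seedA)
      B <- sample_cleavage_dataset(pair$B, nB, "enzB", seedB)
      cache[[key]] <- encode_pair(A, B, SPAN_P3_P4p, BLOSUM)
    }
    cache[[key]]
  }
})

test_that("identical seed and config reproduce AUCs to the last bit", {
  enc <- enc_cached(40, 40)
  cfg <- cv_config(repetitions = 5, seed = 99)
  r1 <- pairwise_auc(enc, cfg)
  r2 <- pairwise_auc(enc, cfg)
  expect_identical(r1$auc_per_repetition, r2$auc_per_repetition)
  expect_equal(r1$auc_reported, max(r1$auc_per_repetition))
  expect_length(r1$auc_per_repetition, 5)
})

test_that("ROC points are monotone nondecreasing in both coordinates", {
  enc <- enc_cached(40, 40, delta = 0.6)
  res <- pairwise_auc(enc, cv_config(repetitions = 3, seed = 1))
  expect_true(all(diff(res$roc_points$fpr) >= 0))
  expect_true(all(diff(res$roc_points$tpr) >= 0))
  expect_true(all(res$auc_per_repetition >= 0 & res$auc_per_repetition <= 1))
})

test_that("swapping which dataset is positive leaves AUC invariant", {
  base <- position_specific_model()
  A <- sample_cleavage_dataset(base, 500, "enzA", 61)
  pair <- make_divergent_pair(base, divergence_spec(0.4, c("P1", "P2'"),
                                                    seed = 8))
  B <- sample_cleavage_dataset(pair$B, 500, "enzB", 62)
  cfg <- cv_config(seed = 4)
  ab <- pairwise_auc(encode_pair(A, B, SPAN_P3_P4p, BLOSUM), cfg)
  ba <- pairwise_auc(encode_pair(B, A, SPAN_P3_P4p, BLOSUM), cfg)
  expect_lt(abs(ab$auc_reported - ba$auc_reported), 0.02)
})

test_that("classes below the minimum size are rejected", {
  enc <- enc_cached(7, 20)
  expect_error(pairwise_auc(enc), ">= 8")
})

test_that("a one-cell grid returns that cell's result", {
  enc <- enc_cached(40, 40, delta = 0.8)
  base_cfg <- cv_config(repetitions = 3, seed = 2)
  gs <- grid_search(enc,
                    grid = list(C = 0.01, kernel = "rbf",
                                gamma_mode = "scale",
                                class_weight = "balanced",
                                jackknife = 0.25),
                    base = base_cfg)
  direct <- pairwise_auc(enc, cv_config(C = 0.01, repetitions = 3, seed = 2))
  expect_equal(gs$best_result$auc_reported, direct$auc_reported)
  expect_equal(nrow(gs$table), 1)
})

test_that("grid search never returns less than any evaluated cell", {
  enc <- enc_cached(40, 40, delta = 0.8)
  base_cfg <- cv_config(repetitions = 3, seed = 2)
  gs <- grid_search(enc, grid = list(C = c(0.001, 0.1),
                                     kernel = c("linear", "rbf")),
                    base = base_cfg)
  expect_equal(gs$best_result$auc_reported,
               max(gs$table$auc_reported, na.rm = TRUE))
  # ties break toward smaller C, then printed kernel order
  t <- gs$table
  winners <- t[t$auc_reported == max(t$auc_reported, na.rm = TRUE), ]
  expect_equal(gs$best_config$C, min(winners$C))
})

test_that("the similarity matrix is symmetric with binned annotation", {
  base <- position_specific_model()
  pair <- make_divergent_pair(base, divergence_spec(0.8, c("P2", "P1", "P1'"),
                                                    seed = 5))
  datasets <- list(
    one = sample_cleavage_dataset(pair$A, 40, "one", 21),
    two = sample_cleavage_dataset(pair$A, 40, "two", 22),
    three = sample_cleavage_dataset(pair$B, 40, "three", 23))
  sim <- similarity_matrix(datasets, SPAN_P3_P4p, BLOSUM,
                           cv_config(repetitions = 5, seed = 6))
  expect_equal(sim$auc, t(sim$auc))
  expect_true(all(is.na(diag(sim$auc))))
  expect_length(sim$pairs, 3)
  # one and two share a generator; three is divergent
  expect_lt(sim$auc["one", "two"], sim$auc["one", "three"])
  expect_true(all(sim$bin[!is.na(sim$auc)] %in%
                    c("<0.5", "0.5-0.6", "0.6-0.7", "0.7-0.8",
                      "0.8-0.9", "0.9-1.0")))
})
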