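# Shared fixtures, built in code at test time.

BLOSUM <- load_substitution_matrix(blosum62_path())
SPAN_P3_P4p <- subsite_span("P3", "P4'")

# A window reading ...AGK | LVF... around the scissile bond (W = 15).
window_agk_lvf <- function() {
  paste0(strrep("S", 12), "AGK", "LVF", strrep("T", 12))
}

tiny_table <- function(n = 3, enzyme = "enzA", seed = 1) {
  sample_cleavage_dataset(position_specific_model(), n, enzyme, seed)
}

write_tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Reference truth used across the kinetics tests: the hyperbolic mixed-type
# parameter set of the mouse cathepsin B / DARPin inhibition experiment.
truth_params <- function(v0_scale = 1) {
  modifier_params(Km = 547.7, Ki = 26.7, alpha = 1.77, beta = 0.047,
                  v0_scale = v0_scale)
}
S_DESIGN <- c(135, 270, 540, 1080)          # uM
IT_DESIGN <- c(53.7, 181, 483, 1448.9)      # nM

# Strongly separated two-motif position models: deterministic disjoint
# residues at P2/P1/P1' and a 0.95-concentrated shared background, so that
# between-motif separation dwarfs within-motif spread.
separated_motif_models <- function() {
  base <- position_specific_model()
  pb <- base$probs
  for (i in seq_len(nrow(pb))) {
    pb[i, ] <- 0.05 / 19
    pb[i, ((i - 1) %% 20) + 1] <- 0.95
  }
  pA <- pb; pB <- pb
  fix <- function(p, pos, aa) {
    p[pos, ] <- as.numeric(STANDARD_AA == aa)
    p
  }
  for (spec in list(c(14, "W", "D"), c(15, "C", "K"), c(16, "P", "Y"))) {
    pos <- as.integer(spec[1])
    pA <- fix(pA, pos, spec[2])
    pB <- fix(pB, pos, spec[3])
  }
  list(A = position_specific_model(15, pA),
       B = position_specific_model(15, pB))
}
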