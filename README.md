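# cleavkin

Statistical comparison of protease substrate specificities from
proteome-derived cleavage-site lists, and kinetic characterisation of
reversible enzyme modifiers by the general (Botts–Morales) mechanism.

The package grew out of a practical problem in inhibitor development:
orthologous proteases — such as mouse and human cathepsin B — can be similar
enough to share most substrates yet different enough that an inhibitor built
against one ignores the other. Answering "how different are these two
enzymes really?" needs tools on two fronts: dataset-level comparison of the
cleavage sites each enzyme produces, and mechanism-level analysis of what an
inhibitor does to the enzyme it binds.

## What it computes

**Specificity profiling.** Cleavage sites are fixed residue windows centred
on the scissile bond, indexed in Schechter–Berger notation (P15…P1 ↓
P1′…P15′). For a chosen subsite span (typically P3–P4′):

* *Subsite heterogeneity* — at each position the vector of 20 per-residue
  relative frequencies is tested for normality with the Anderson–Darling
  test; positions dominated by one or two residues reject (p ≤ 0.05 →
  heterogeneous, ≤ 0.08 → borderline, else normal).
* *Pairwise discriminability* — residues are encoded as their BLOSUM62
  substitution rows (20 · L features) and a support vector machine is
  trained to separate the two datasets under repeated stratified 75/25
  hold-out; the AUC-ROC of held-out decision scores measures how
  distinguishable the two specificities are (0.5 = indistinguishable,
  1.0 = fully distinct). The reported AUC is the maximum across
  repetitions, with mean ± sd alongside. An all-pairs `similarity_matrix()`
  summarises several enzymes at once.
* *Enzyme-specific substrates* — the combined encoded dataset is Ward
  clustered (Euclidean distances over BLOSUM62 features, dendrogram cut at
  up to 400 clusters) and clusters whose members all come from one enzyme
  (purity 1.0, size ≥ 2) are extracted.

**Modifier kinetics.** For a reversible modifier with competitive constant
K_i, ternary-complex factor α and residual turnover β (σ = [S]/K_m):

    v_i / v_0 = (1+σ)(1 + βI/(αK_i)) / [(1 + I/K_i) + σ(1 + I/(αK_i))]

* forward simulation with and without inhibitor depletion (the
  tight-binding closed form is validated against a numeric mass-balance
  solver to 1e−6);
* α, β, K_i estimation by primary/secondary specific velocity plots;
* depletion-aware nonlinear K_i fitting at fixed substrate;
* derived constants: noncompetitive K_i = α·K_i, and K_D = k_d/k_a from
  SPR rate constants.

A synthetic-data module generates cleavage datasets from position-specific
residue models with a tunable divergence between two pseudo-enzymes, and
noisy initial-rate data from the modifier model, so every analysis runs and
is tested without external downloads.

## Worked example

Kinetics — recover the modifier parameters of a hyperbolic mixed-type
inhibitor from a simulated titration (α = 1.77, β = 0.047, K_i = 26.7 nM,
K_m = 547.7 µM, the constants of a DARPin inhibitor of mouse cathepsin B):

```r
library(cleavkin)

params <- modifier_params(Km = 547.7, Ki = 26.7, alpha = 1.77, beta = 0.047)
pts <- simulate_rate_data(S_grid = c(135, 270, 540, 1080),
                          It_grid = c(0, 53.7, 181, 483, 1448.9),
                          Et = 1e-9, params = params, noise_cv = 0, seed = 1)
specific_velocity_analysis(pts, Km = 547.7)
#> specific velocity plot analysis
#>   alpha    = 1.77 (se 2.88e-11)
#>   beta     = 0.047 (se 4.26e-13)
#>   alphaKi  = 47.26 (se 5.04e-11)
#>   Ki       = 26.7 (se 4.36e-10)

noncompetitive_ki(1.77, 26.7)
#> [1] 47.259
spr_kd(ka = 9.80e4, kd = 6.44e-3)   # SPR rates -> K_D in nM
#> [1] 65.71429
```

Specificity — two pseudo-enzymes whose P2/P1/P1′ preferences diverge:

```r
m <- load_substitution_matrix(blosum62_path())
span <- subsite_span("P3", "P4'")
pair <- make_divergent_pair(position_specific_model(),
                            divergence_spec(0.4, c("P2", "P1", "P1'"), seed = 7))
A <- sample_cleavage_dataset(pair$A, 500, "enzA", seed = 301)
B <- sample_cleavage_dataset(pair$B, 500, "enzB", seed = 302)
pairwise_auc(encode_pair(A, B, span, m), cv_config(seed = 1))
#> discrimination_result: enzA vs enzB, AUC = 0.862 (max of 25 reps; mean 0.816 +/- 0.022)
```

An AUC of 0.86 says the two cleavage repertoires are readily separable at
this divergence; at `delta = 0` the same pipeline returns ≈ 0.5 (the null),
and the reported value increases monotonically with divergence.

File-based orchestration (`run_positions()`, `run_discriminate()`,
`run_matrix()`, `run_cluster()`, `run_kinetics()`) writes TSV/JSON reports;
a thin command-line dispatcher over the same functions ships in
`inst/cli/cleavkin.R`.

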