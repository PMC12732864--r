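# The equilibrium oracle (numeric mass-balance solution) is the source of
# truth; both closed-form velocity functions are checked against it, and the
# two parameter-estimation routes are checked against each other.

random_draw <- function() {
  list(S = runif(1, 50, 2000),
       Et = 10^runif(1, -3, 1),
       It = 10^runif(1, -1, 3.5),
       params = modifier_params(Km = 10^runif(1, 1, 3),
                                Ki = 10^runif(1, 0, 2.5),
                                alpha = 10^runif(1, -1, 1),
                                beta = runif(1),
                                v0_scale = runif(1, 0.5, 5)))
}

test_that("zero inhibitor and a silent modifier leave the velocity at v0", {
  p <- truth_params(v0_scale = 2.5)
  S <- 700
  v0 <- 2.5 * (S / p$Km) / (1 + S / p$Km)
  expect_equal(equilibrium_oracle(S, 0, 1, p)$vi, v0)
  expect_equal(velocity_with_depletion(S, 0, 1, p), v0)
  expect_equal(velocity_no_depletion(S, 0, p), 1)

  silent <- modifier_params(Km = 547.7, Ki = 26.7, alpha = 1, beta = 1)
  for (It in c(1, 100, 1e4)) {
    expect_equal(velocity_no_depletion(S, It, silent), 1, tolerance = 1e-12)
    expect_equal(equilibrium_oracle(S, It, 1, silent)$vi,
                 (S / 547.7) / (1 + S / 547.7), tolerance = 1e-10)
  }
})

test_that("saturating modifier approaches the hyperbolic limit", {
  p <- truth_params()
  S <- 700
  sigma <- S / p$Km
  limit <- p$beta * (1 + sigma) / (p$alpha + sigma)
  got <- velocity_no_depletion(S, 1e6 * p$Ki, p)
  expect_equal(got, limit, tolerance = 1e-4)
  o <- equilibrium_oracle(S, 1e6 * p$Ki, 0.01, p)
  expect_equal(o$vi / ((sigma / (1 + sigma))), limit, tolerance = 1e-4)
})

test_that("beta = 0 with large alpha reduces to competitive inhibition", {
  p <- modifier_params(Km = 547.7, Ki = 26.7, alpha = 1e9, beta = 0)
  S <- c(135, 700); I <- c(10, 100)
  for (s in S) for (i in I) {
    sigma <- s / p$Km
    competitive <- (1 + sigma) / (1 + i / p$Ki + sigma)
    expect_equal(velocity_no_depletion(s, i, p), competitive,
                 tolerance = 1e-6)
  }
})

test_that("closed forms match the equilibrium oracle over random sweeps", {
  withr::with_seed(2024, {
    for (i in 1:300) {
      d <- random_draw()
      o <- equilibrium_oracle(d$S, d$It, d$Et, d$params)
      cf <- velocity_with_depletion(d$S, d$It, d$Et, d$params)
      expect_equal(cf, o$vi, tolerance = 1e-6)
    }
    # non-depleted law against the oracle at vanishing enzyme
    for (i in 1:100) {
      d <- random_draw()
      o <- equilibrium_oracle(d$S, d$It, d$It * 1e-8, d$params)
      sigma <- d$S / d$params$Km
      nd <- velocity_no_depletion(d$S, d$It, d$params) *
        d$params$v0_scale * sigma / (1 + sigma)
      expect_equal(nd, o$vi, tolerance = 1e-6)
    }
  })
})

test_that("depletion vanishes when enzyme is negligible", {
  # first-order bound: the relative velocity deviation cannot exceed the
  # relative inhibitor depletion, itself at most Et/It
  p <- truth_params(v0_scale = 3)
  S <- 700
  sigma <- S / p$Km
  for (ratio in c(1e-4, 1e-6)) {
    for (It in c(10, 100, 1000)) {
      vd <- velocity_with_depletion(S, It, It * ratio, p)
      nd <- velocity_no_depletion(S, It, p) * 3 * sigma / (1 + sigma)
      expect_lt(abs(vd - nd) / nd, 2 * ratio)
    }
  }
})

test_that("the depleted titration curve matches the oracle pointwise", {
  p <- truth_params(v0_scale = 1)
  its <- c(1.8, 5, 10, 25, 50, 100, 200, 294)
  for (It in its) {
    expect_equal(velocity_with_depletion(700, It, 1, p),
                 equilibrium_oracle(700, It, 1, p)$vi, tolerance = 1e-9)
  }
})

test_that("velocity is strictly decreasing in inhibitor for beta < 1", {
  for (alpha in c(1, 1.77, 5)) {
    p <- modifier_params(Km = 547.7, Ki = 26.7, alpha = alpha, beta = 0.047)
    vi <- velocity_with_depletion(700, seq(0, 500, by = 10), 1, p)
    expect_true(all(diff(vi) < 0))
    ratio <- velocity_no_depletion(700, 10^seq(-2, 5, 0.5), p)
    expect_true(all(diff(ratio) < 0))
    sigma <- 700 / 547.7
    floor_v <- p$beta * (1 + sigma) / (p$alpha + sigma)
    expect_true(all(ratio > floor_v & ratio <= 1))
  }
})

test_that("specific velocity plot recovers exact parameters exactly", {
  pts <- simulate_rate_data(S_DESIGN, c(0, IT_DESIGN), Et = 1e-9,
                            params = truth_params(), noise_cv = 0, seed = 1)
  ana <- specific_velocity_analysis(pts, Km = 547.7)
  est <- setNames(ana$estimates$value, ana$estimates$parameter)
  expect_equal(est[["alpha"]], 1.77, tolerance = 1e-6)
  expect_equal(est[["beta"]], 0.047, tolerance = 1e-6)
  expect_equal(est[["Ki"]], 26.7, tolerance = 1e-6)
  expect_equal(est[["alphaKi"]], 1.77 * 26.7, tolerance = 1e-6)
  # primary lines are exact for exact data
  expect_true(all(ana$primary$r_squared > 1 - 1e-10))
})

test_that("an inert modifier leaves no usable inhibitor series", {
  inert <- modifier_params(Km = 547.7, Ki = 26.7, alpha = 1, beta = 1)
  pts <- simulate_rate_data(S_DESIGN, c(0, IT_DESIGN), Et = 1e-9,
                            params = inert, noise_cv = 0, seed = 1)
  expect_warning(expect_error(
    specific_velocity_analysis(pts, Km = 547.7), "fewer than 3"),
    "no measurable inhibition")
  expect_error(specific_velocity_analysis(
    pts[pts$It > 0, ], Km = 547.7), "uninhibited")
})

test_that("specific velocity estimates are robust to 2% noise", {
  alphas <- vapply(1:200, function(r) {
    pts <- simulate_rate_data(S_DESIGN, c(0, IT_DESIGN), Et = 1e-9,
                              params = truth_params(), noise_cv = 0.02,
                              seed = 5000 + r)
    ana <- suppressWarnings(specific_velocity_analysis(pts, Km = 547.7))
    ana$estimates$value[ana$estimates$parameter == "alpha"]
  }, numeric(1))
  expect_lt(abs(median(alphas) - 1.77) / 1.77, 0.05)
})

test_that("the depletion-aware fit recovers Ki from noise-free data", {
  p <- truth_params(v0_scale = 3)
  pts <- simulate_rate_data(700, c(0, 1.8, 4, 9, 18, 37, 75, 150, 294),
                            Et = 1, params = p, noise_cv = 0, seed = 1)
  init <- modifier_params(Km = 547.7, Ki = 5, alpha = 1.77, beta = 0.047,
                          v0_scale = 1)
  fit <- fit_ki(pts, Et = 1, params_init = init)
  est <- setNames(fit$estimates$value, fit$estimates$parameter)
  expect_equal(est[["Ki"]], 26.7, tolerance = 1e-3)
  expect_equal(est[["v0_scale"]], 3, tolerance = 1e-3)

  # reparameterized truth: doubling Ki doubles the recovered value
  p2 <- modifier_params(Km = 547.7, Ki = 53.4, alpha = 1.77, beta = 0.047,
                        v0_scale = 3)
  pts2 <- simulate_rate_data(700, c(0, 1.8, 4, 9, 18, 37, 75, 150, 294),
                             Et = 1, params = p2, noise_cv = 0, seed = 1)
  fit2 <- fit_ki(pts2, Et = 1, params_init = init)
  expect_equal(fit2$estimates$value[fit2$estimates$parameter == "Ki"],
               53.4, tolerance = 1e-3)
})

test_that("both estimation routes agree on exact data to 0.1%", {
  p <- truth_params()
  svp_pts <- simulate_rate_data(S_DESIGN, c(0, IT_DESIGN), Et = 1e-9,
                                params = p, noise_cv = 0, seed = 1)
  ana <- specific_velocity_analysis(svp_pts, Km = 547.7)
  est <- setNames(ana$estimates$value, ana$estimates$parameter)

  fit_pts <- simulate_rate_data(700, c(0, 1.8, 4, 9, 18, 37, 75, 150, 294),
                                Et = 1, params = p, noise_cv = 0, seed = 1)
  init <- modifier_params(Km = 547.7, Ki = 5, alpha = est[["alpha"]],
                          beta = est[["beta"]], v0_scale = 0.5)
  fit <- fit_ki(fit_pts, Et = 1, params_init = init)
  ki_fit <- fit$estimates$value[fit$estimates$parameter == "Ki"]
  expect_equal(ki_fit, est[["Ki"]], tolerance = 1e-3)
})

test_that("Monte-Carlo spread of fitted Ki reflects assay noise", {
  p <- truth_params(v0_scale = 3)
  init <- modifier_params(Km = 547.7, Ki = 10, alpha = 1.77, beta = 0.047,
                          v0_scale = 1)
  kis <- vapply(1:100, function(r) {
    pts <- simulate_rate_data(700, c(0, 1.8, 4, 9, 18, 37, 75, 150, 294),
                              Et = 1, params = p, noise_cv = 0.05,
                              seed = 9000 + r)
    fit <- suppressWarnings(fit_ki(pts, Et = 1, params_init = init))
    fit$estimates$value[fit$estimates$parameter == "Ki"]
  }, numeric(1))
  expect_lt(abs(median(kis) - 26.7) / 26.7, 0.1)
  # spread comparable to a few nM under ~5% assay noise
  expect_lt(stats::sd(kis), 10)
  expect_gt(stats::sd(kis), 0.5)
})

test_that("derived constants follow their defining arithmetic", {
  expect_equal(noncompetitive_ki(1.77, 26.7), 47.259, tolerance = 1e-10)
  expect_equal(noncompetitive_ki(1, 7), 7)
  expect_equal(noncompetitive_ki(2, 10), 20)
  expect_equal(spr_kd(1, 1), 1e9)
  expect_error(noncompetitive_ki(-1, 1))
  expect_error(spr_kd(0, 1))
})

test_that("rate tables round-trip through TSV", {
  pts <- simulate_rate_data(c(135, 270), c(0, 50, 100), Et = 1,
                            params = truth_params(), noise_cv = 0.05,
                            seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rate_table(pts, path)
  got <- read_rate_table(path)
  expect_equal(got$S, pts$S)
  expect_equal(got$It, pts$It)
  expect_equal(got$v, pts$v, tolerance = 1e-12)
})
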