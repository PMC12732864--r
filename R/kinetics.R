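# General modifier (Botts-Morales) mechanism under rapid equilibrium.
#
# E binds substrate S with Michaelis constant Km and modifier I with
# dissociation constant Ki; the ternary complex ESI forms with affinity
# scaled by alpha (alpha*Ki from ES, alpha*Km from EI) and turns over at a
# fraction beta of the uninhibited rate.  With sigma = S/Km the fractional
# velocity at free modifier concentration I is
#
#   vi/v0 = (1 + sigma) * (1 + beta*I/(alpha*Ki))
#           / ((1 + I/Ki) + sigma * (1 + I/(alpha*Ki)))
#
# alpha > 1 skews competitive; 0 < beta < 1 gives hyperbolic (partial)
# inhibition with limiting fractional velocity beta*(1+sigma)/(alpha+sigma).
# When the inhibitor is not in large excess over the enzyme (tight binding),
# free I differs from total It and is recovered from the mass balances.
#
# Units are fixed throughout: substrate and Km in uM, inhibitor/enzyme/Ki in
# nM, velocities in the (arbitrary) units of v0_scale.

#' Parameters of the general modifier mechanism
#'
#' @param Km substrate Michaelis constant (uM).
#' @param Ki competitive inhibition constant (nM).
#' @param alpha ratio of competitive to noncompetitive inhibition constants
#'   (> 0); values above 1 indicate predominantly competitive behaviour.
#' @param beta turnover of the inhibited relative to the uninhibited enzyme,
#'   in \[0, 1\].
#' @param v0_scale maximal-velocity scale kcat * Et in signal units; the
#'   uninhibited velocity at substrate S is
#'   `v0_scale * sigma / (1 + sigma)` with `sigma = S / Km`.
#' @return A `modifier_params` list.
#' @export
modifier_params <- function(Km, Ki, alpha, beta, v0_scale = 1) {
  stopifnot(Km > 0, Ki > 0, alpha > 0, beta >= 0, beta <= 1, v0_scale > 0,
            is.finite(alpha * Ki))
  structure(list(Km = Km, Ki = Ki, alpha = alpha, beta = beta,
                 v0_scale = v0_scale),
            class = "modifier_params")
}

#' @export
print.modifier_params <- function(x, ...) {
  cat(sprintf(
    "modifier_params: Km = %g uM, Ki = %g nM, alpha = %g, beta = %g, v0_scale = %g\n",
    x$Km, x$Ki, x$alpha, x$beta, x$v0_scale))
  invisible(x)
}

#' Numeric equilibrium solver for the modifier scheme (reference oracle)
#'
#' Solves the rapid-equilibrium mass balances of the four-species scheme
#' (E, ES, EI, ESI) by safeguarded bisection on the free inhibitor
#' concentration in \[0, It\], with substrate treated as un-depleted
#' (S in uM is assumed far above Et in nM).  This solver is the package's
#' source of truth: both closed-form velocity functions are validated
#' against it.
#'
#' @param S substrate concentration (uM, scalar).
#' @param It total inhibitor concentration (nM, scalar).
#' @param Et total enzyme concentration (nM, scalar).
#' @param params a [modifier_params()].
#' @return List of species concentrations `E`, `ES`, `EI`, `ESI` (nM), free
#'   inhibitor `I_free` (nM), and the velocity `vi`
#'   (`v0_scale * (ES + beta*ESI) / Et`, so that `vi` equals the uninhibited
#'   velocity when `It = 0`).
#' @export
equilibrium_oracle <- function(S, It, Et, params) {
  stopifnot(inherits(params, "modifier_params"),
            length(S) == 1, length(It) == 1, length(Et) == 1,
            S > 0, It >= 0, Et > 0)
  sigma <- S / params$Km
  a <- params$alpha; Ki <- params$Ki
  cI <- (a + sigma) / (a * Ki)        # (1/Ki + sigma/(alpha*Ki))
  bound <- function(I) Et * I * cI / ((1 + sigma) + I * cI)
  f <- function(I) I + bound(I) - It  # monotone increasing in I

  if (It == 0) {
    I <- 0
  } else {
    lo <- 0; hi <- It
    for (iter in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if ((hi - lo) <= 1e-16 * It) break
    }
    I <- (lo + hi) / 2
  }
  E <- Et / ((1 + sigma) + I * cI)
  species <- list(E = E, ES = E * sigma, EI = E * I / Ki,
                  ESI = E * sigma * I / (a * Ki), I_free = I)
  # both mass balances must close to 1e-10 * Et
  res_E <- abs(E + species$ES + species$EI + species$ESI - Et)
  res_I <- abs(I + species$EI + species$ESI - It)
  stopifnot(res_E < 1e-10 * Et, res_I < 1e-10 * max(Et, It))
  species$vi <- params$v0_scale * (species$ES + params$beta * species$ESI) / Et
  species
}

#' Fractional velocity without inhibitor depletion
#'
#' The classical rate law of the general modifier mechanism, valid when the
#' free inhibitor concentration equals the total (It >> Et).
#'
#' @param S substrate concentration(s) (uM).
#' @param I free inhibitor concentration(s) (nM).
#' @param params a [modifier_params()].
#' @return `vi / v0`, dimensionless, vectorized over `S` and `I`.
#' @export
velocity_no_depletion <- function(S, I, params) {
  stopifnot(inherits(params, "modifier_params"))
  if (any(S <= 0)) stop("substrate concentration must be positive",
                        call. = FALSE)
  if (any(I < 0)) stop("inhibitor concentration must be nonnegative",
                       call. = FALSE)
  sigma <- S / params$Km
  a <- params$alpha; b <- params$beta; Ki <- params$Ki
  (1 + sigma) * (1 + b * I / (a * Ki)) /
    ((1 + I / Ki) + sigma * (1 + I / (a * Ki)))
}

#' Velocity with inhibitor depletion (tight-binding closed form)
#'
#' Closed-form solution of the depletion-aware modifier scheme: the free
#' inhibitor concentration is the positive root of
#' `I^2 + I*(Kapp + Et - It) - It*Kapp = 0` with apparent inhibition
#' constant `Kapp = alpha*Ki*(1+sigma)/(alpha+sigma)`, evaluated in a
#' cancellation-free form.  Agrees with [equilibrium_oracle()] to relative
#' 1e-6 (validated in the test suite over random parameter sweeps).
#'
#' @param S substrate concentration(s) (uM).
#' @param It total inhibitor concentration(s) (nM).
#' @param Et total enzyme concentration (nM, scalar).
#' @param params a [modifier_params()].
#' @return Velocity `vi` in the units of `v0_scale`, vectorized over `S`
#'   and `It`; `It = 0` returns the uninhibited velocity
#'   `v0_scale * sigma / (1 + sigma)`.
#' @export
velocity_with_depletion <- function(S, It, Et, params) {
  stopifnot(inherits(params, "modifier_params"), length(Et) == 1)
  if (Et <= 0) stop("Et must be positive", call. = FALSE)
  if (any(S <= 0)) stop("substrate concentration must be positive",
                        call. = FALSE)
  if (any(It < 0)) stop("total inhibitor must be nonnegative", call. = FALSE)
  sigma <- S / params$Km
  a <- params$alpha; b <- params$beta; Ki <- params$Ki
  Kapp <- a * Ki * (1 + sigma) / (a + sigma)
  bb <- Kapp + Et - It
  # I = (-bb + sqrt(bb^2 + 4*It*Kapp))/2, written to avoid cancellation
  I <- ifelse(It == 0, 0,
              2 * It * Kapp / (bb + sqrt(bb^2 + 4 * It * Kapp)))
  v0 <- params$v0_scale * sigma / (1 + sigma)
  v0 * (1 + b * I / (a * Ki)) / (1 + I / Kapp)
}

#' Estimate alpha, beta and Ki by the specific velocity plot
#'
#' Primary stage: for each total inhibitor concentration It, the specific
#' velocity `v0/vi` is regressed on `x = sigma/(1+sigma)`; the fitted values
#' at `x = 0` and `x = 1` give the intercept series `a0(It)` and `a1(It)`.
#' Secondary stage: `1/(a1 - 1)` and `1/(a0 - 1)` are regressed on `1/It`;
#' with slope/intercept (s1, c1) of the first line and (s2, c2) of the
#' second,
#' `beta = c1/(1+c1)`, `alpha*Ki = s1*(1-beta)`, `alpha = beta + beta/c2`,
#' `Ki = alpha*Ki / alpha`.  These relations are exact for data generated by
#' [velocity_no_depletion()] (verified in the test suite by exact recovery),
#' so the procedure assumes It >> Et.
#'
#' Standard errors are first-order (delta method) propagations of the
#' secondary-regression coefficient errors, treating the two secondary lines
#' as independent.
#'
#' @param points data.frame with columns `S` (uM), `It` (nM), `v`; must
#'   contain an uninhibited (`It = 0`) series covering every S value, and
#'   at least 3 usable inhibitor concentrations with >= 3 distinct S each.
#' @param Km substrate Michaelis constant (uM).
#' @param Et optional total enzyme concentration (nM); when given, a warning
#'   is issued if any It is below `20 * Et`, where ignoring depletion biases
#'   the primary lines.
#' @return A `specific_velocity_analysis`: `primary` (per-It line fits and
#'   intercepts), `secondary` (the two 1/It regressions), `estimates`
#'   (data.frame of alpha, beta, alpha*Ki, Ki with standard errors),
#'   `excluded_It`, `Km`.
#' @export
specific_velocity_analysis <- function(points, Km, Et = NULL) {
  stopifnot(is.data.frame(points), all(c("S", "It", "v") %in% names(points)),
            Km > 0)
  v0_series <- points[points$It == 0, , drop = FALSE]
  if (nrow(v0_series) == 0) {
    stop("an uninhibited (It = 0) series is required to form v0/vi",
         call. = FALSE)
  }
  v0_by_S <- tapply(v0_series$v, v0_series$S, mean)

  its <- sort(unique(points$It[points$It > 0]))
  if (length(its) < 3) {
    stop("need >= 3 distinct inhibitor concentrations", call. = FALSE)
  }
  if (!is.null(Et) && any(its < 20 * Et)) {
    warning("some It are below 20 * Et; the specific velocity plot assumes ",
            "negligible inhibitor depletion")
  }

  primary <- lapply(its, function(it) {
    d <- points[points$It == it, , drop = FALSE]
    if (length(unique(d$S)) < 3) {
      stop("need >= 3 distinct substrate concentrations at It = ", it,
           call. = FALSE)
    }
    v0 <- v0_by_S[as.character(d$S)]
    if (anyNA(v0)) {
      stop("no uninhibited velocity for some S at It = ", it, call. = FALSE)
    }
    sigma <- d$S / Km
    x <- sigma / (1 + sigma)
    y <- as.numeric(v0) / d$v
    fit <- stats::lm(y ~ x)
    co <- stats::coef(fit)
    data.frame(It = it, intercept = co[[1]], slope = co[[2]],
               a0 = co[[1]], a1 = co[[1]] + co[[2]],
               r_squared = suppressWarnings(summary(fit)$r.squared))
  })
  primary <- do.call(rbind, primary)
  rownames(primary) <- NULL

  usable <- primary$a0 > 1 & primary$a1 > 1
  if (any(!usable)) {
    warning("excluding It = ",
            paste(primary$It[!usable], collapse = ", "),
            " nM: intercepts <= 1 indicate no measurable inhibition")
  }
  prim <- primary[usable, , drop = FALSE]
  if (nrow(prim) < 3) {
    stop("fewer than 3 usable inhibitor concentrations after exclusion",
         call. = FALSE)
  }

  inv_It <- 1 / prim$It
  fit1 <- stats::lm(I(1 / (prim$a1 - 1)) ~ inv_It)  # sigma -> infinity series
  fit2 <- stats::lm(I(1 / (prim$a0 - 1)) ~ inv_It)  # sigma -> 0 series
  c1 <- stats::coef(fit1)[[1]]; s1 <- stats::coef(fit1)[[2]]
  c2 <- stats::coef(fit2)[[1]]; s2 <- stats::coef(fit2)[[2]]
  # exact synthetic data fits perfectly; summary()'s warning about that is
  # expected and uninformative here
  se1 <- suppressWarnings(summary(fit1)$coefficients[, "Std. Error"])
  se2 <- suppressWarnings(summary(fit2)$coefficients[, "Std. Error"])
  se_c1 <- se1[[1]]; se_s1 <- se1[[2]]; se_c2 <- se2[[1]]

  if (c1 <= 0 || c2 <= 0) {
    warning("nonpositive secondary intercept(s); estimates are outside the ",
            "hyperbolic-modifier domain")
  }
  beta <- c1 / (1 + c1)
  se_beta <- se_c1 / (1 + c1)^2
  alphaKi <- s1 * (1 - beta)
  se_alphaKi <- sqrt(((1 - beta) * se_s1)^2 + (s1 * se_beta)^2)
  alpha <- beta + beta / c2
  se_alpha <- sqrt(((1 + 1 / c2) * se_beta)^2 + (beta / c2^2 * se_c2)^2)
  Ki <- alphaKi / alpha
  se_Ki <- abs(Ki) * sqrt((se_alphaKi / alphaKi)^2 + (se_alpha / alpha)^2)

  estimates <- data.frame(
    parameter = c("alpha", "beta", "alphaKi", "Ki"),
    value = c(alpha, beta, alphaKi, Ki),
    se = c(se_alpha, se_beta, se_alphaKi, se_Ki))
  structure(
    list(primary = primary, usable = usable,
         secondary = list(asymptote_high = fit1, asymptote_low = fit2,
                          s1 = s1, c1 = c1, s2 = s2, c2 = c2),
         estimates = estimates, excluded_It = primary$It[!usable], Km = Km),
    class = "specific_velocity_analysis")
}

#' @export
print.specific_velocity_analysis <- function(x, ...) {
  cat("specific velocity plot analysis\n")
  est <- x$estimates
  for (i in seq_len(nrow(est))) {
    cat(sprintf("  %-8s = %.4g (se %.3g)\n", est$parameter[i], est$value[i],
                est$se[i]))
  }
  if (length(x$excluded_It) > 0) {
    cat("  excluded It:", paste(x$excluded_It, collapse = ", "), "nM\n")
  }
  invisible(x)
}

#' Fit the depletion-aware velocity equation to rate data at fixed substrate
#'
#' Nonlinear least squares ([minpack.lm::nlsLM()]) of
#' [velocity_with_depletion()] against measured velocities over an inhibitor
#' titration at one substrate concentration.  By default only `Ki` and
#' `v0_scale` are free, with `alpha` and `beta` fixed at the values supplied
#' in `params_init` (typically from [specific_velocity_analysis()]).
#'
#' @param points data.frame with columns `S` (uM, one unique value), `It`
#'   (nM) and `v`; needs >= 5 points with It spanning below and above
#'   `5 * Et`.
#' @param Et total enzyme concentration (nM).
#' @param params_init a [modifier_params()] giving starting values (and the
#'   fixed values of the non-free parameters, including Km).
#' @param free character subset of `c("Ki", "v0_scale", "alpha", "beta")`.
#' @param weights `"none"` (unweighted, default) or `"inverse_v"` (1/v
#'   weights).
#' @return A `fit_result`: `params` (fitted `modifier_params`), `estimates`
#'   (free-parameter values with asymptotic standard errors), `residuals`,
#'   `converged`, `config`.
#' @export
fit_ki <- function(points, Et, params_init,
                   free = c("Ki", "v0_scale"),
                   weights = c("none", "inverse_v")) {
  stopifnot(is.data.frame(points), all(c("S", "It", "v") %in% names(points)),
            inherits(params_init, "modifier_params"), Et > 0)
  weights <- match.arg(weights)
  free <- match.arg(free, c("Ki", "v0_scale", "alpha", "beta"),
                    several.ok = TRUE)
  if (nrow(points) < 5) stop("need >= 5 rate points", call. = FALSE)
  if (length(unique(points$S)) != 1) {
    stop("fit_ki expects a single fixed substrate concentration",
         call. = FALSE)
  }
  if (!(any(points$It < 5 * Et) && any(points$It > 5 * Et))) {
    warning("inhibitor titration does not span both sides of 5 * Et; ",
            "depletion is poorly constrained")
  }

  full <- c(Ki = params_init$Ki, v0_scale = params_init$v0_scale,
            alpha = params_init$alpha, beta = params_init$beta)
  lower_all <- c(Ki = 1e-12, v0_scale = 1e-12, alpha = 1e-12, beta = 0)
  upper_all <- c(Ki = Inf, v0_scale = Inf, alpha = Inf, beta = 1)

  model_v <- function(theta) {
    p <- full
    p[free] <- theta
    velocity_with_depletion(points$S, points$It, Et,
                            modifier_params(Km = params_init$Km,
                                            Ki = p[["Ki"]],
                                            alpha = p[["alpha"]],
                                            beta = p[["beta"]],
                                            v0_scale = p[["v0_scale"]]))
  }
  w <- if (weights == "inverse_v") 1 / pmax(points$v, .Machine$double.eps)
       else rep(1, nrow(points))

  resid_fn <- function(theta) sqrt(w) * (points$v - model_v(theta))
  start <- full[free]
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       lower = lower_all[free], upper = upper_all[free],
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-12, ptol = 1e-10)),
    error = function(e) stop("Ki fit failed: ", conditionMessage(e),
                             call. = FALSE))
  converged <- fit$info %in% 1:4
  if (!converged) {
    stop("Ki fit did not converge (", fit$message, "); last iterate: ",
         paste(sprintf("%s = %.6g", names(fit$par), fit$par),
               collapse = ", "),
         call. = FALSE)
  }
  est <- stats::coef(fit)
  covm <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  se <- if (!is.null(covm)) sqrt(diag(covm)) else rep(NA_real_, length(est))
  p <- full
  p[free] <- est
  fitted_params <- modifier_params(Km = params_init$Km, Ki = p[["Ki"]],
                                   alpha = p[["alpha"]], beta = p[["beta"]],
                                   v0_scale = p[["v0_scale"]])
  if (all(points$It[points$It > 0] > 50 * p[["Ki"]])) {
    warning("entire titration is far above the fitted Ki; ",
            "Ki is poorly identified")
  }
  structure(
    list(params = fitted_params,
         estimates = data.frame(parameter = names(est), value = unname(est),
                                se = unname(se)),
         residuals = points$v - model_v(est),
         converged = converged,
         config = list(free = free, fixed = setdiff(names(full), free),
                       weights = weights, Et = Et,
                       start = as.list(start))),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("depletion-aware modifier fit (converged)\n")
  est <- x$estimates
  for (i in seq_len(nrow(est))) {
    cat(sprintf("  %-8s = %.4g (se %.3g)\n", est$parameter[i], est$value[i],
                est$se[i]))
  }
  invisible(x)
}

#' Noncompetitive inhibition constant alpha * Ki
#'
#' @param alpha modifier parameter alpha (> 0).
#' @param ki competitive inhibition constant (nM).
#' @return `alpha * ki` in nM.
#' @export
noncompetitive_ki <- function(alpha, ki) {
  stopifnot(alpha > 0, ki > 0)
  alpha * ki
}

#' Equilibrium dissociation constant from SPR rate constants
#'
#' @param ka association rate constant (1/(M*s)).
#' @param kd dissociation rate constant (1/s).
#' @return `K_D = kd / ka`, converted to nM.
#' @examples
#' spr_kd(9.80e4, 6.44e-3)  # 65.7 nM
#' @export
spr_kd <- function(ka, kd) {
  stopifnot(ka > 0, kd > 0)
  kd / ka * 1e9
}

#' Read / write initial-rate tables
#'
#' TSV with header `S_uM`, `I_nM`, `v`.
#'
#' @param path file path.
#' @return `read_rate_table`: data.frame with columns `S`, `It`, `v`.
#' @export
read_rate_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#")
  required <- c("S_uM", "I_nM", "v")
  if (!all(required %in% names(df))) {
    stop("rate table header must name columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(S = df$S_uM, It = df$I_nM, v = df$v)
  if (any(out$S <= 0) || any(out$It < 0) || any(out$v < 0)) {
    stop("rate table violates S > 0, It >= 0, v >= 0", call. = FALSE)
  }
  out
}

#' @rdname read_rate_table
#' @param points data.frame with columns `S`, `It`, `v`.
#' @export
write_rate_table <- function(points, path) {
  utils::write.table(
    data.frame(S_uM = points$S, I_nM = points$It, v = points$v),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
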