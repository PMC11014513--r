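# analytic expected effect-size estimates under each covariate adjustment
# strategy, computed by solving population normal equations built from the
# exact moments of the generating model; plus the structured zero-bias
# condition reports and the bias-magnitude surface

#' Parameters of the two-variant theoretical model
#'
#' The model tracks a causal variant (Variant 1), an unlinked neutral
#' variant on another chromosome (Variant 2), the admixture proportion
#' `pi` with moments `(pi_mean, pi_var)`, the trait
#' `y = beta1 * g1 + beta_pi * pi + N(0, 1)`, and optionally an extraneous
#' component `z = w1 * std(g1) + w2 * std(g2) + N(0, noise_sd^2)` where
#' `std()` standardizes by the population moments. Genotypes are sums of
#' two allele copies whose ancestries are Bernoulli(`pi`) and whose alleles
#' are Bernoulli(`p_k1`) or Bernoulli(`p_k0`) by ancestry.
#'
#' @param p10,p11 causal-variant allele frequencies in populations 0 and 1.
#' @param p20,p21 neutral-variant allele frequencies.
#' @param pi_mean,pi_var moments of the admixture-proportion distribution;
#'   `pi_var <= pi_mean * (1 - pi_mean)` is required.
#' @param beta1,beta_pi trait-model effects.
#' @param z_weight1,z_weight2,z_noise_sd extraneous-component construction
#'   (weights on standardized `g1`, `g2`, and the sd of the added noise).
#' @return a list of class `theory_model`.
#' @export
theory_model <- function(p10, p11, p20, p21, pi_mean = 0.8, pi_var = 0.01,
                         beta1 = 1, beta_pi = 0,
                         z_weight1 = 1, z_weight2 = 1, z_noise_sd = 0.2) {
  check_prob(c(p10, p11, p20, p21), "allele frequencies")
  if (pi_var < 0 || pi_var > pi_mean * (1 - pi_mean)) {
    stop("pi_var must lie in [0, pi_mean * (1 - pi_mean)]", call. = FALSE)
  }
  structure(list(p10 = p10, p11 = p11, p20 = p20, p21 = p21,
                 pi_mean = pi_mean, pi_var = pi_var,
                 beta1 = beta1, beta_pi = beta_pi,
                 z_weight1 = z_weight1, z_weight2 = z_weight2,
                 z_noise_sd = z_noise_sd),
            class = "theory_model")
}

# exact single-variant moments: E[g], Var(g), Cov(g, pi)
variant_moments <- function(p0, p1, mu, V) {
  d <- p1 - p0
  Eq <- p0 + d * mu                       # per-copy allele probability
  Eq2 <- p0^2 + 2 * p0 * d * mu + d^2 * (V + mu^2)
  list(d = d, mean = 2 * Eq,
       var = 2 * (Eq - Eq2) + 4 * d^2 * V,   # total variance over pi
       cov_pi = 2 * d * V)
}

#' First and second moments of (g1, g2, pi, z)
#'
#' Exact moments of the generating model: `E[g_k] = 2 (p_k0 + d_k mu)`,
#' `Var(g_k)` by the law of total variance, `Cov(g_k, pi) = 2 d_k Vpi`,
#' `Cov(g1, g2) = 4 d1 d2 Vpi` (conditional independence given `pi`), and
#' the `z` moments propagated linearly from its construction. Also reports
#' the average conditional covariances `Cov(g_k, z | pi)`, the quantities
#' whose vanishing switches the collider pathway off.
#'
#' @param model a [theory_model()].
#' @return list with `mean` (named vector over `g1, g2, pi, z`), `cov`
#'   (4 x 4 covariance matrix), and `cond_cov_z` (named vector of
#'   `Cov(g1, z | pi)`, `Cov(g2, z | pi)`).
#' @export
genotype_moments <- function(model) {
  stopifnot(inherits(model, "theory_model"))
  mu <- model$pi_mean
  V <- model$pi_var
  m1 <- variant_moments(model$p10, model$p11, mu, V)
  m2 <- variant_moments(model$p20, model$p21, mu, V)
  c12 <- 4 * m1$d * m2$d * V
  s1 <- sqrt(m1$var)
  s2 <- sqrt(m2$var)
  w1 <- model$z_weight1
  w2 <- model$z_weight2
  vars <- c("g1", "g2", "pi", "z")
  mean_v <- c(g1 = m1$mean, g2 = m2$mean, pi = mu, z = 0)
  C <- matrix(0, 4, 4, dimnames = list(vars, vars))
  C["g1", "g1"] <- m1$var
  C["g2", "g2"] <- m2$var
  C["pi", "pi"] <- V
  C["g1", "g2"] <- C["g2", "g1"] <- c12
  C["g1", "pi"] <- C["pi", "g1"] <- m1$cov_pi
  C["g2", "pi"] <- C["pi", "g2"] <- m2$cov_pi
  C["z", "z"] <- w1^2 + w2^2 + 2 * w1 * w2 * c12 / (s1 * s2) +
    model$z_noise_sd^2
  C["z", "g1"] <- C["g1", "z"] <- w1 * s1 + w2 * c12 / s2
  C["z", "g2"] <- C["g2", "z"] <- w2 * s2 + w1 * c12 / s1
  C["z", "pi"] <- C["pi", "z"] <- w1 * m1$cov_pi / s1 + w2 * m2$cov_pi / s2
  # E[Var(g|pi)] = Var(g) - Var(E[g|pi]); conditional independence given pi
  cond <- c(g1 = w1 * (m1$var - 4 * m1$d^2 * V) / s1,
            g2 = w2 * (m2$var - 4 * m2$d^2 * V) / s2)
  list(mean = mean_v, cov = C, cond_cov_z = cond)
}

#' Large-sample expected effect-size estimate
#'
#' The population least-squares projection of `y` on `[1, g_target, w]`,
#' obtained by solving the normal equations built from
#' [genotype_moments()] and `Cov(y, .)` under the trait model. Adjustments:
#' `"none"` (no covariate), `"ancestry"` (`w = pi`), `"pcs"` (the idealized
#' global-ancestry PC — an affine transform of `pi`, hence identical
#' expected coefficients to `"ancestry"`), `"artificial"` (`w = [pi, z]`).
#' Covariates that are degenerate under the model (e.g. `pi` when
#' `pi_var = 0`, `z` when its variance is 0) are dropped before solving.
#'
#' @param model a [theory_model()].
#' @param adjustment one of `"none"`, `"ancestry"`, `"pcs"`, `"artificial"`.
#' @param target `"causal"` (Variant 1; truth `beta1`) or `"neutral"`
#'   (Variant 2; truth 0).
#' @return list of class `expected_estimate` with `target`, `adjustment`,
#'   `expected_beta`, `truth`, `bias`, `zero_bias_conditions` (a character
#'   vector naming the analytic conditions that individually annihilate the
#'   bias; see [bias_conditions()]).
#' @export
expected_coefficients <- function(model,
                                  adjustment = c("none", "ancestry", "pcs",
                                                 "artificial"),
                                  target = c("causal", "neutral")) {
  adjustment <- match.arg(adjustment)
  target <- match.arg(target)
  mo <- genotype_moments(model)
  C <- mo$cov
  mean_v <- mo$mean
  b1 <- model$beta1
  bpi <- model$beta_pi
  cov_y <- c(g1 = b1 * C["g1", "g1"] + bpi * C["pi", "g1"],
             g2 = b1 * C["g1", "g2"] + bpi * C["pi", "g2"],
             pi = b1 * C["g1", "pi"] + bpi * C["pi", "pi"],
             z  = b1 * C["g1", "z"] + bpi * C["pi", "z"])
  Ey <- b1 * mean_v["g1"] + bpi * mean_v["pi"]
  tv <- if (target == "causal") "g1" else "g2"
  wv <- switch(adjustment, none = character(0), ancestry = "pi",
               pcs = "pi", artificial = c("pi", "z"))
  wv <- wv[diag(C)[wv] > 1e-14]           # drop degenerate covariates
  keep <- c(tv, wv)
  if (C[tv, tv] <= 1e-14) {
    stop("tested variant is degenerate (zero variance)", call. = FALSE)
  }
  M <- rbind(c(1, mean_v[keep]),
             cbind(mean_v[keep],
                   C[keep, keep, drop = FALSE] +
                     outer(mean_v[keep], mean_v[keep])))
  rhs <- c(Ey, cov_y[keep] + mean_v[keep] * as.numeric(Ey))
  sol <- tryCatch(solve(M, rhs), error = function(e) {
    stop("singular moment matrix for adjustment '", adjustment,
         "' (collinear covariates): ", conditionMessage(e), call. = FALSE)
  })
  expected_beta <- unname(sol[2])
  truth <- if (target == "causal") b1 else 0
  structure(list(target = target, adjustment = adjustment,
                 expected_beta = expected_beta, truth = truth,
                 bias = expected_beta - truth,
                 zero_bias_conditions =
                   zero_bias_condition_names(adjustment, target)),
            class = "expected_estimate")
}

# the analytic conditions that individually force bias = 0, per case
zero_bias_condition_names <- function(adjustment, target) {
  key <- paste(adjustment, target, sep = ".")
  switch(key,
    "none.causal" = c("pi_var = 0", "beta_pi = 0", "d1 = 0"),
    "none.neutral" = c("pi_var = 0", "d2 = 0", "beta_pi = 0 and d1 = 0"),
    "ancestry.causal" = "always unbiased",
    "ancestry.neutral" = "always unbiased",
    "pcs.causal" = "always unbiased",
    "pcs.neutral" = "always unbiased",
    "artificial.causal" = "always unbiased",
    "artificial.neutral" = c("beta1 = 0", "cov(g1, z | pi) = 0",
                             "cov(g2, z | pi) = 0"))
}

# instantiate a named condition on a model (returns the modified model)
apply_zero_bias_condition <- function(model, condition) {
  m <- unclass(model)
  switch(condition,
    "pi_var = 0" = { m$pi_var <- 0 },
    "beta_pi = 0" = { m$beta_pi <- 0 },
    "beta1 = 0" = { m$beta1 <- 0 },
    "d1 = 0" = { m$p11 <- m$p10 },
    "d2 = 0" = { m$p21 <- m$p20 },
    "beta_pi = 0 and d1 = 0" = { m$beta_pi <- 0; m$p11 <- m$p10 },
    "cov(g1, z | pi) = 0" = { m$z_weight1 <- 0 },
    "cov(g2, z | pi) = 0" = { m$z_weight2 <- 0 },
    "always unbiased" = { },
    stop("unknown condition: ", condition))
  do.call(theory_model, m)
}

#' Structured zero-bias condition report
#'
#' For the requested adjustment/target, lists the analytic conditions under
#' which the expected estimate is unbiased, instantiates each condition
#' numerically on the supplied model, and reports the resulting bias (which
#' should vanish to numerical precision). For the unadjusted model the
#' conditions mirror the confounding logic (no ancestral heterogeneity, no
#' direct ancestry effect + no frequency difference at the causal variant,
#' no frequency difference at the tested variant); for the
#' extraneous-component model they mirror the collider logic (no causal
#' effect to redistribute, or the component decoupled from either variant).
#'
#' @param model a [theory_model()].
#' @param adjustment,target as in [expected_coefficients()].
#' @return `data.frame` with columns `condition`, `bias_at_condition`,
#'   `holds` (|bias| < 1e-12).
#' @export
bias_conditions <- function(model,
                            adjustment = c("none", "ancestry", "pcs",
                                           "artificial"),
                            target = c("causal", "neutral")) {
  adjustment <- match.arg(adjustment)
  target <- match.arg(target)
  conds <- zero_bias_condition_names(adjustment, target)
  bias <- vapply(conds, function(cn) {
    m2 <- apply_zero_bias_condition(model, cn)
    expected_coefficients(m2, adjustment, target)$bias
  }, numeric(1))
  data.frame(condition = conds, bias_at_condition = unname(bias),
             holds = abs(unname(bias)) < 1e-12,
             stringsAsFactors = FALSE)
}

#' Bias-magnitude surface over a parameter grid
#'
#' Evaluates `|bias|` at the neutral variant over a grid of causal effect
#' sizes, coupling strengths (a common scale on both `z` weights), and
#' admixture-proportion variances, for both the collider pathway (the
#' `[pi, z]`-adjusted model) and the confounding pathway (the unadjusted
#' model). Along the grid the collider bias is exactly linear in `beta1`
#' and increasing in the coupling scale; the confounding bias is increasing
#' in `pi_var`.
#'
#' @param model a [theory_model()] giving the fixed parameters.
#' @param beta1_grid,coupling_grid,pi_var_grid grid values; the coupling
#'   scale multiplies both of the model's `z` weights.
#' @return `data.frame` with columns `beta1`, `coupling`, `pi_var`,
#'   `abs_bias_collider`, `abs_bias_confounding`.
#' @export
bias_magnitude_surface <- function(model,
                                   beta1_grid = c(0, 0.5, 1, 2, 4),
                                   coupling_grid = c(0, 0.25, 0.5, 0.75, 1),
                                   pi_var_grid = c(0, 0.0025, 0.005, 0.01,
                                                   0.02)) {
  stopifnot(inherits(model, "theory_model"),
            length(beta1_grid) >= 1, length(coupling_grid) >= 1,
            length(pi_var_grid) >= 1)
  grid <- expand.grid(beta1 = beta1_grid, coupling = coupling_grid,
                      pi_var = pi_var_grid, KEEP.OUT.ATTRS = FALSE)
  res <- t(apply(grid, 1, function(row) {
    m <- unclass(model)
    m$beta1 <- row[["beta1"]]
    m$pi_var <- row[["pi_var"]]
    m$z_weight1 <- model$z_weight1 * row[["coupling"]]
    m$z_weight2 <- model$z_weight2 * row[["coupling"]]
    m <- do.call(theory_model, m)
    c(abs(expected_coefficients(m, "artificial", "neutral")$bias),
      abs(expected_coefficients(m, "none", "neutral")$bias))
  }))
  grid$abs_bias_collider <- res[, 1]
  grid$abs_bias_confounding <- res[, 2]
  grid
}

#' Monte-Carlo oracle: mean OLS estimates under the generating model
#'
#' Draws `reps` independent cohorts of size `n` from the two-variant model
#' (admixture proportions from the Beta with the model's moments; genotypes
#' binomial given `pi`; `z` from sample-standardized genotypes; trait from
#' the trait model), fits the OLS regression for each adjustment/target,
#' and returns the mean and Monte-Carlo standard error of the estimate.
#' This is the simulation counterpart against which
#' [expected_coefficients()] is validated.
#'
#' The `"pcs"` adjustment uses the idealized global-ancestry PC
#' (standardized `pi`), matching its theoretical treatment.
#'
#' @param model a [theory_model()].
#' @param n individuals per replicate.
#' @param reps number of replicates.
#' @param adjustments,targets subsets of the strategies/targets to run.
#' @param seed integer seed, or `NULL`.
#' @return `data.frame` with columns `adjustment`, `target`, `mean_beta`,
#'   `mc_se`, `reps`.
#' @export
simulate_ols_means <- function(model, n = 2000, reps = 5000,
                               adjustments = c("none", "ancestry", "pcs",
                                               "artificial"),
                               targets = c("causal", "neutral"),
                               seed = NULL) {
  stopifnot(inherits(model, "theory_model"))
  mu <- model$pi_mean
  V <- model$pi_var
  est <- array(NA_real_,
               dim = c(reps, length(adjustments), length(targets)),
               dimnames = list(NULL, adjustments, targets))
  with_seed_maybe(seed, {
    for (r in seq_len(reps)) {
      pi <- if (V == 0) rep(mu, n) else {
        nu <- mu * (1 - mu) / V - 1
        stats::rbeta(n, mu * nu, (1 - mu) * nu)
      }
      g1 <- stats::rbinom(n, 2, model$p10 + (model$p11 - model$p10) * pi)
      g2 <- stats::rbinom(n, 2, model$p20 + (model$p21 - model$p20) * pi)
      s1 <- stats::sd(g1)
      s2 <- stats::sd(g2)
      z <- model$z_weight1 * (g1 - mean(g1)) / s1 +
        model$z_weight2 * (g2 - mean(g2)) / s2 +
        stats::rnorm(n, 0, model$z_noise_sd)
      y <- model$beta1 * g1 + model$beta_pi * pi + stats::rnorm(n)
      pc1 <- if (stats::sd(pi) > 0) as.numeric(scale(pi)) else NULL
      for (a in adjustments) {
        w <- switch(a, none = NULL, ancestry = pi, pcs = pc1,
                    artificial = cbind(pi, z))
        for (tv in targets) {
          g <- if (tv == "causal") g1 else g2
          X <- cbind(1, g, w)
          est[r, a, tv] <- .lm.fit(X, y)$coefficients[2]
        }
      }
    }
  })
  out <- expand.grid(adjustment = adjustments, target = targets,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean_beta <- mapply(function(a, tv) mean(est[, a, tv]),
                          out$adjustment, out$target)
  out$mc_se <- mapply(function(a, tv) stats::sd(est[, a, tv]) / sqrt(reps),
                      out$adjustment, out$target)
  out$reps <- reps
  out
}
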