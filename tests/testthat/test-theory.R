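model_default <- function(...) {
  args <- list(p10 = 0.1, p11 = 0.7, p20 = 0.2, p21 = 0.8,
               pi_mean = 0.8, pi_var = 0.01, beta1 = 2, beta_pi = 1)
  mods <- list(...)
  args[names(mods)] <- mods
  do.call(theory_model, args)
}

test_that("model moments match their closed forms and a simulation oracle", {
  # degenerate structure: no ancestry variance => no covariances
  m0 <- genotype_moments(model_default(pi_var = 0))
  expect_equal(m0$cov["g1", "pi"], 0)
  expect_equal(m0$cov["g1", "g2"], 0)

  # no frequency difference at the causal variant => no ancestry covariance
  md <- genotype_moments(model_default(p10 = 0.4, p11 = 0.4))
  expect_equal(md$cov["g1", "pi"], 0)

  # empirical moments at n = 200000
  mo <- genotype_moments(model_default())
  set.seed(101)
  n <- 200000
  nu <- 0.8 * 0.2 / 0.01 - 1
  pi <- rbeta(n, 0.8 * nu, 0.2 * nu)
  g1 <- rbinom(n, 2, 0.1 + 0.6 * pi)
  g2 <- rbinom(n, 2, 0.2 + 0.6 * pi)
  se_mean <- sd(g1) / sqrt(n)
  expect_lt(abs(mean(g1) - mo$mean["g1"]), 3 * se_mean)
  ip <- (g1 - mean(g1)) * (g2 - mean(g2))
  expect_lt(abs(mean(ip) - mo$cov["g1", "g2"]), 3 * sd(ip) / sqrt(n))
  ip2 <- (g1 - mean(g1))^2
  expect_lt(abs(mean(ip2) - mo$cov["g1", "g1"]), 3 * sd(ip2) / sqrt(n))
  ip3 <- (g1 - mean(g1)) * (pi - mean(pi))
  expect_lt(abs(mean(ip3) - mo$cov["g1", "pi"]), 3 * sd(ip3) / sqrt(n))
})

test_that("expected coefficients recover the known closed forms", {
  m <- model_default()
  mo <- genotype_moments(m)

  # adjusting for true ancestry is unbiased at both variants
  expect_equal(expected_coefficients(m, "ancestry", "causal")$bias, 0,
               tolerance = 1e-12)
  expect_equal(expected_coefficients(m, "ancestry", "neutral")$bias, 0,
               tolerance = 1e-12)
  # the idealized-PC adjustment is its affine equivalent
  expect_equal(expected_coefficients(m, "pcs", "neutral")$expected_beta,
               expected_coefficients(m, "ancestry", "neutral")$expected_beta)

  # unadjusted neutral: beta1 Cov(g1,g2)/Var(g2) + beta_pi Cov(pi,g2)/Var(g2)
  closed <- (m$beta1 * mo$cov["g1", "g2"] + m$beta_pi * mo$cov["pi", "g2"]) /
    mo$cov["g2", "g2"]
  expect_equal(expected_coefficients(m, "none", "neutral")$expected_beta,
               unname(closed), tolerance = 1e-12)

  # unadjusted causal: beta1 + beta_pi Cov(pi,g1)/Var(g1)
  closed1 <- m$beta1 + m$beta_pi * mo$cov["pi", "g1"] / mo$cov["g1", "g1"]
  expect_equal(expected_coefficients(m, "none", "causal")$expected_beta,
               unname(closed1), tolerance = 1e-12)

  # extraneous component leaves the causal variant unbiased
  expect_equal(expected_coefficients(m, "artificial", "causal")$bias, 0,
               tolerance = 1e-10)
  # ... but biases the neutral variant
  expect_gt(abs(expected_coefficients(m, "artificial", "neutral")$bias),
            0.5)
})

test_that("theory matches the OLS simulation oracle", {
  m <- model_default(beta_pi = 0.5)
  sim <- simulate_ols_means(m, n = 1000, reps = 600, seed = 102)
  for (i in seq_len(nrow(sim))) {
    th <- expected_coefficients(m, sim$adjustment[i], sim$target[i])
    expect_lt(abs(sim$mean_beta[i] - th$expected_beta), 3 * sim$mc_se[i])
  }
  # oracle is seed-deterministic
  sim2 <- simulate_ols_means(m, n = 1000, reps = 600, seed = 102)
  expect_identical(sim, sim2)
})

test_that("every emitted zero-bias condition annihilates the bias and perturbations restore it", {
  m <- model_default()
  for (adj in c("none", "artificial")) {
    for (tv in c("causal", "neutral")) {
      bc <- bias_conditions(m, adj, tv)
      expect_true(all(bc$holds),
                  info = paste(adj, tv, ":",
                               paste(bc$condition[!bc$holds],
                                     collapse = "; ")))
    }
  }
  # at a generic point violating every condition the bias is nonzero
  expect_gt(abs(expected_coefficients(m, "none", "causal")$bias), 1e-3)
  expect_gt(abs(expected_coefficients(m, "none", "neutral")$bias), 1e-3)
  expect_gt(abs(expected_coefficients(m, "artificial", "neutral")$bias),
            1e-3)
  # the adjusted strategies are unconditionally unbiased
  expect_true(all(bias_conditions(m, "ancestry", "neutral")$holds))
  expect_true(all(bias_conditions(m, "pcs", "causal")$holds))
})

test_that("bias magnitude scales with effect size, coupling, and heterogeneity", {
  m <- model_default(beta_pi = 0)
  surf <- bias_magnitude_surface(m)

  # collider bias is exactly linear in beta1 ...
  s0 <- surf[surf$coupling == 1 & surf$pi_var == 0.01, ]
  s0 <- s0[order(s0$beta1), ]
  expect_equal(s0$abs_bias_collider[s0$beta1 == 0], 0, tolerance = 1e-12)
  expect_equal(s0$abs_bias_collider[s0$beta1 == 2],
               2 * s0$abs_bias_collider[s0$beta1 == 1], tolerance = 1e-10)
  # ... and monotone along the beta1 grid
  expect_true(all(diff(s0$abs_bias_collider) >= -1e-12))

  # monotone in the coupling scale
  s1 <- surf[surf$beta1 == 2 & surf$pi_var == 0.01, ]
  s1 <- s1[order(s1$coupling), ]
  expect_true(all(diff(s1$abs_bias_collider) >= -1e-12))

  # confounding bias (unadjusted model) is monotone in ancestral
  # heterogeneity and vanishes without it
  m2 <- model_default(beta_pi = 1)
  surf2 <- bias_magnitude_surface(m2, beta1_grid = 2, coupling_grid = 1)
  s2 <- surf2[order(surf2$pi_var), ]
  expect_equal(s2$abs_bias_confounding[s2$pi_var == 0], 0,
               tolerance = 1e-12)
  expect_true(all(diff(s2$abs_bias_confounding) >= -1e-12))
})

test_that("degenerate ancestry variance collapses all strategies to the no-structure values", {
  m <- model_default(pi_var = 0, beta_pi = 3)
  # with Var(pi) = 0 the ancestry covariate is dropped; no confounding exists
  expect_equal(expected_coefficients(m, "none", "neutral")$bias, 0,
               tolerance = 1e-12)
  expect_equal(expected_coefficients(m, "ancestry", "causal")$bias, 0,
               tolerance = 1e-12)
  expect_equal(expected_coefficients(m, "ancestry", "neutral")$bias, 0,
               tolerance = 1e-12)
})
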