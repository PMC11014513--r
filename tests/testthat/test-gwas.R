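test_that("trait simulation follows the generating model", {
  n <- 50000
  G <- matrix(0L, n, 1)
  pi <- rep(0.5, n)
  y <- simulate_trait(G, pi, trait_params(1, 0, 0), seed = 81)
  expect_lt(abs(mean(y)), 3 / sqrt(n))
  expect_lt(abs(var(y) - 1), 3 * sqrt(2 / n))

  y2 <- simulate_trait(matrix(1L, 1000, 1), rep(0, 1000),
                       trait_params(1, 2, 0), seed = 82)
  expect_lt(abs(mean(y2) - 2), 3 / sqrt(1000))

  # OLS recovers (beta1, beta_pi) at large n
  co <- fixture_cohort()
  n <- nrow(co$genotypes)
  y3 <- simulate_trait(co$genotypes, co$pi, trait_params(5, 1, 1), seed = 83)
  fit <- summary(lm(y3 ~ co$genotypes[, 5] + co$pi))$coefficients
  expect_lt(abs(fit[2, 1] - 1), 3 * fit[2, 2])
  expect_lt(abs(fit[3, 1] - 1), 3 * fit[3, 2])

  expect_error(simulate_trait(co$genotypes, co$pi, trait_params(10^6, 1)),
               "causal_index")
})

test_that("covariate construction honours each strategy", {
  co <- fixture_cohort()
  keep <- maf_filter(co$genotypes)
  pca <- run_pca(standardize_genotypes(co$genotypes[, keep]), k = 3)

  w0 <- build_covariates(covariate_spec("none"), pi = co$pi)
  expect_equal(ncol(w0), 0)
  expect_equal(nrow(w0), length(co$pi))

  w1 <- build_covariates(covariate_spec("ancestry"), pi = co$pi)
  expect_equal(drop(w1), co$pi, ignore_attr = TRUE)

  wp <- build_covariates(covariate_spec("pcs", k = 1), pca = pca)
  expect_equal(drop(wp), pca$scores[, 1], ignore_attr = TRUE)

  # symmetric artificial component: equal weights, no noise, independent
  # equal-variance variants => corr(z, g_a) == corr(z, g_b) exactly
  set.seed(84)
  G <- cbind(rbinom(500, 2, 0.5), rbinom(500, 2, 0.5))
  spec <- covariate_spec("artificial",
                         artificial = artificial_pc_spec(1, 2, 1, 1, 0))
  wz <- build_covariates(spec, pi = rep(0.5, 500), genotypes = G, seed = 85)
  expect_equal(cor(wz[, "z"], G[, 1]), cor(wz[, "z"], G[, 2]),
               tolerance = 1e-12)

  expect_error(build_covariates(covariate_spec("ancestry")), "requires")
  expect_error(covariate_spec("artificial"), "artificial_pc_spec")
})

test_that("the marginal fit matches exact arithmetic and normal equations", {
  f <- fit_marginal(c(1, 2, 3), c(0, 1, 2))
  expect_equal(f$beta, 1)

  set.seed(86)
  X <- cbind(rbinom(50, 2, 0.5), rnorm(50))
  y <- rnorm(50)
  f2 <- fit_marginal(y, X[, 1], X[, 2, drop = FALSE])
  D <- cbind(1, X)
  ref <- solve(t(D) %*% D, t(D) %*% y)
  expect_lt(abs(f2$beta - ref[2]), 1e-10)

  expect_error(fit_marginal(y, X[, 2], X[, 2, drop = FALSE]),
               "collinear|rank")
})

test_that("the genome scan reproduces per-variant OLS exactly", {
  co <- fixture_cohort()
  G <- co$genotypes[, maf_filter(co$genotypes)]
  chrom <- co$panel$chrom[maf_filter(co$genotypes)]
  pos <- co$panel$pos_bp[maf_filter(co$genotypes)]
  y <- simulate_trait(G, co$pi, trait_params(3, 0.5, 1), seed = 87)
  w <- cbind(pi = co$pi)
  res <- run_gwas(y, G, w, chrom, pos)

  for (j in c(1, 3, 57)) {
    f <- fit_marginal(y, G[, j], w)
    expect_equal(res$beta[j], f$beta, tolerance = 1e-10)
    expect_equal(res$se[j], f$se, tolerance = 1e-10)
    expect_equal(res$pvalue[j], f$pvalue, tolerance = 1e-10)
  }
  # Wald and p are mutually consistent
  expect_equal(res$pvalue, pchisq(res$wald^2, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # m = 1 reduces to the single fit
  r1 <- run_gwas(y, G[, 1, drop = FALSE], w, chrom[1], pos[1])
  expect_equal(r1$beta, fit_marginal(y, G[, 1], w)$beta)

  # permuting variants permutes rows but not values
  set.seed(88)
  perm <- sample(ncol(G))
  rp <- run_gwas(y, G[, perm], w, chrom[perm], pos[perm])
  expect_equal(rp$beta, res$beta[perm])

  # a covariate-collinear variant yields missing statistics, not an error
  G2 <- cbind(G[, 1:5], round(2 * co$pi))
  G2[, 6] <- G2[, 5]
  r2 <- run_gwas(y, G2, cbind(G2[, 5]), chrom[1:6], pos[1:6])
  expect_true(is.na(r2$beta[5]) && is.na(r2$beta[6]))
})

test_that("null p-values are calibrated at nominal level", {
  panel <- sim_frequency_panel(n_chrom = 10, m_per_chrom = 200, seed = 89)
  co <- simulate_cohort(sim_config(n = 600, seed = 90), panel = panel)
  G <- co$genotypes[, maf_filter(co$genotypes)]
  y <- simulate_trait(G, co$pi, trait_params(1, 0, 0), seed = 91)
  res <- run_gwas(y, G, NULL, co$panel$chrom[maf_filter(co$genotypes)],
                  co$panel$pos_bp[maf_filter(co$genotypes)])
  frac <- mean(res$pvalue < 0.05, na.rm = TRUE)
  m <- sum(!is.na(res$pvalue))
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / m))
})

test_that("spurious-chromosome counting is chromosome-level and excludes the causal one", {
  res <- data.frame(chrom = c("1", "2", "2", "3"),
                    pos_bp = 1:4,
                    pvalue = c(1e-9, 1e-9, 1e-10, 0.5),
                    wald = c(6, 6, 6.5, 0.1))
  expect_equal(count_spurious(res, "1", 5e-8), 1)  # both chr2 hits count once
  expect_equal(count_spurious(res, "2", 5e-8), 1)  # only chr1
  res2 <- res
  res2$pvalue <- 0.5
  expect_equal(count_spurious(res2, "1", 5e-8), 0)
})

test_that("genomic-control lambda is the median chi-square ratio and is median-robust", {
  res <- data.frame(wald = rep(sqrt(qchisq(0.5, 1)), 11))
  expect_equal(genomic_control_lambda(res), 1)

  set.seed(92)
  res2 <- data.frame(wald = rnorm(10000))
  lam <- genomic_control_lambda(res2)
  expect_lt(abs(lam - 1), 0.05)

  res3 <- rbind(res2, data.frame(wald = 1000))
  expect_lt(abs(genomic_control_lambda(res3) - lam), 0.01)
})
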