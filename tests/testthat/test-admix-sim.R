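test_that("admixture proportions honour the requested Beta moments", {
  expect_equal(draw_admixture_proportions(5, 0.8, 0, seed = 1),
               rep(0.8, 5))

  x <- draw_admixture_proportions(10000, 0.8, 0.1, seed = 1)
  expect_true(all(x >= 0 & x <= 1))
  expect_lt(abs(mean(x) - 0.8), 0.01)
  expect_lt(abs(sd(x) - 0.1), 0.01)

  expect_identical(draw_admixture_proportions(3, 0.8, 0.1, seed = 7),
                   draw_admixture_proportions(3, 0.8, 0.1, seed = 7))

  expect_error(draw_admixture_proportions(5, 0.5, 0.6), "sd")
  expect_error(draw_admixture_proportions(5, 1.2, 0.1), "mean")
})

test_that("local ancestry matches its sampling models in both modes", {
  panel <- sim_frequency_panel(n_chrom = 1, m_per_chrom = 2000, seed = 3)

  a1 <- draw_local_ancestry(rep(1, 5), panel, "independent", seed = 4)
  expect_true(all(a1 == 2L))

  # independent mode: per-individual mean of a/2 is binomial around pi
  pi <- rep(0.5, 5)
  a <- draw_local_ancestry(pi, panel, "independent", seed = 5)
  se <- sqrt(0.5 * 0.5 / (2 * 2000))
  expect_true(all(abs(rowMeans(a) / 2 - 0.5) < 3 * se))

  # block mode: crossover count is Poisson(generations * genome length)
  panel100 <- ancestral_panel(rep("1", 50), seq(2e6, 100e6, length.out = 50),
                              rep(0.5, 50), rep(0.5, 50))
  ab <- draw_local_ancestry(rep(0.5, 2000), panel100, "block",
                            generations = 6, cm_per_mb = 1, seed = 6)
  xo <- attr(ab, "n_crossovers")
  lam <- 6 * max(panel100$pos_bp) / 1e8
  expect_lt(abs(mean(xo) - lam), 3 * sqrt(lam / length(xo)))
  # E[a] = 2 pi holds in block mode too (loose bound: entries within a
  # segment are identical, so the effective sample is segments, not sites)
  expect_lt(abs(mean(ab) - 1), 0.02)

  expect_error(draw_local_ancestry(pi, panel, "bogus"))
})

test_that("genotypes are population-conditional Bernoulli draws", {
  pan <- ancestral_panel("1", 100, p0 = 1, p1 = 1)
  a <- matrix(c(0L, 1L, 2L), 3, 1)
  expect_true(all(draw_genotypes(a, pan, seed = 1) == 2L))

  pan2 <- ancestral_panel("1", 100, p0 = 0, p1 = 1)
  a2 <- matrix(1L, 10, 1)
  expect_true(all(draw_genotypes(a2, pan2, seed = 2) == 1L))

  # mixture frequency: E[g]/2 = pi * p1 + (1 - pi) * p0
  pan3 <- ancestral_panel("1", 100, p0 = 0.1, p1 = 0.9)
  n <- 20000
  a3 <- draw_local_ancestry(rep(0.5, n), pan3, "independent", seed = 3)
  g <- draw_genotypes(a3, pan3, seed = 4)
  expect_lt(abs(mean(g) / 2 - 0.5), 3 * sqrt(0.5 * 0.5 / (2 * n)))

  expect_error(draw_genotypes(matrix(0L, 2, 3), pan3), "variants")
})

test_that("LD feature injection has copy semantics governed by coupling", {
  co <- fixture_cohort()
  region <- data.frame(chrom = "1", start_bp = 1, end_bp = 4e7)
  m_in <- sum(co$panel$chrom == "1" & co$panel$pos_bp <= 4e7)
  expect_gt(m_in, 3)

  co0 <- inject_ld_feature(co, ld_feature_spec(region, coupling = 0),
                           seed = 11)
  expect_identical(co0$genotypes, co$genotypes)

  co1 <- inject_ld_feature(co, ld_feature_spec(region, coupling = 1),
                           seed = 11)
  idx <- co1$latent[[1]]$variants
  h <- co1$latent[[1]]$h
  expect_true(all(co1$genotypes[, idx] == h))
  r2 <- cor(co1$genotypes[, idx])^2
  expect_true(all(abs(r2 - 1) < 1e-12))

  # warning + unchanged cohort when no variants fall in the regions
  expect_warning(
    un <- inject_ld_feature(
      co, ld_feature_spec(data.frame(chrom = "9", start_bp = 1,
                                     end_bp = 100), coupling = 1), seed = 1),
    "no panel variants")
  expect_identical(un$genotypes, co$genotypes)
})

test_that("partial coupling reproduces the r2 level of a brute-force oracle", {
  # oracle: simulate the replacement process directly from its definition
  oracle_mean_r2 <- function(n, q, coupling, seed) {
    set.seed(seed)
    g <- matrix(rbinom(n * q, 2, 0.5), n, q)
    h <- rbinom(n, 2, 0.5)
    rep_mask <- matrix(rbinom(n * q, 1, coupling) == 1, n, q)
    g[rep_mask] <- rep(h, q)[rep_mask]
    r2 <- cor(g)^2
    mean(r2[upper.tri(r2)])
  }
  target <- mean(vapply(1:4, function(s) oracle_mean_r2(5000, 8, 0.8, s),
                        numeric(1)))

  pan <- ancestral_panel(rep("1", 8), seq(1000, 8000, by = 1000),
                         rep(0.5, 8), rep(0.5, 8))
  cfg <- sim_config(n = 5000, admixture_sd = 0.1, seed = 21)
  co <- simulate_cohort(cfg, panel = pan)
  spec <- ld_feature_spec(data.frame(chrom = "1", start_bp = 1,
                                     end_bp = 1e4),
                          latent_freq0 = 0.5, latent_freq1 = 0.5,
                          coupling = 0.8)
  coF <- inject_ld_feature(co, spec, seed = 22)
  r2 <- cor(coF$genotypes)^2
  got <- mean(r2[upper.tri(r2)])
  expect_lt(abs(got - target), 0.03)
})

test_that("global ancestry is the genome-wide average of local ancestry", {
  expect_equal(true_global_ancestry(matrix(2L, 3, 5)), rep(1, 3))
  expect_equal(true_global_ancestry(matrix(c(2L, 1L), 1, 2)), 0.75)
  a <- fixture_cohort()$ancestry
  expect_equal(true_global_ancestry(a) + true_global_ancestry(2L - a),
               rep(1, nrow(a)))
  expect_error(true_global_ancestry(matrix(0L, 0, 0)), "empty")
})

test_that("cohort simulation is deterministic given the seed", {
  c1 <- simulate_cohort(sim_config(n = 50, seed = 77),
                        panel = sim_frequency_panel(n_chrom = 2,
                                                    m_per_chrom = 50,
                                                    seed = 78))
  c2 <- simulate_cohort(sim_config(n = 50, seed = 77),
                        panel = sim_frequency_panel(n_chrom = 2,
                                                    m_per_chrom = 50,
                                                    seed = 78))
  expect_identical(c1$pi, c2$pi)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$ancestry, c2$ancestry)
})

test_that("sample allele frequencies converge to the ancestry mixture", {
  pan <- sim_frequency_panel(n_chrom = 1, m_per_chrom = 40, seed = 31)
  n <- 20000
  co <- simulate_cohort(sim_config(n = n, admixture_mean = 0.8,
                                   admixture_sd = 0.1, seed = 32),
                        panel = pan)
  expected <- mean(co$pi) * pan$p1 + (1 - mean(co$pi)) * pan$p0
  phat <- colMeans(co$genotypes) / 2
  se <- sqrt(pmax(expected * (1 - expected), 1e-6) / (2 * n))
  # conditioning on the realized pi's removes the Beta-sampling component
  expect_true(all(abs(phat - expected) < 3 * se + 0.005))
})

test_that("cross-chromosome genotypes are independent given ancestry", {
  co <- fixture_cohort()
  chrom <- co$panel$chrom
  set.seed(41)
  poly <- which(apply(co$genotypes, 2, var) > 0)
  pairs <- cbind(sample(intersect(which(chrom == "1"), poly), 100,
                        replace = TRUE),
                 sample(intersect(which(chrom == "3"), poly), 100,
                        replace = TRUE))
  pcors <- apply(pairs, 1, function(p) {
    r1 <- resid(lm(co$genotypes[, p[1]] ~ co$pi))
    r2 <- resid(lm(co$genotypes[, p[2]] ~ co$pi))
    cor(r1, r2)
  })
  expect_lt(abs(mean(pcors)), 3 / sqrt(nrow(co$genotypes) * 100) + 0.005)
})
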