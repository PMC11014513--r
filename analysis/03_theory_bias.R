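#!/usr/bin/env Rscript
# Step 3 — analytic expected effect sizes under each adjustment strategy,
# the zero-bias condition reports, and the bias-magnitude surface. Also
# cross-checks the analytic values against the OLS simulation oracle.

suppressPackageStartupMessages(library(admixpca))
dir.create("results", showWarnings = FALSE)

m <- theory_model(p10 = 0.1, p11 = 0.7, p20 = 0.2, p21 = 0.8,
                  pi_mean = 0.8, pi_var = 0.01, beta1 = 2, beta_pi = 1)

grid <- expand.grid(adjustment = c("none", "ancestry", "pcs", "artificial"),
                    target = c("causal", "neutral"),
                    stringsAsFactors = FALSE)
grid$expected_beta <- NA_real_
grid$truth <- NA_real_
grid$bias <- NA_real_
for (i in seq_len(nrow(grid))) {
  ec <- expected_coefficients(m, grid$adjustment[i], grid$target[i])
  grid$expected_beta[i] <- ec$expected_beta
  grid$truth[i] <- ec$truth
  grid$bias[i] <- ec$bias
}
write.table(grid, "results/03_expected_estimates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

conds <- do.call(rbind, lapply(c("none", "artificial"), function(adj) {
  do.call(rbind, lapply(c("causal", "neutral"), function(tv) {
    cbind(adjustment = adj, target = tv, bias_conditions(m, adj, tv))
  }))
}))
write.table(conds, "results/03_zero_bias_conditions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

surf <- bias_magnitude_surface(m)
write.table(surf, "results/03_bias_surface.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sim <- simulate_ols_means(m, n = 2000, reps = 2000, seed = 301)
sim$theory <- mapply(function(a, tv) {
  expected_coefficients(m, a, tv)$expected_beta
}, sim$adjustment, sim$target)
sim$abs_z <- abs(sim$mean_beta - sim$theory) / sim$mc_se
write.table(sim, "results/03_theory_vs_sim.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf(
  "unadjusted neutral-variant expected slope %.4f (confounding); [pi,z]-adjusted %.4f (collider)",
  grid$expected_beta[grid$adjustment == "none" & grid$target == "neutral"],
  grid$expected_beta[grid$adjustment == "artificial" &
                       grid$target == "neutral"]))
message(sprintf("all %d zero-bias conditions hold: %s",
                nrow(conds), all(conds$holds)))
message(sprintf("max |z| theory vs simulation: %.2f", max(sim$abs_z)))
message("wrote results/03_*.tsv")
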