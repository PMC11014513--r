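# shared fixtures, built in code and memoized per test run

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, expr, envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small plain admixed cohort, no injected features
fixture_cohort <- function() {
  memo("cohort", {
    panel <- sim_frequency_panel(n_chrom = 4, m_per_chrom = 120, seed = 901)
    simulate_cohort(sim_config(n = 200, seed = 902), panel = panel)
  })
}

# the canonical contaminated cohort (multi-region feature, dense regions)
fixture_feature_cohort <- function() {
  memo("feature_cohort", simulate_feature_cohort(n = 500, seed = 903))
}

# independent all-pairs greedy pruning oracle: no windows/pointer logic,
# literal restatement of the rule the fast implementation must satisfy
brute_force_prune <- function(G, chrom, pos, r2, window) {
  kept <- integer(0)
  o <- order(chrom, pos)
  for (j in o) {
    ok <- TRUE
    for (k in kept) {
      if (chrom[k] == chrom[j] && abs(pos[k] - pos[j]) <= window &&
          stats::cor(G[, j], G[, k])^2 > r2) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, j)
  }
  sort(kept)
}

# exhaustive post-condition scan: TRUE iff no retained same-chromosome pair
# within the window has r^2 above the threshold
prune_postcondition_holds <- function(G, chrom, pos, kept, r2, window) {
  for (a in seq_along(kept)) {
    for (b in seq_len(a - 1)) {
      ja <- kept[a]; jb <- kept[b]
      if (chrom[ja] == chrom[jb] && abs(pos[ja] - pos[jb]) <= window &&
          stats::cor(G[, ja], G[, jb])^2 > r2) {
        return(FALSE)
      }
    }
  }
  TRUE
}
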