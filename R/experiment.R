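# orchestration of the two replicate simulation designs: the array-style
# design (PCs computed from the cohort under each pre-processing regime,
# causal variants chosen by loading/frequency-difference strata) and the
# sequence-style artificial-PC (collider) design

#' Stratify candidate causal variants
#'
#' Mirrors the causal-variant selection of the array-style design. Strata:
#' `top_loading` — for each PC, the `top_per_chrom` variants per chromosome
#' with the highest PC-genotype `|r|`; `low_loading` — variants whose
#' maximum `|r|` over the first PCs is below `low_loading_cutoff`;
#' `large_freq_diff` / `small_freq_diff` — variants with
#' `|p1 - p0| > large_diff` / `< small_diff`. A variant may appear in
#' several strata.
#'
#' @param diag a [pc_diagnostics()] computed from a regime-`none` PCA.
#' @param panel the cohort's [ancestral_panel()].
#' @param chrom per-variant chromosome labels.
#' @param top_per_chrom count per chromosome per PC for the top stratum.
#' @param low_loading_cutoff `|r|` ceiling for the low stratum.
#' @param large_diff,small_diff ancestral frequency-difference cutoffs.
#' @return `data.frame` with columns `variant`, `stratum`. Empty strata are
#'   dropped with a warning.
#' @export
select_causal_variants <- function(diag, panel, chrom,
                                   top_per_chrom = 10,
                                   low_loading_cutoff = 0.05,
                                   large_diff = 0.6, small_diff = 0.005) {
  stopifnot(inherits(diag, "pc_diagnostics"))
  ac <- diag$pc_variant_abs_corr
  stopifnot(nrow(ac) == nrow(panel), length(chrom) == nrow(panel))
  out <- list()
  top <- integer(0)
  for (j in seq_len(ncol(ac))) {
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      o <- idx[order(ac[idx, j], decreasing = TRUE)]
      top <- c(top, utils::head(o, top_per_chrom))
    }
  }
  out$top_loading <- unique(top)
  # monomorphic variants have no defined correlation: trivially low-loading
  maxr <- apply(ac, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r)) max(r) else -Inf
  })
  out$low_loading <- which(maxr < low_loading_cutoff)
  fd <- abs(panel$p1 - panel$p0)
  out$large_freq_diff <- which(fd > large_diff)
  out$small_freq_diff <- which(fd < small_diff)
  empty <- names(out)[vapply(out, length, integer(1)) == 0]
  if (length(empty)) {
    warning("empty causal-variant strata omitted: ",
            paste(empty, collapse = ", "))
  }
  out <- out[vapply(out, length, integer(1)) > 0]
  data.frame(variant = unlist(out, use.names = FALSE),
             stratum = rep(names(out), lengths(out)),
             stringsAsFactors = FALSE)
}

#' Configuration of a replicate simulation scenario
#'
#' @param cohort_config a [sim_config()] for the genotype cohort.
#' @param regimes pre-processing regimes whose PCs are used as covariates.
#' @param k_pcs PC counts to adjust for (array-style design).
#' @param beta_grid causal effect sizes to sweep.
#' @param n_replicates trait replicates per cell.
#' @param threshold genome-wide significance threshold.
#' @param artificial an [artificial_pc_spec()] (sequence-style design).
#' @param seed master seed.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(cohort_config = sim_config(),
                            regimes = c("none", "both"),
                            k_pcs = c(1, 4),
                            beta_grid = c(0, 0.25, 0.5, 1, 2, 4, 8),
                            n_replicates = 50,
                            threshold = 5e-8,
                            artificial = NULL,
                            seed = 1L) {
  stopifnot(n_replicates >= 1, threshold > 0, threshold < 1)
  structure(list(cohort_config = cohort_config, regimes = regimes,
                 k_pcs = k_pcs, beta_grid = beta_grid,
                 n_replicates = n_replicates, threshold = threshold,
                 artificial = artificial, seed = seed),
            class = "scenario_config")
}

# fit one strategy's GWAS and summarize: spurious count + lambda
gwas_cell <- function(y, cohort, w, causal_chrom, threshold) {
  res <- run_gwas(y, cohort$genotypes, w, cohort$panel$chrom,
                  cohort$panel$pos_bp)
  list(spurious = count_spurious(res, causal_chrom, threshold),
       lambda = genomic_control_lambda(res))
}

#' Array-style replicate design
#'
#' One genotype cohort is simulated from `config$cohort_config` (with
#' `config$seed`), PCs are computed under each requested regime, and for
#' every (causal variant, effect size, replicate) a fresh trait is drawn
#' and each covariate strategy is fit: no adjustment, the true genome-wide
#' average local ancestry, and the first `k` PCs per regime. Spurious
#' chromosome counts and genomic-control lambdas are recorded per cell.
#'
#' @param config a [scenario_config()].
#' @param causal_variants integer vector of causal variant column indices;
#'   by default the most feature-loaded variant and one low-loading variant.
#' @param panel optional [ancestral_panel()] for the cohort; a fresh default
#'   panel is drawn when omitted.
#' @return list of class `experiment_report` with elements `per_replicate`
#'   (long `data.frame`) and `summary` (mean spurious count and mean lambda
#'   per strategy x beta x causal variant), plus `flags` (per-regime
#'   local-feature flags) and `cohort`.
#' @export
run_array_design <- function(config, causal_variants = NULL, panel = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config$cohort_config
  cfg$seed <- child_seed(config$seed, 1)
  cohort <- simulate_cohort(cfg, panel = panel)
  panel <- cohort$panel
  pi_hat <- true_global_ancestry(cohort$ancestry)

  pcas <- list()
  flags <- list()
  for (rg in config$regimes) {
    ar <- apply_regime(cohort$genotypes, panel$chrom, panel$pos_bp, rg)
    X <- standardize_genotypes(cohort$genotypes[, ar$kept, drop = FALSE])
    pca <- run_pca(X, k = max(config$k_pcs), regime = rg)
    pcas[[rg]] <- pca
    dg <- pc_diagnostics(pca, cohort$genotypes, pi_hat, panel$chrom)
    flags[[rg]] <- dg$local_feature_flags
    if (rg == config$regimes[1]) diag_none <- dg
  }
  if (is.null(causal_variants)) {
    maxr <- apply(diag_none$pc_variant_abs_corr[, -1, drop = FALSE], 1, max)
    causal_variants <- c(which.max(maxr), which.min(maxr))
  }

  rows <- list()
  ri <- 0
  for (cv in causal_variants) {
    causal_chrom <- panel$chrom[cv]
    for (beta in config$beta_grid) {
      tp <- trait_params(cv, beta1 = beta, beta_pi = 0)
      for (rep in seq_len(config$n_replicates)) {
        ri <- ri + 1
        y <- simulate_trait(cohort$genotypes, cohort$pi, tp,
                            seed = child_seed(config$seed, 1000 + ri))
        strategies <- list(none = NULL, ancestry = cbind(pi = pi_hat))
        for (rg in config$regimes) {
          for (k in config$k_pcs) {
            strategies[[paste0("pc", k, "_", rg)]] <-
              pcas[[rg]]$scores[, seq_len(k), drop = FALSE]
          }
        }
        for (s in names(strategies)) {
          cell <- tryCatch(
            gwas_cell(y, cohort, strategies[[s]], causal_chrom,
                      config$threshold),
            error = function(e) list(spurious = NA_integer_,
                                     lambda = NA_real_))
          rows[[length(rows) + 1]] <- data.frame(
            causal_variant = cv, beta = beta, replicate = rep,
            strategy = s, spurious = cell$spurious, lambda = cell$lambda,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  per_replicate <- do.call(rbind, rows)
  summary <- stats::aggregate(
    cbind(spurious, lambda) ~ causal_variant + beta + strategy,
    data = per_replicate, FUN = mean)
  names(summary)[names(summary) == "spurious"] <- "mean_spurious"
  names(summary)[names(summary) == "lambda"] <- "mean_lambda"
  structure(list(per_replicate = per_replicate, summary = summary,
                 flags = flags, cohort = cohort),
            class = "experiment_report")
}

#' Sequence-style artificial-PC (collider) design
#'
#' One cohort is simulated; an extraneous component `z` loading on the
#' causal variant (`variant_a`) and a partner variant on a distinct
#' chromosome (`variant_b`) is constructed once; then for each replicate a
#' fresh trait depending only on the causal variant is drawn and two models
#' are compared: adjusting for global ancestry alone (`[pi]`) versus also
#' for the extraneous component (`[pi, z]`). Spurious chromosome counts,
#' whether the partner variant's chromosome is spurious, and lambda are
#' recorded per replicate. Default threshold 5e-9 (sequence-scale).
#'
#' @param config a [scenario_config()] whose `artificial` field is set and
#'   whose `beta_grid` first element is used as the causal effect size.
#' @param panel optional [ancestral_panel()]; drawn fresh when omitted.
#' @return list of class `experiment_report` with `per_replicate`,
#'   `summary` (per strategy: mean spurious count, rate of a hit on the
#'   partner chromosome, mean lambda), and `cohort`.
#' @export
run_sequence_design <- function(config, panel = NULL) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(config$artificial, "artificial_pc_spec"))
  a <- config$artificial
  cfg <- config$cohort_config
  cfg$seed <- child_seed(config$seed, 1)
  cohort <- simulate_cohort(cfg, panel = panel)
  panel <- cohort$panel
  if (panel$chrom[a$variant_a] == panel$chrom[a$variant_b]) {
    stop("artificial-PC variants must sit on distinct chromosomes",
         call. = FALSE)
  }
  pi_hat <- true_global_ancestry(cohort$ancestry)
  w_z <- build_covariates(
    covariate_spec("artificial", artificial = a),
    pi = pi_hat, genotypes = cohort$genotypes,
    seed = child_seed(config$seed, 2))
  beta <- config$beta_grid[1]
  tp <- trait_params(a$variant_a, beta1 = beta, beta_pi = 0)
  causal_chrom <- panel$chrom[a$variant_a]
  partner_chrom <- panel$chrom[a$variant_b]

  rows <- list()
  for (rep in seq_len(config$n_replicates)) {
    y <- simulate_trait(cohort$genotypes, cohort$pi, tp,
                        seed = child_seed(config$seed, 1000 + rep))
    for (s in c("pi", "pi_z")) {
      w <- if (s == "pi") cbind(pi = pi_hat) else w_z
      res <- run_gwas(y, cohort$genotypes, w, panel$chrom, panel$pos_bp)
      sig <- !is.na(res$pvalue) & res$pvalue < config$threshold
      rows[[length(rows) + 1]] <- data.frame(
        replicate = rep, strategy = s,
        spurious = count_spurious(res, causal_chrom, config$threshold),
        partner_hit = any(sig & res$chrom == partner_chrom),
        lambda = genomic_control_lambda(res),
        stringsAsFactors = FALSE)
    }
  }
  per_replicate <- do.call(rbind, rows)
  summary <- stats::aggregate(
    cbind(spurious, partner_hit, lambda) ~ strategy,
    data = per_replicate, FUN = mean)
  names(summary) <- c("strategy", "mean_spurious", "partner_hit_rate",
                      "mean_lambda")
  structure(list(per_replicate = per_replicate, summary = summary,
                 cohort = cohort),
            class = "experiment_report")
}

#' Manhattan-style ordered result table
#'
#' Orders a GWAS table by (chromosome, position) and adds `neg_log10_p` and
#' a significance flag (`pvalue < threshold`, strict).
#'
#' @param results a [run_gwas()] table.
#' @param threshold significance threshold.
#' @return the ordered `data.frame` with the extra columns.
#' @export
manhattan_table <- function(results, threshold = 5e-8) {
  stopifnot(nrow(results) >= 1)
  num_chrom <- suppressWarnings(as.numeric(normalize_chrom(results$chrom)))
  o <- order(if (any(is.na(num_chrom))) normalize_chrom(results$chrom)
             else num_chrom, results$pos_bp)
  out <- results[o, , drop = FALSE]
  out$neg_log10_p <- -log10(out$pvalue)
  out$significant <- !is.na(out$pvalue) & out$pvalue < threshold
  rownames(out) <- NULL
  out
}

#' Write an experiment report as tab-separated tables
#'
#' @param report an `experiment_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$summary, file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$per_replicate,
                     file.path(dir, "per_replicate.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
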