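# trait simulation, per-variant marginal regression with Wald tests,
# chromosome-level spurious-association counting, genomic-control lambda,
# and artificial-PC covariate construction

#' Trait-model parameters
#'
#' The generating model is
#' `y_i = beta1 * g_i,causal + beta_pi * pi_i + e_i`, `e_i ~ N(0, 1)`:
#' a single causal variant plus an optional direct effect of global
#' ancestry, with unit residual variance.
#'
#' @param causal_index column index of the causal variant.
#' @param beta1 causal effect size (trait units per allele).
#' @param beta_pi direct global-ancestry effect (trait units per unit pi).
#' @return a list of class `trait_params`.
#' @export
trait_params <- function(causal_index, beta1, beta_pi = 0) {
  stopifnot(length(causal_index) == 1, causal_index >= 1)
  structure(list(causal_index = as.integer(causal_index),
                 beta1 = beta1, beta_pi = beta_pi, residual_sd = 1),
            class = "trait_params")
}

#' Simulate a quantitative trait
#'
#' @param genotypes `n x m` dosage matrix.
#' @param pi admixture proportions (length `n`).
#' @param params a [trait_params()].
#' @param seed integer seed, or `NULL`.
#' @return numeric trait vector of length `n`.
#' @export
simulate_trait <- function(genotypes, pi, params, seed = NULL) {
  stopifnot(inherits(params, "trait_params"))
  if (params$causal_index > ncol(genotypes)) {
    stop("causal_index ", params$causal_index, " exceeds variant count ",
         ncol(genotypes), call. = FALSE)
  }
  n <- nrow(genotypes)
  g1 <- genotypes[, params$causal_index]
  with_seed_maybe(seed,
    params$beta1 * g1 + params$beta_pi * pi + stats::rnorm(n))
}

#' Specification of an artificial (extraneous) PC
#'
#' Constructs a component `z` that loads on exactly two variants on distinct
#' chromosomes — the situation in which an included PC becomes a collider:
#' `z = weight_a * std(g_a) + weight_b * std(g_b) + N(0, noise_sd^2)`,
#' where `std()` is sample standardization. Small `noise_sd` means tight
#' coupling between the component and the variants it captures.
#'
#' @param variant_a,variant_b column indices of the two variants.
#' @param weight_a,weight_b loading weights.
#' @param noise_sd added Gaussian noise standard deviation.
#' @return a list of class `artificial_pc_spec`.
#' @export
artificial_pc_spec <- function(variant_a, variant_b, weight_a = 1,
                               weight_b = 1, noise_sd = 0.2) {
  structure(list(variant_a = as.integer(variant_a),
                 variant_b = as.integer(variant_b),
                 weight_a = weight_a, weight_b = weight_b,
                 noise_sd = noise_sd),
            class = "artificial_pc_spec")
}

#' Covariate strategy for GWAS models
#'
#' @param kind one of `"none"` (no adjustment), `"ancestry"` (admixture
#'   proportion), `"pcs"` (first `k` PC score vectors), `"artificial"`
#'   (admixture proportion plus an extraneous component `z`).
#' @param k PC count when `kind = "pcs"`.
#' @param regime pre-processing regime tag for the PCs (bookkeeping only).
#' @param artificial an [artificial_pc_spec()] when `kind = "artificial"`.
#' @return a list of class `covariate_spec`.
#' @export
covariate_spec <- function(kind = c("none", "ancestry", "pcs", "artificial"),
                           k = 1, regime = NA_character_, artificial = NULL) {
  kind <- match.arg(kind)
  if (kind == "pcs" && k < 1) stop("k must be >= 1 for kind = 'pcs'",
                                   call. = FALSE)
  if (kind == "artificial" && !inherits(artificial, "artificial_pc_spec")) {
    stop("kind = 'artificial' requires an artificial_pc_spec", call. = FALSE)
  }
  structure(list(kind = kind, k = as.integer(k), regime = regime,
                 artificial = artificial),
            class = "covariate_spec")
}

#' Build the covariate matrix for a strategy
#'
#' @param spec a [covariate_spec()].
#' @param pca a [run_pca()] result (required for `kind = "pcs"`).
#' @param pi admixture proportions (required for `"ancestry"` and
#'   `"artificial"`).
#' @param genotypes dosage matrix (required for `"artificial"`).
#' @param seed integer seed for the artificial component's noise.
#' @return an `n x q` covariate matrix (`q = 0` for `kind = "none"`).
#' @export
build_covariates <- function(spec, pca = NULL, pi = NULL, genotypes = NULL,
                             seed = NULL) {
  stopifnot(inherits(spec, "covariate_spec"))
  switch(spec$kind,
    none = {
      n <- if (!is.null(pi)) length(pi) else nrow(genotypes)
      matrix(numeric(0), nrow = n, ncol = 0)
    },
    ancestry = {
      if (is.null(pi)) stop("kind = 'ancestry' requires pi", call. = FALSE)
      cbind(pi = pi)
    },
    pcs = {
      if (is.null(pca)) stop("kind = 'pcs' requires a pca result",
                             call. = FALSE)
      if (spec$k > ncol(pca$scores)) {
        stop("requested ", spec$k, " PCs but pca has ", ncol(pca$scores),
             call. = FALSE)
      }
      pca$scores[, seq_len(spec$k), drop = FALSE]
    },
    artificial = {
      if (is.null(pi) || is.null(genotypes)) {
        stop("kind = 'artificial' requires pi and genotypes", call. = FALSE)
      }
      a <- spec$artificial
      z <- with_seed_maybe(seed, {
        a$weight_a * as.numeric(scale(genotypes[, a$variant_a])) +
          a$weight_b * as.numeric(scale(genotypes[, a$variant_b])) +
          stats::rnorm(length(pi), 0, a$noise_sd)
      })
      cbind(pi = pi, z = z)
    })
}

#' Fit the marginal association model at one variant
#'
#' Ordinary least squares for `y ~ 1 + g + w` with the classical
#' homoskedastic variance estimate; the Wald statistic `beta / se` is
#' referred to the standard normal for a two-sided p-value.
#'
#' @param y trait vector.
#' @param g dosage vector for the tested variant.
#' @param w covariate matrix (or `NULL`).
#' @return list with `beta`, `se`, `wald`, `pvalue`.
#' @export
fit_marginal <- function(y, g, w = NULL) {
  X <- cbind(`(Intercept)` = 1, g = g, w)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("design is rank deficient at the tested variant ",
         "(genotype collinear with covariates)", call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- solve(crossprod(X))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  beta <- unname(fit$coefficients["g"])
  wald <- beta / se
  list(beta = beta, se = se, wald = wald,
       pvalue = 2 * stats::pnorm(-abs(wald)))
}

#' Genome-wide marginal regression scan
#'
#' Applies the marginal model at every variant. Implemented by residualizing
#' the trait and all dosage columns on `[1, w]` (Frisch-Waugh), which
#' reproduces the per-variant OLS fit exactly. Variants collinear with the
#' covariates (including monomorphic variants) are reported with missing
#' statistics rather than dropped, keeping per-chromosome bookkeeping
#' stable.
#'
#' @param y trait vector.
#' @param genotypes `n x m` dosage matrix.
#' @param w covariate matrix (or `NULL`).
#' @param chrom,pos_bp per-variant labels and positions.
#' @return `data.frame` with columns `chrom`, `pos_bp`, `beta`, `se`,
#'   `wald`, `pvalue` (class `gwas_result`).
#' @export
run_gwas <- function(y, genotypes, w = NULL, chrom, pos_bp) {
  n <- length(y)
  m <- ncol(genotypes)
  stopifnot(nrow(genotypes) == n, length(chrom) == m, length(pos_bp) == m)
  Xw <- cbind(rep(1, n), w)
  Q <- qr.Q(qr(Xw))
  yt <- y - Q %*% crossprod(Q, y)
  Gt <- genotypes - Q %*% crossprod(Q, genotypes)
  den <- colSums(Gt^2)
  tot <- colSums(scale(genotypes, scale = FALSE)^2)
  ok <- den > pmax(tot, 1) * 1e-10
  num <- as.numeric(crossprod(Gt, yt))
  beta <- ifelse(ok, num / den, NA_real_)
  rss <- sum(yt^2) - ifelse(ok, beta^2 * den, 0)
  df <- n - ncol(Xw) - 1
  se <- ifelse(ok, sqrt(rss / df / den), NA_real_)
  wald <- beta / se
  out <- data.frame(chrom = as.character(chrom), pos_bp = pos_bp,
                    beta = beta, se = se, wald = wald,
                    pvalue = 2 * stats::pnorm(-abs(wald)),
                    stringsAsFactors = FALSE)
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Count spurious chromosomes
#'
#' The chromosome-level spurious-association statistic: the number of
#' distinct chromosomes, excluding the causal variant's chromosome, that
#' contain at least one variant with `pvalue < threshold` (strict
#' inequality). Counting at the chromosome level avoids multiple counting
#' of variants in mutual LD.
#'
#' @param results a [run_gwas()] table.
#' @param causal_chrom chromosome label of the causal variant.
#' @param threshold genome-wide significance threshold; 5e-8 is the
#'   conventional array-scale value and 5e-9 the sequence-scale value.
#' @return integer count.
#' @export
count_spurious <- function(results, causal_chrom, threshold = 5e-8) {
  stopifnot(nrow(results) >= 1)
  sig <- !is.na(results$pvalue) & results$pvalue < threshold
  hit <- normalize_chrom(results$chrom[sig])
  length(setdiff(unique(hit), normalize_chrom(causal_chrom)))
}

#' Genomic-control inflation factor
#'
#' `lambda = median(wald^2) / median(chi^2_1)`; the null median of a 1-df
#' chi-square is `qchisq(0.5, 1) = 0.4549...`. Because it is a median,
#' lambda is insensitive to a handful of extreme statistics — which is why
#' localized collider-induced spurious associations do not show up in it.
#'
#' @param results a [run_gwas()] table.
#' @return numeric lambda.
#' @export
genomic_control_lambda <- function(results) {
  w2 <- results$wald[!is.na(results$wald)]^2
  if (length(w2) == 0) stop("no valid Wald statistics", call. = FALSE)
  stats::median(w2) / stats::qchisq(0.5, 1)
}
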