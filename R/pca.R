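# PCA of standardized genotypes and the diagnostics used to decide whether
# each PC captures genome-wide ancestry or a local genomic feature

#' Standardize a genotype dosage matrix
#'
#' Classical allele-frequency scaling:
#' `x_ij = (g_ij - 2 p_j) / sqrt(2 p_j (1 - p_j))` with `p_j` the sample
#' allele frequency of variant `j`. Columns have mean exactly zero.
#'
#' @param genotypes `n x m` dosage matrix without monomorphic columns.
#' @return the standardized `n x m` matrix.
#' @export
standardize_genotypes <- function(genotypes) {
  p <- colMeans(genotypes) / 2
  bad <- which(p == 0 | p == 1)
  if (length(bad)) {
    stop("monomorphic variant(s) cannot be standardized (first index ",
         bad[1], "); filter before calling", call. = FALSE)
  }
  sweep(sweep(genotypes, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
}

#' PCA of a standardized genotype matrix
#'
#' Computes the top `k` principal components of `X` as the singular value
#' decomposition `X = U D V'`, equivalently the eigendecomposition of the
#' genetic relationship matrix `X X' / m`. When `m > n` the `n x n`
#' eigendecomposition route is used. PC score vectors (`U` columns) have
#' unit norm; eigenvalues are those of `X X' / m` so their scale is free of
#' the variant count; loadings are the `V` columns (`X' u_k / d_k`). The
#' sign of each PC is fixed so its largest-magnitude score entry is
#' positive.
#'
#' @param X standardized genotype matrix (`n x m`).
#' @param k number of components, `1 <= k <= min(n, m)`.
#' @param regime optional tag recording the pre-processing regime used.
#' @return an object of class `genotype_pca`: list with `scores` (`n x k`),
#'   `eigenvalues` (all `min(n, m)` eigenvalues of `X X' / m`,
#'   non-increasing), `loadings` (`m x k`), `d` (singular values for the
#'   top `k`), `n_variants_used`, `regime`.
#' @export
run_pca <- function(X, k = 4, regime = NA_character_) {
  n <- nrow(X)
  m <- ncol(X)
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)
  if (k < 1 || k > min(n, m)) {
    stop("k must lie in [1, min(n, m)]", call. = FALSE)
  }
  if (m >= n) {
    K <- tcrossprod(X) / m
    eg <- eigen(K, symmetric = TRUE)
    lambda <- pmax(eg$values, 0)
    U <- eg$vectors[, seq_len(k), drop = FALSE]
    d <- sqrt(lambda[seq_len(k)] * m)
  } else {
    sv <- svd(X)
    lambda <- sv$d^2 / m
    U <- sv$u[, seq_len(k), drop = FALSE]
    d <- sv$d[seq_len(k)]
  }
  # deterministic sign: largest-|score| entry of each PC is positive
  for (j in seq_len(k)) {
    s <- sign(U[which.max(abs(U[, j])), j])
    if (s < 0) U[, j] <- -U[, j]
  }
  V <- crossprod(X, U)
  V <- sweep(V, 2, pmax(d, .Machine$double.eps), "/")
  colnames(U) <- colnames(V) <- paste0("PC", seq_len(k))
  structure(list(scores = U, eigenvalues = lambda, loadings = V, d = d,
                 n_variants_used = m, regime = regime),
            class = "genotype_pca")
}

#' Absolute correlation between PCs and variant dosages
#'
#' The per-variant diagnostic of record: Pearson `|r|` between each PC score
#' vector and each variant's dosages. Zero-variance variants are reported as
#' `NA`, not 0.
#'
#' @param pca a [run_pca()] result.
#' @param genotypes `n x m` dosage matrix (any variant set; need not be the
#'   set the PCA was run on).
#' @return `m x k` matrix of `|r|` values.
#' @export
pc_variant_correlation <- function(pca, genotypes) {
  stopifnot(inherits(pca, "genotype_pca"),
            nrow(genotypes) == nrow(pca$scores))
  v <- matrixStats_colVars(genotypes)
  ok <- v > 0
  out <- matrix(NA_real_, ncol(genotypes), ncol(pca$scores))
  if (any(ok)) {
    out[ok, ] <- abs(stats::cor(genotypes[, ok, drop = FALSE], pca$scores))
  }
  colnames(out) <- colnames(pca$scores)
  out
}

# column variances without an extra dependency
matrixStats_colVars <- function(x) {
  mu <- colMeans(x)
  (colSums(x^2) - nrow(x) * mu^2) / (nrow(x) - 1)
}

#' Signed correlation between PCs and admixture proportions
#'
#' @param pca a [run_pca()] result.
#' @param pi admixture-proportion vector (length `n`).
#' @return named numeric vector, one correlation per PC.
#' @export
pc_ancestry_correlation <- function(pca, pi) {
  stopifnot(inherits(pca, "genotype_pca"), length(pi) == nrow(pca$scores))
  if (stats::sd(pi) == 0) {
    stop("pi is constant; PC-ancestry correlation undefined", call. = FALSE)
  }
  drop(stats::cor(pi, pca$scores))
}

#' Per-PC diagnostics
#'
#' Bundles the PC-genotype correlations, the PC-ancestry correlations,
#' the per-chromosome maximum `|r|` per PC, and the local-feature flags.
#'
#' @param pca a [run_pca()] result.
#' @param genotypes `n x m` dosage matrix.
#' @param pi admixture proportions.
#' @param chrom per-variant chromosome labels (length `m`).
#' @param corr_peak_threshold,ancestry_corr_floor passed to
#'   [flag_local_feature_pcs()].
#' @return list of class `pc_diagnostics` with `pc_variant_abs_corr`
#'   (`m x k`), `pc_ancestry_corr`, `chrom_max_abs_corr`
#'   (chromosomes x k), `local_feature_flags`.
#' @export
pc_diagnostics <- function(pca, genotypes, pi, chrom,
                           corr_peak_threshold = 0.3,
                           ancestry_corr_floor = 0.5) {
  stopifnot(length(chrom) == ncol(genotypes))
  ac <- pc_variant_correlation(pca, genotypes)
  chroms <- unique(as.character(chrom))
  cm <- t(vapply(chroms, function(ch) {
    apply(ac[chrom == ch, , drop = FALSE], 2, max, na.rm = TRUE)
  }, numeric(ncol(ac))))
  rownames(cm) <- chroms
  diag <- structure(list(pc_variant_abs_corr = ac,
                         pc_ancestry_corr = pc_ancestry_correlation(pca, pi),
                         chrom_max_abs_corr = cm,
                         local_feature_flags = NULL),
                    class = "pc_diagnostics")
  diag$local_feature_flags <- flag_local_feature_pcs(
    diag, corr_peak_threshold, ancestry_corr_floor)
  diag
}

#' Flag PCs that capture local genomic features
#'
#' Operationalizes visual inspection of loading plots: a PC is flagged iff
#' its maximum `|r|` with any single variant is at least
#' `corr_peak_threshold` (a pronounced peak) while its `|correlation|` with
#' global ancestry is below `ancestry_corr_floor` (so the PC is not an
#' ancestry axis). An ancestry PC spreads its correlation thinly across the
#' genome; a feature PC concentrates on the variants it captures.
#'
#' @param diag a [pc_diagnostics()] result (the flags it already contains
#'   are ignored; they are recomputed from the thresholds given here).
#' @param corr_peak_threshold peak height `tau` (default 0.3).
#' @param ancestry_corr_floor ancestry-correlation floor `rho` (default 0.5).
#' @return named logical vector, one flag per PC.
#' @export
flag_local_feature_pcs <- function(diag, corr_peak_threshold = 0.3,
                                   ancestry_corr_floor = 0.5) {
  stopifnot(inherits(diag, "pc_diagnostics"))
  peak <- apply(diag$pc_variant_abs_corr, 2, max, na.rm = TRUE)
  peak >= corr_peak_threshold &
    abs(diag$pc_ancestry_corr) < ancestry_corr_floor
}
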