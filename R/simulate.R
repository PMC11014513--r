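# synthetic admixed-cohort generator: heterogeneous admixture proportions,
# local ancestry (independent or block model), population-conditional
# genotypes, and injectable localized-LD features

#' Draw admixture proportions from a Beta distribution
#'
#' Admixture proportions (the genome-wide fraction of each genome inherited
#' from ancestral population 1) are drawn from a Beta distribution
#' parameterized by its mean and standard deviation. `sd = 0` gives the
#' degenerate point mass at `mean`.
#'
#' @param n number of individuals.
#' @param mean target mean, in `(0, 1)`.
#' @param sd target standard deviation; must satisfy `sd^2 < mean * (1 - mean)`.
#' @param seed integer seed, or `NULL`.
#' @return numeric vector of length `n` with values in `[0, 1]`.
#' @export
draw_admixture_proportions <- function(n, mean = 0.8, sd = 0.1, seed = NULL) {
  stopifnot(n >= 1)
  if (mean <= 0 || mean >= 1) {
    stop("admixture mean must lie in (0, 1)", call. = FALSE)
  }
  if (sd < 0 || sd^2 >= mean * (1 - mean)) {
    stop("admixture sd must satisfy sd^2 < mean * (1 - mean) ",
         "(valid Beta moments)", call. = FALSE)
  }
  if (sd == 0) return(rep(mean, n))
  nu <- mean * (1 - mean) / sd^2 - 1
  with_seed_maybe(seed, stats::rbeta(n, mean * nu, (1 - mean) * nu))
}

#' Draw local-ancestry copy counts
#'
#' Returns the number of allele copies (0/1/2) inherited from ancestral
#' population 1, per individual per variant. In `"independent"` mode each of
#' the two copies at each variant is from population 1 with probability
#' `pi[i]`, independently across variants. In `"block"` mode each haplotype
#' of each chromosome is cut by a Poisson crossover process with rate
#' `generations` per Morgan (physical positions mapped at `cm_per_mb`
#' centimorgan per megabase, uniform map, no interference) and each segment
#' is assigned population 1 with probability `pi[i]`. Both modes satisfy
#' `E[a_ij] = 2 * pi[i]`.
#'
#' For block mode, the per-haplotype genome-wide crossover counts are
#' returned in `attr(, "n_crossovers")` (an `n x 2` integer matrix).
#'
#' @param pi vector of admixture proportions in `[0, 1]`.
#' @param panel an [ancestral_panel()] giving variant positions.
#' @param mode `"independent"` or `"block"`.
#' @param generations admixture age in generations (block mode), `>= 1`.
#' @param cm_per_mb recombination-map density (centimorgan per megabase).
#' @param seed integer seed, or `NULL`.
#' @return integer matrix `n x m` of population-1 copy counts.
#' @export
draw_local_ancestry <- function(pi, panel, mode = c("independent", "block"),
                                generations = 6, cm_per_mb = 1, seed = NULL) {
  mode <- match.arg(mode)
  check_prob(pi, "pi")
  stopifnot(inherits(panel, "ancestral_panel"))
  n <- length(pi)
  m <- nrow(panel)
  with_seed_maybe(seed, {
    if (mode == "independent") {
      a <- matrix(stats::rbinom(n * m, 2L, rep(pi, times = m)), n, m)
      return(a)
    }
    if (generations < 1) stop("generations must be >= 1 in block mode",
                              call. = FALSE)
    # map positions to Morgans; crossovers ~ Poisson(generations * length)
    chroms <- unique(panel$chrom)
    a <- matrix(0L, n, m)
    xo <- matrix(0L, n, 2)
    for (ch in chroms) {
      idx <- which(panel$chrom == ch)
      pos_m <- panel$pos_bp[idx] * cm_per_mb / 1e8  # bp -> Morgans
      len <- max(pos_m)
      for (i in seq_len(n)) {
        for (h in 1:2) {
          k <- stats::rpois(1, generations * len)
          cuts <- sort(stats::runif(k, 0, len))
          seg <- findInterval(pos_m, cuts) + 1L
          anc <- stats::rbinom(k + 1L, 1L, pi[i])
          a[i, idx] <- a[i, idx] + anc[seg]
          xo[i, h] <- xo[i, h] + k
        }
      }
    }
    attr(a, "n_crossovers") <- xo
    a
  })
}

#' Draw genotype dosages given local ancestry
#'
#' Each allele copy is Bernoulli with the allele frequency of the ancestral
#' population it was inherited from: `p1[j]` for population-1 copies and
#' `p0[j]` otherwise. The dosage is the sum over the two copies.
#'
#' @param ancestry integer matrix `n x m` of population-1 copy counts.
#' @param panel an [ancestral_panel()] with `m` rows.
#' @param seed integer seed, or `NULL`.
#' @return integer matrix `n x m` of dosages in `{0, 1, 2}`.
#' @export
draw_genotypes <- function(ancestry, panel, seed = NULL) {
  stopifnot(inherits(panel, "ancestral_panel"))
  if (ncol(ancestry) != nrow(panel)) {
    stop("ancestry has ", ncol(ancestry), " variants but panel has ",
         nrow(panel), call. = FALSE)
  }
  n <- nrow(ancestry)
  m <- ncol(ancestry)
  with_seed_maybe(seed, {
    p1 <- rep(panel$p1, each = n)
    p0 <- rep(panel$p0, each = n)
    a <- as.vector(ancestry)
    g <- stats::rbinom(n * m, a, p1) + stats::rbinom(n * m, 2L - a, p0)
    matrix(g, n, m)
  })
}

#' Specify a localized linkage-disequilibrium feature
#'
#' A feature is a latent diploid factor shared by all variants it spans:
#' with probability `coupling`, each in-region variant's genotype is replaced
#' by the latent factor's dosage. Features may span several regions on
#' different chromosomes, emulating structures (inversions, regions of
#' unusual LD) that principal components can latch onto. The latent allele
#' has its own ancestral frequencies, so features can be ancestry-informative
#' (`latent_freq0 != latent_freq1`) or ancestry-neutral.
#'
#' @param regions `data.frame` with columns `chrom`, `start_bp`, `end_bp`
#'   (1-based closed intervals).
#' @param latent_freq0,latent_freq1 latent-allele frequency in each ancestral
#'   population, in `[0, 1]`.
#' @param coupling probability in `[0, 1]` that an in-region variant is
#'   copied from the latent factor.
#' @return an object of class `ld_feature_spec`.
#' @export
ld_feature_spec <- function(regions, latent_freq0 = 0.5, latent_freq1 = 0.5,
                            coupling = 0.9) {
  stopifnot(is.data.frame(regions), nrow(regions) >= 1,
            all(c("chrom", "start_bp", "end_bp") %in% names(regions)))
  if (any(regions$start_bp > regions$end_bp) || any(regions$start_bp < 1)) {
    stop("invalid region coordinates", call. = FALSE)
  }
  check_prob(coupling, "coupling")
  check_prob(latent_freq0, "latent_freq0")
  check_prob(latent_freq1, "latent_freq1")
  structure(list(regions = regions, latent_freq0 = latent_freq0,
                 latent_freq1 = latent_freq1, coupling = coupling),
            class = "ld_feature_spec")
}

#' Inject a localized LD feature into a cohort
#'
#' Draws the latent diploid factor `h_i` (two copies, each with ancestry
#' Bernoulli(`pi[i]`) and allele frequency `latent_freq` of that ancestry),
#' then, for each variant falling inside any spec region, independently per
#' variant replaces its genotype column by `h` with probability `coupling`.
#' The realized latent genotypes are appended to `cohort$latent`.
#'
#' @param cohort an `admix_cohort`.
#' @param spec an [ld_feature_spec()].
#' @param seed integer seed, or `NULL`.
#' @return the modified cohort.
#' @export
inject_ld_feature <- function(cohort, spec, seed = NULL) {
  stopifnot(inherits(cohort, "admix_cohort"), inherits(spec, "ld_feature_spec"))
  panel <- cohort$panel
  in_region <- rep(FALSE, nrow(panel))
  pchrom <- normalize_chrom(panel$chrom)
  for (r in seq_len(nrow(spec$regions))) {
    in_region <- in_region |
      (pchrom == normalize_chrom(spec$regions$chrom[r]) &
         panel$pos_bp >= spec$regions$start_bp[r] &
         panel$pos_bp <= spec$regions$end_bp[r])
  }
  idx <- which(in_region)
  if (length(idx) == 0) {
    warning("feature regions contain no panel variants; cohort unchanged")
    return(cohort)
  }
  n <- nrow(cohort$genotypes)
  with_seed_maybe(seed, {
    anc <- stats::rbinom(n, 1L, cohort$pi) + stats::rbinom(n, 1L, cohort$pi)
    # anc = number of population-1 copies of the latent locus
    h <- stats::rbinom(n, anc, spec$latent_freq1) +
      stats::rbinom(n, 2L - anc, spec$latent_freq0)
    replace <- matrix(stats::rbinom(n * length(idx), 1L, spec$coupling),
                      n, length(idx)) == 1L
    g <- cohort$genotypes[, idx, drop = FALSE]
    g[replace] <- rep(h, times = length(idx))[replace]
    cohort$genotypes[, idx] <- g
    cohort$latent <- c(cohort$latent,
                       list(list(spec = spec, h = h, variants = idx)))
    cohort
  })
}

#' Genome-wide average local ancestry
#'
#' The true global-ancestry fraction per individual:
#' `(1 / (2m)) * sum_j a_ij` for population 1; the population-0 fraction is
#' its complement.
#'
#' @param ancestry integer matrix `n x m` of population-1 copy counts.
#' @return numeric vector of length `n` in `[0, 1]`.
#' @export
true_global_ancestry <- function(ancestry) {
  if (is.null(dim(ancestry)) || ncol(ancestry) == 0 || nrow(ancestry) == 0) {
    stop("ancestry matrix is empty", call. = FALSE)
  }
  rowMeans(ancestry) / 2
}

#' Simulation configuration for an admixed cohort
#'
#' Defaults emulate an African-American-like cohort: mean African ancestry
#' 0.8 with considerable inter-individual variability (sd 0.1), ten
#' 130-Mb chromosomes with 500 variants each, ancestral allele frequencies
#' differentiated at effective Fst 0.35.
#'
#' @param n number of individuals.
#' @param admixture_mean,admixture_sd Beta moments of the admixture
#'   proportion distribution.
#' @param ancestry_mode `"independent"` or `"block"`.
#' @param generations admixture age (block mode).
#' @param cm_per_mb uniform recombination-map density.
#' @param features list of [ld_feature_spec()] objects to inject.
#' @param seed master integer seed for the whole cohort, or `NULL`.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n = 1000, admixture_mean = 0.8, admixture_sd = 0.1,
                       ancestry_mode = "independent", generations = 6,
                       cm_per_mb = 1, features = list(), seed = NULL) {
  stopifnot(n >= 1)
  structure(list(n = n, admixture_mean = admixture_mean,
                 admixture_sd = admixture_sd, ancestry_mode = ancestry_mode,
                 generations = generations, cm_per_mb = cm_per_mb,
                 features = features, seed = seed),
            class = "sim_config")
}

#' Simulate an admixed cohort
#'
#' Draws admixture proportions, local ancestry, and genotypes, then injects
#' any configured LD features. All randomness derives from `config$seed`
#' through [child_seed()] streams (1 = admixture, 2 = ancestry,
#' 3 = genotypes, 10 + k = feature k), so components are individually
#' reproducible.
#'
#' @param config a [sim_config()].
#' @param panel an [ancestral_panel()]; by default a fresh
#'   [sim_frequency_panel()] drawn on stream 0.
#' @return an object of class `admix_cohort`: a list with elements `pi`,
#'   `ancestry`, `genotypes`, `panel`, `latent`.
#' @export
simulate_cohort <- function(config = sim_config(), panel = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  sub <- function(k) if (is.null(seed)) NULL else child_seed(seed, k)
  if (is.null(panel)) panel <- sim_frequency_panel(seed = sub(0))
  pi <- draw_admixture_proportions(config$n, config$admixture_mean,
                                   config$admixture_sd, seed = sub(1))
  ancestry <- draw_local_ancestry(pi, panel, config$ancestry_mode,
                                  config$generations, config$cm_per_mb,
                                  seed = sub(2))
  genotypes <- draw_genotypes(ancestry, panel, seed = sub(3))
  cohort <- structure(list(pi = pi, ancestry = ancestry,
                           genotypes = genotypes, panel = panel,
                           latent = list()),
                      class = "admix_cohort")
  for (k in seq_along(config$features)) {
    cohort <- inject_ld_feature(cohort, config$features[[k]],
                                seed = sub(10 + k))
  }
  cohort
}

#' Canonical multi-region LD-feature scenario
#'
#' Builds the study's reference "contaminated" cohort: the default admixed
#' cohort plus three independent latent features, one per 0.4-Mb region on
#' distinct chromosomes — two inside bundled high-LD regions (the
#' LCT-region interval on chromosome 2 and the HLA interval on chromosome 6)
#' and one outside any bundled region (chromosome 9) — each locally
#' densified to `n_dense` variants so the features carry enough weight to
#' reach the top PCs. The latent alleles are ancestry-neutral
#' (`latent_freq0 = latent_freq1 = 0.5`): pure local structure, orthogonal
#' to global ancestry.
#'
#' Because the three region factors are independent with near-equal
#' variance share, their eigenvalues are nearly degenerate and the
#' corresponding PCs come out as mixtures loading on several regions at
#' once — the multi-peak pattern that makes an included PC a collider. And
#' because each region fits inside the default 0.5-Mb pruning window, LD
#' pruning thins every feature to about one variant per region, which is
#' the mechanism by which pruning stops PCs from capturing them.
#'
#' @param n individuals.
#' @param coupling feature coupling strength.
#' @param n_dense extra variants per feature region.
#' @param seed master seed.
#' @return an `admix_cohort` with the features injected.
#' @export
simulate_feature_cohort <- function(n = 500, coupling = 0.9, n_dense = 15,
                                    seed = NULL) {
  regions <- data.frame(chrom = c("2", "6", "9"),
                        start_bp = c(131e6, 30e6, 95e6),
                        end_bp = c(131.4e6, 30.4e6, 95.4e6))
  panel <- sim_frequency_panel(
    dense_regions = cbind(regions, n_variants = n_dense),
    seed = if (is.null(seed)) NULL else child_seed(seed, 0))
  feats <- lapply(seq_len(nrow(regions)), function(r) {
    ld_feature_spec(regions[r, , drop = FALSE], latent_freq0 = 0.5,
                    latent_freq1 = 0.5, coupling = coupling)
  })
  simulate_cohort(sim_config(n = n, features = feats, seed = seed),
                  panel = panel)
}

#' @method print admix_cohort
#' @export
print.admix_cohort <- function(x, ...) {
  cat("admix_cohort:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "variants on",
      length(unique(x$panel$chrom)), "chromosomes\n")
  cat("  mean ancestry (pop 1):", round(mean(x$pi), 3),
      " sd:", round(stats::sd(x$pi), 3), "\n")
  if (length(x$latent)) {
    cat("  injected LD features:", length(x$latent), "\n")
  }
  invisible(x)
}
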