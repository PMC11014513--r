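# pre-PCA variant filtering: high-LD region exclusion, windowed r^2 LD
# pruning, MAF filtering, and the four composed regimes

#' Bundled list of high-LD regions (genome build 38)
#'
#' Eighteen regions of the genome with high, long-range, or otherwise
#' unusual linkage disequilibrium that the literature recommends excluding
#' before PCA (including the LCT locus, the HLA region, and the large
#' inversions on 8p23 and 17q21). Coordinates are 1-based closed intervals
#' on genome build 38.
#'
#' @return a `data.frame` with columns `chrom`, `start_bp`, `end_bp`,
#'   `label`, and attribute `build = "38"`.
#' @export
high_ld_regions <- function() {
  path <- system.file("extdata", "high_ld_regions_b38.tsv",
                      package = "admixpca", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "integer",
                                         "character"))
  attr(df, "build") <- "38"
  df
}

#' Convert a 1-based closed region list to BED intervals
#'
#' BED uses 0-based half-open coordinates, so `start` is decremented by one
#' and `end` is kept.
#'
#' @param regions `data.frame` with `chrom`, `start_bp`, `end_bp`.
#' @param path optional file to write (tab-separated, no header).
#' @return a `data.frame` with `chrom`, `start`, `end` (BED convention).
#' @export
regions_to_bed <- function(regions, path = NULL) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start_bp - 1L,
                    end = regions$end_bp)
  if (!is.null(path)) {
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  bed
}

#' Keep-mask for variants outside a region list
#'
#' A variant is excluded iff some region on the same chromosome satisfies
#' `start_bp <= pos <= end_bp` (closed interval, both endpoints excluded).
#' Chromosome labels are normalized so `"chr6"` and `"6"` match.
#'
#' @param chrom per-variant chromosome labels.
#' @param pos_bp per-variant 1-based positions.
#' @param regions region `data.frame` (e.g. [high_ld_regions()]).
#' @return logical keep mask of length `length(chrom)`.
#' @export
exclude_regions <- function(chrom, pos_bp, regions) {
  stopifnot(length(chrom) == length(pos_bp))
  keep <- rep(TRUE, length(chrom))
  if (is.null(regions) || nrow(regions) == 0) return(keep)
  vchrom <- normalize_chrom(chrom)
  rchrom <- normalize_chrom(regions$chrom)
  for (r in seq_len(nrow(regions))) {
    keep <- keep & !(vchrom == rchrom[r] &
                       pos_bp >= regions$start_bp[r] &
                       pos_bp <= regions$end_bp[r])
  }
  keep
}

#' LD-pruning parameters
#'
#' @param r2_threshold squared-correlation cutoff in `(0, 1]`; the stricter
#'   0.1 (rather than the commonly used 0.2) is the default, which admixed
#'   cohorts typically require.
#' @param window_bp physical window size in bp (default 0.5 Mb).
#' @return a list of class `prune_params`.
#' @export
prune_params <- function(r2_threshold = 0.1, window_bp = 5e5) {
  if (r2_threshold <= 0 || r2_threshold > 1) {
    stop("r2_threshold must lie in (0, 1]", call. = FALSE)
  }
  if (window_bp <= 0) stop("window_bp must be positive", call. = FALSE)
  structure(list(r2_threshold = r2_threshold, window_bp = window_bp),
            class = "prune_params")
}

#' Greedy windowed LD pruning
#'
#' Deterministic single forward pass in position order within each
#' chromosome: a candidate variant is dropped iff its squared Pearson
#' correlation (on unphased dosages, i.e. composite LD) with any
#' already-retained variant on the same chromosome within `window_bp`
#' exceeds `r2_threshold`. On conflict the earlier-position variant wins.
#' Every retained same-chromosome pair within the window is guaranteed to
#' have `r^2 <= r2_threshold`.
#'
#' @param genotypes `n x m` dosage matrix; all columns must have positive
#'   variance (drop monomorphic variants first, e.g. via [maf_filter()]).
#' @param chrom,pos_bp per-variant labels and positions.
#' @param params a [prune_params()].
#' @return integer vector of kept variant indices (in input order).
#' @export
ld_prune <- function(genotypes, chrom, pos_bp, params = prune_params()) {
  m <- ncol(genotypes)
  stopifnot(length(chrom) == m, length(pos_bp) == m, m >= 1)
  v <- apply(genotypes, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance variant(s) reached ld_prune (index ",
         which(v == 0)[1], "); remove monomorphic variants first",
         call. = FALSE)
  }
  kept <- integer(0)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    idx <- idx[order(pos_bp[idx])]
    kept_ch <- integer(0)
    kept_pos <- numeric(0)
    for (j in idx) {
      near <- kept_ch[abs(kept_pos - pos_bp[j]) <= params$window_bp]
      drop <- FALSE
      if (length(near)) {
        r <- suppressWarnings(
          stats::cor(genotypes[, j], genotypes[, near, drop = FALSE]))
        drop <- any(r^2 > params$r2_threshold, na.rm = TRUE)
      }
      if (!drop) {
        kept_ch <- c(kept_ch, j)
        kept_pos <- c(kept_pos, pos_bp[j])
      }
    }
    kept <- c(kept, kept_ch)
  }
  sort(kept)
}

#' Minor-allele-frequency keep mask
#'
#' A variant is kept iff `min(p, 1 - p) >= min_maf` where `p` is the sample
#' allele frequency (mean dosage / 2).
#'
#' @param genotypes `n x m` dosage matrix with values in `[0, 2]`.
#' @param min_maf frequency threshold (default 0.01).
#' @return logical keep mask of length `m`.
#' @export
maf_filter <- function(genotypes, min_maf = 0.01) {
  p <- colMeans(genotypes) / 2
  pmin(p, 1 - p) >= min_maf
}

#' Apply a pre-processing regime
#'
#' Composes the filters in order MAF -> region exclusion (regimes `exclude`
#' and `both`) -> LD pruning (regimes `prune` and `both`) and returns the
#' surviving variant indices together with per-stage counts.
#'
#' @param genotypes `n x m` dosage matrix.
#' @param chrom,pos_bp per-variant labels and positions.
#' @param regime one of `"none"`, `"exclude"`, `"prune"`, `"both"`.
#' @param regions region list for the exclusion stage
#'   (default [high_ld_regions()]).
#' @param params [prune_params()] for the pruning stage.
#' @param min_maf MAF threshold applied in every regime.
#' @return list with `kept` (integer indices into the input columns),
#'   `counts` (named per-stage variant counts), and `regime`.
#' @export
apply_regime <- function(genotypes, chrom, pos_bp,
                         regime = c("none", "exclude", "prune", "both"),
                         regions = high_ld_regions(),
                         params = prune_params(), min_maf = 0.01) {
  regime <- match.arg(regime)
  m <- ncol(genotypes)
  kept <- which(maf_filter(genotypes, min_maf))
  counts <- c(input = m, maf = length(kept))
  if (regime %in% c("exclude", "both")) {
    mask <- exclude_regions(chrom[kept], pos_bp[kept], regions)
    kept <- kept[mask]
    counts <- c(counts, exclude = length(kept))
  }
  if (regime %in% c("prune", "both")) {
    pk <- ld_prune(genotypes[, kept, drop = FALSE], chrom[kept],
                   pos_bp[kept], params)
    kept <- kept[pk]
    counts <- c(counts, prune = length(kept))
  }
  if (length(kept) == 0) {
    stop("no variants survive regime '", regime, "'", call. = FALSE)
  }
  list(kept = kept, counts = counts, regime = regime)
}
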