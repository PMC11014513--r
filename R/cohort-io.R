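# cohort persistence: minimal VCFv4.2 genotype export plus tab-separated
# sidecar tables for the panel, admixture proportions and local ancestry

#' Write a cohort to disk
#'
#' Genotypes are exported as a minimal VCFv4.2 file (one record per variant,
#' unphased diploid GT field, single ALT allele, dosage = ALT-allele count;
#' REF/ALT are placeholder `A`/`B` since the simulator tracks dosages, not
#' sequences). The frequency panel, admixture proportions, and local-ancestry
#' copy counts are written as tab-separated sidecars.
#'
#' @param cohort an `admix_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "admix_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(cohort$genotypes)
  m <- ncol(cohort$genotypes)
  panel <- cohort$panel

  gt_code <- c("0/0", "0/1", "1/1")
  samples <- sprintf("S%04d", seq_len(n))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=admixpca",
    sprintf("##contig=<ID=%s>", unique(panel$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt <- matrix(gt_code[cohort$genotypes + 1L], n, m)
  records <- vapply(seq_len(m), function(j) {
    paste(c(panel$chrom[j], panel$pos_bp[j],
            sprintf("var%06d", j), "A", "B", ".", "PASS", ".", "GT",
            gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, records), file.path(dir, "genotypes.vcf"))

  write_panel(panel, file.path(dir, "panel.tsv"))
  utils::write.table(data.frame(sample = samples, pi = cohort$pi),
                     file.path(dir, "pi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  anc <- as.data.frame(cohort$ancestry)
  names(anc) <- sprintf("var%06d", seq_len(m))
  utils::write.table(cbind(data.frame(sample = samples), anc),
                     file.path(dir, "ancestry.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' The VCF is parsed with the vcfR package; unphased or phased separators
#' are accepted and dosages are recovered as ALT-allele counts.
#' `read_cohort(write_cohort(c))` reproduces genotypes, positions, ancestry
#' and admixture proportions exactly.
#'
#' @param dir directory produced by [write_cohort()].
#' @return an `admix_cohort` (without any `latent` feature records).
#' @export
read_cohort <- function(dir) {
  vcf_path <- file.path(dir, "genotypes.vcf")
  v <- tryCatch(
    vcfR::read.vcfR(vcf_path, verbose = FALSE),
    error = function(e) stop("malformed VCF at ", vcf_path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  parsed <- gsub("\\|", "/", gt)
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dos[] <- known[parsed]
  if (any(is.na(dos))) {
    bad <- which(is.na(known[parsed]))[1]
    stop("unparseable GT field at record index ",
         (bad - 1) %% nrow(gt) + 1, call. = FALSE)
  }
  genotypes <- t(dos)  # vcfR is variants x samples

  panel <- read_panel(file.path(dir, "panel.tsv"))
  if (nrow(panel) != ncol(genotypes)) {
    stop("panel/VCF record count mismatch", call. = FALSE)
  }
  pi_tab <- utils::read.table(file.path(dir, "pi.tsv"), header = TRUE,
                              sep = "\t")
  anc_tab <- utils::read.table(file.path(dir, "ancestry.tsv"), header = TRUE,
                               sep = "\t", check.names = FALSE)
  ancestry <- as.matrix(anc_tab[, -1, drop = FALSE])
  dimnames(ancestry) <- NULL
  dimnames(genotypes) <- NULL
  structure(list(pi = pi_tab$pi, ancestry = ancestry, genotypes = genotypes,
                 panel = panel, latent = list()),
            class = "admix_cohort")
}
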