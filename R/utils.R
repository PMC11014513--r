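# internal helpers shared across modules

#' Derive a child seed from a parent seed
#'
#' All randomness in the package flows from a single user-supplied seed.
#' Sub-tasks (admixture draw, local ancestry, genotypes, each injected
#' feature, each trait replicate, ...) use children derived with this
#' function so that modules can be re-run independently and deterministically.
#' Children stay below 2^31 - 1 so they remain valid R integer seeds.
#'
#' @param seed parent integer seed.
#' @param stream non-negative integer stream index.
#' @return an integer seed.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stream))
  as.integer((as.numeric(seed) + 1000003 * as.numeric(stream)) %% 2147483647)
}

# evaluate `code` under `seed` without disturbing the caller's RNG state;
# seed = NULL means "use the current RNG stream"
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# strip any leading "chr" (case-insensitive) so "chr6" and "6" compare equal
normalize_chrom <- function(chrom) {
  out <- sub("^[Cc][Hh][Rr]", "", as.character(chrom))
  if (any(!nzchar(out))) {
    stop("unresolvable chromosome label(s): ",
         paste(utils::head(unique(chrom[!nzchar(out)]), 3), collapse = ", "))
  }
  out
}

# stop() with the offending argument named, used by the parameter validators
check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(name, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
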