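#' @import data.table
#' @importFrom stats dnorm kmeans ks.test p.adjust pchisq prcomp quantile
#'   rbeta rbinom rhyper rlnorm runif sd var cor setNames complete.cases
#'   chisq.test
#' @importFrom utils head read.table write.table
NULL

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

#' Expected spacing between recognition sites
#'
#' For an i.i.d. equal-base-frequency sequence, a motif of length L occurs
#' on average once every 4^L bases.
#'
#' @param motif recognition motif (e.g. `"TCGA"`), or its length.
#' @return expected spacing in bp.
#' @export
expected_site_spacing <- function(motif) {
  len <- if (is.character(motif)) nchar(motif) else as.integer(motif)
  stopifnot(len >= 1)
  4^len
}

#' Projected tile yield from a sequence budget
#'
#' How many cut-site-centered tiles a given amount of sequence is expected
#' to provide, before uniqueness/overlap filtering.
#'
#' @param total_bp total sequence length in bp.
#' @param motif recognition motif or its length.
#' @return expected number of recognition sites (= candidate tiles).
#' @export
projected_tile_yield <- function(total_bp, motif) {
  total_bp / expected_site_spacing(motif)
}

#' Mean inter-marker spacing
#'
#' @param genome_bp genome size in bp.
#' @param n_markers number of markers (tiles).
#' @return mean spacing in bp.
#' @export
intermarker_spacing <- function(genome_bp, n_markers) {
  stopifnot(n_markers > 0)
  genome_bp / n_markers
}

#' Generate a random genome
#'
#' i.i.d. equal-frequency A/C/G/T records, used for simulations and tests.
#'
#' @param lengths integer vector of record lengths; names become record ids.
#' @param seed RNG seed.
#' @return named character vector of uppercase DNA sequences.
#' @export
random_genome <- function(lengths, seed = NULL) {
  if (is.null(names(lengths)))
    names(lengths) <- sprintf("scaffold_%d", seq_along(lengths))
  with_seed(seed, {
    vapply(lengths, function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
            collapse = ""), "")
  })
}
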