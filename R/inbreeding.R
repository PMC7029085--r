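#' Individual inbreeding coefficients from the additive GRM
#'
#' `F_i = A_ii - 1`: the amount by which an individual's genomic
#' self-relationship exceeds 1. With true allele frequencies the
#' expectation equals the pedigree inbreeding coefficient (1/16 for
#' offspring of first-cousin matings, 1/8 for half-sib matings). Negative
#' estimates are reported as-is.
#'
#' @param rel A `relationship_matrices` object from [build_grms()], or an
#'   additive GRM matrix.
#' @return Named numeric vector of per-individual `F`.
#' @export
grm_inbreeding <- function(rel) {
  A <- if (inherits(rel, "relationship_matrices")) rel$A else as.matrix(rel)
  diag(A) - 1
}

#' Heterozygosity-excess inbreeding coefficient
#'
#' Method-of-moments estimator contrasting observed and expected
#' homozygosity per individual:
#' \deqn{F_i = \frac{O_{hom}(i) - E_{hom}(i)}{L_i - E_{hom}(i)},}
#' where `O_hom` is the observed number of homozygous loci, `L_i` the
#' number of loci called for individual i, and `E_hom` the expected
#' homozygous count under HWE summed over those loci. With sample
#' frequencies the per-locus expected heterozygosity `2 p q` carries the
#' small-sample correction `S_k / (S_k - 1)` with `S_k` the number of
#' called alleles (2 x called individuals) at locus k; with externally
#' supplied (true) frequencies no correction is applied.
#'
#' @param gm A [genotype_matrix()].
#' @param freqs `"sample"` or a numeric vector of per-locus ALT
#'   frequencies (see [build_grms()]).
#' @return Named numeric vector of per-individual `F` (always <= 1). If
#'   `L_i` equals `E_hom(i)` the estimator is undefined and `NA` is
#'   returned for that individual with a warning.
#' @export
het_inbreeding <- function(gm, freqs = "sample") {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (n_loci(gm) == 0L) stop("no loci")
  sample_freqs <- identical(freqs, "sample")
  p <- if (sample_freqs) allele_freqs(gm) else as.numeric(freqs)
  if (length(p) != n_loci(gm)) stop("`freqs` must have one entry per locus")
  check_poly(p)
  het_exp <- 2 * p * (1 - p)
  if (sample_freqs) {
    s <- 2 * colSums(!is.na(gm$calls))
    het_exp <- het_exp * s / (s - 1)
  }
  obs <- !is.na(gm$calls)
  hom <- obs & gm$calls != 1L
  L <- rowSums(obs)
  O_hom <- rowSums(hom)
  E_hom <- as.vector(obs %*% (1 - het_exp))
  denom <- L - E_hom
  f <- (O_hom - E_hom) / denom
  undef <- abs(denom) < 1e-12
  if (any(undef)) {
    warning("heterozygosity-excess F undefined for: ",
            paste(gm$samples[undef], collapse = ", "))
    f[undef] <- NA_real_
  }
  names(f) <- gm$samples
  f
}

#' Classify inbreeding coefficients by nearest pedigree expectation
#'
#' Assigns each individual to the mating type whose pedigree expectation
#' its estimated `F` is closest to, among: not notably inbred (`F = 0`),
#' offspring of first-cousin mating (`F = 1/16`), of half-sib mating
#' (`F = 1/8`), and of full-sib or parent-offspring mating (`F = 1/4`).
#' By default the class boundaries are the midpoints between neighbouring
#' expectations.
#'
#' @param f Numeric vector of inbreeding coefficients.
#' @param expectations Named numeric vector of class expectations
#'   (ascending). Defaults to `c(noninbred = 0, first_cousin_mating =
#'   1/16, half_sib_mating = 1/8, full_sib_mating = 1/4)`.
#' @return Factor of class labels, one per input value (`NA` preserved).
#' @examples
#' classify_inbreeding(c(0.01, 0.0625, 0.125))
#' @export
classify_inbreeding <- function(f,
                                expectations = c(noninbred = 0,
                                                 first_cousin_mating = 1 / 16,
                                                 half_sib_mating = 1 / 8,
                                                 full_sib_mating = 1 / 4)) {
  stopifnot(!is.unsorted(expectations))
  cuts <- (expectations[-1L] + expectations[-length(expectations)]) / 2
  labels <- names(expectations)
  out <- labels[findInterval(f, cuts) + 1L]
  factor(out, levels = labels)
}

#' Inbreeding summary table for a genotype matrix
#'
#' Convenience wrapper computing both inbreeding estimators and the
#' pedigree-expectation class per individual.
#'
#' @param gm A [genotype_matrix()].
#' @param rel Optional precomputed `relationship_matrices`; built with
#'   `freqs` if absent.
#' @param freqs See [build_grms()].
#' @return Data frame with columns `sample`, `grm_F`, `het_F`, `class`
#'   (class of `grm_F`).
#' @export
inbreeding_table <- function(gm, rel = NULL, freqs = "sample") {
  if (is.null(rel)) rel <- build_grms(gm, freqs = freqs)
  grm_f <- grm_inbreeding(rel)
  het_f <- het_inbreeding(gm, freqs = freqs)
  data.frame(sample = gm$samples, grm_F = unname(grm_f),
             het_F = unname(het_f[gm$samples]),
             class = classify_inbreeding(unname(grm_f)),
             stringsAsFactors = FALSE)
}
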