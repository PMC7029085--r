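#' Additive and dominance marker codings
#'
#' Per-locus genotype codings underlying the genomic relationship
#' matrices, under within-SNP standardization (each SNP scaled by its own
#' HWE variance). The additive code is `x - 2p` for dosage `x`; the
#' dominance code is `-2p^2`, `2pq`, `-2q^2` for `x = 0, 1, 2` (`q = 1 -
#' p`). Both codings have expectation zero under HWE genotype frequencies.
#' The variance divisors (`2pq` for additive, `(2pq)^2` for dominance) are
#' applied at accumulation time in [build_grms()], not here.
#'
#' @param dosages Vector of ALT dosages (0/1/2, `NA` allowed).
#' @param p ALT allele frequency, strictly inside (0, 1).
#' @return Numeric vector of codes (`NA` preserved).
#' @export
additive_codes <- function(dosages, p) {
  check_poly(p)
  dosages - 2 * p
}

#' @rdname additive_codes
#' @export
dominance_codes <- function(dosages, p) {
  check_poly(p)
  q <- 1 - p
  w <- rep(NA_real_, length(dosages))
  w[!is.na(dosages) & dosages == 0L] <- -2 * p^2
  w[!is.na(dosages) & dosages == 1L] <- 2 * p * q
  w[!is.na(dosages) & dosages == 2L] <- -2 * q^2
  w
}

check_poly <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("allele frequency must lie strictly in (0, 1); ",
         "exclude monomorphic loci before building relationship matrices")
  }
  invisible(p)
}

#' Build additive and dominance genomic relationship matrices
#'
#' Computes the n x n additive (`A`) and dominance (`D`) genomic
#' relationship matrices under within-SNP standardization: each SNP is
#' scaled by its own HWE variance and the matrices are averages over loci,
#' \deqn{A_{ij} = \frac{1}{m_{ij}} \sum_k \frac{(x_{ik}-2p_k)(x_{jk}-2p_k)}{2 p_k q_k},}
#' \deqn{D_{ij} = \frac{1}{m_{ij}} \sum_k \frac{w_{ik} w_{jk}}{(2 p_k q_k)^2},}
#' with the dominance codes `w` of [dominance_codes()]. Missing genotypes
#' contribute nothing to a pair's sum and shrink that pair's locus count
#' `m_ij` (pairwise-complete accumulation), so no imputation is performed.
#'
#' The diagonal of `A` is `1 + F` in expectation for an individual with
#' inbreeding coefficient `F` when true frequencies are used; negative
#' entries are legitimate estimates and are never truncated.
#'
#' @param gm A [genotype_matrix()].
#' @param freqs Either the string `"sample"` (ALT frequencies observed in
#'   the full sample, the default and the convention that includes the
#'   focal individuals -- a known source of slight downward bias in small
#'   samples) or a numeric vector of per-locus frequencies, e.g. the true
#'   founder frequencies of a simulation.
#' @return An object of class `relationship_matrices`: list with `A`, `D`
#'   (labelled symmetric matrices), `freqs_used`, `n_loci_used`, and
#'   `pair_loci` (matrix of pairwise-complete locus counts).
#' @examples
#' gm <- genotype_matrix(rbind(a = c(0L, 2L), b = c(2L, 0L)),
#'   loci = data.frame(id = c("s1", "s2"), chrom = "1", pos = 1:2,
#'                     ref = "A", alt = "G"))
#' build_grms(gm, freqs = c(0.5, 0.5))$A
#' @export
build_grms <- function(gm, freqs = "sample") {
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- n_loci(gm)
  if (m == 0L) stop("no loci")
  if (identical(freqs, "sample")) {
    p <- allele_freqs(gm)
  } else {
    p <- as.numeric(freqs)
    if (length(p) != m) stop("`freqs` must have one entry per locus")
  }
  mono <- !is.finite(p) | p <= 0 | p >= 1
  if (any(mono)) {
    stop("monomorphic loci under the chosen frequencies: ",
         paste(utils::head(gm$loci$id[mono], 10L), collapse = ", "),
         if (sum(mono) > 10L) sprintf(" (and %d more)", sum(mono) - 10L))
  }
  q <- 1 - p
  x <- gm$calls
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0L

  # additive: (x - 2p)/sqrt(2pq) with missing cells zeroed
  za <- sweep(x0, 2L, 2 * p, "-")
  za[!obs] <- 0
  za <- sweep(za, 2L, sqrt(2 * p * q), "/")

  # dominance: w/(2pq) with missing cells zeroed
  wd <- matrix(0, nrow(x), ncol(x))
  v2pq <- 2 * p * q
  wd[obs & x0 == 0L] <- (rep(-2 * p^2 / v2pq, each = nrow(x)))[obs & x0 == 0L]
  wd[obs & x0 == 1L] <- (rep(v2pq / v2pq, each = nrow(x)))[obs & x0 == 1L]
  wd[obs & x0 == 2L] <- (rep(-2 * q^2 / v2pq, each = nrow(x)))[obs & x0 == 2L]

  if (all(obs)) {
    pair_loci <- matrix(m, nrow(x), nrow(x))
  } else {
    storage.mode(obs) <- "double"
    pair_loci <- tcrossprod(obs)
  }
  A <- tcrossprod(za) / pair_loci
  D <- tcrossprod(wd) / pair_loci
  dimnames(A) <- dimnames(D) <- dimnames(pair_loci) <- list(gm$samples, gm$samples)
  structure(list(A = A, D = D, freqs_used = p, n_loci_used = m,
                 pair_loci = pair_loci, samples = gm$samples),
            class = "relationship_matrices")
}

#' @param x A `relationship_matrices` object.
#' @param ... Ignored.
#' @rdname build_grms
#' @export
print.relationship_matrices <- function(x, ...) {
  cat(sprintf("relationship_matrices: %d individuals, %d loci\n",
              nrow(x$A), x$n_loci_used))
  cat(sprintf("  mean diag(A) = %.4f, mean offdiag(A) = %.4f\n",
              mean(diag(x$A)), mean(x$A[upper.tri(x$A)])))
  invisible(x)
}

#' Pairwise coancestry coefficients from the additive GRM
#'
#' The coancestry (kinship) coefficient of a pair is half the
#' off-diagonal additive relationship: `theta_ij = A_ij / 2`. Small
#' negative estimates are expected for genuinely unrelated pairs when
#' sample allele frequencies are used and are reported as-is.
#'
#' @param rel A `relationship_matrices` object from [build_grms()], or an
#'   additive GRM matrix with sample ids as dimnames.
#' @return Data frame with one row per unordered pair: `id1`, `id2`,
#'   `theta`.
#' @export
coancestry <- function(rel) {
  A <- if (inherits(rel, "relationship_matrices")) rel$A else as.matrix(rel)
  ids <- rownames(A)
  idx <- pair_index(nrow(A))
  data.frame(id1 = ids[idx[, 1L]], id2 = ids[idx[, 2L]],
             theta = A[idx] / 2, stringsAsFactors = FALSE)
}

#' Pairwise dominance coefficients from the dominance GRM
#'
#' The dominance coefficient of a pair (the probability that both alleles
#' are jointly identical by descent) is the off-diagonal entry of the
#' dominance GRM. Classical expectations: 1/4 for full sibs, 1/16 for
#' double first cousins, 0 for all other non-inbred relationships.
#'
#' @param rel A `relationship_matrices` object, or a dominance GRM matrix.
#' @return Data frame with `id1`, `id2`, `dom` per unordered pair.
#' @export
dominance_coefficients <- function(rel) {
  D <- if (inherits(rel, "relationship_matrices")) rel$D else as.matrix(rel)
  ids <- rownames(D)
  idx <- pair_index(nrow(D))
  data.frame(id1 = ids[idx[, 1L]], id2 = ids[idx[, 2L]],
             dom = D[idx], stringsAsFactors = FALSE)
}
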