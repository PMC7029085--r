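#' Identity-by-state sharing for one pair
#'
#' Counts loci by IBS class over the loci called in both individuals:
#' IBS 2 = identical dosage, IBS 1 = dosage distance 1 (one shared
#' allele), IBS 0 = opposite homozygotes (dosage distance 2). The
#' similarity fraction is `DST = (ibs2 + ibs1/2) / n_shared`.
#'
#' @param x,y Dosage vectors of equal length (`NA` = missing).
#' @return List with `ibs0`, `ibs1`, `ibs2`, `n_shared`, `dst`.
#' @export
ibs_counts <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  d <- abs(x[ok] - y[ok])
  n <- sum(ok)
  ibs0 <- sum(d == 2)
  ibs1 <- sum(d == 1)
  ibs2 <- sum(d == 0)
  list(ibs0 = ibs0, ibs1 = ibs1, ibs2 = ibs2, n_shared = n,
       dst = if (n > 0L) (ibs2 + 0.5 * ibs1) / n else NA_real_)
}

# Per-locus expected IBS-class proportions conditional on IBD state.
# p: ALT frequency vector; s: number of sampled alleles per locus used to
# estimate p (Inf or NULL = frequencies known without error). The
# finite-sample correction replaces each frequency polynomial by its
# unbiased estimator built from falling factorials of the allele counts.
ibs_expectations <- function(p, s = NULL) {
  q <- 1 - p
  if (is.null(s) || all(!is.finite(s))) {
    u <- function(a, b) p^a * q^b
  } else {
    if (any(s < 4)) stop("at least 4 sampled alleles per locus are needed ",
                         "for the finite-sample IBS expectations")
    X <- p * s
    Y <- q * s
    ff <- function(z, k) {
      out <- rep(1, length(z))
      for (i in seq_len(k)) out <- out * (z - (i - 1))
      out
    }
    u <- function(a, b) ff(X, a) * ff(Y, b) / ff(s, a + b)
  }
  e00 <- pmax(2 * u(2, 2), 0)
  e10 <- pmax(4 * u(3, 1) + 4 * u(1, 3), 0)
  e11 <- pmax(2 * u(2, 1) + 2 * u(1, 2), 0)
  list(e00 = e00, e10 = e10, e20 = pmax(1 - e00 - e10, 0),
       e11 = e11, e21 = pmax(1 - e11, 0))
}

#' Method-of-moments IBD state probabilities for one pair
#'
#' Estimates the probabilities `Z0`, `Z1`, `Z2` that a random locus of
#' the pair shares 0, 1 or 2 alleles identical by descent, by inverting
#' the observed IBS class counts against their allele-frequency
#' expectations conditional on each IBD state (with finite-sample bias
#' correction when frequencies were estimated from the sample):
#' `Z0 = N0/E[N0|IBD0]`, `Z1 = (N1 - Z0 E[N1|IBD0])/E[N1|IBD1]`, `Z2` the
#' remainder. Estimates outside the probability simplex are clamped
#' (negative components set to 0, then renormalized). The overall
#' relatedness summary is `PI_HAT = Z1/2 + Z2`.
#'
#' @param x,y Dosage vectors for the two individuals.
#' @param freqs Per-locus ALT frequencies, strictly in (0, 1).
#' @param n_samples Number of individuals the frequencies were estimated
#'   from (the correction uses `2 * n_samples` alleles per locus);
#'   `NULL`/`Inf` means the frequencies are known exactly (e.g.
#'   simulation truth) and no correction is applied.
#' @return List with `Z0`, `Z1`, `Z2`, `PI_HAT`.
#' @export
mom_ibd <- function(x, y, freqs, n_samples = NULL) {
  stopifnot(length(x) == length(y), length(freqs) == length(x))
  check_poly(freqs)
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no loci called in both individuals")
  s <- if (is.null(n_samples) || !is.finite(n_samples)) NULL else
    rep(2 * n_samples, sum(ok))
  e <- ibs_expectations(freqs[ok], s)
  d <- abs(x[ok] - y[ok])
  invert_ibd(sum(d == 2), sum(d == 1), sum(d == 0),
             sum(e$e00), sum(e$e10), sum(e$e20), sum(e$e11), sum(e$e21),
             sum(ok))
}

# Moments inversion + simplex clamp shared by scalar and all-pairs paths.
invert_ibd <- function(n0, n1, n2, E00, E10, E20, E11, E21, L) {
  if (E00 < 1e-8 || E11 < 1e-8) {
    stop("degenerate IBS expectations for this locus set")
  }
  z0 <- n0 / E00
  z1 <- (n1 - z0 * E10) / E11
  z2 <- (n2 - z0 * E20 - z1 * E21) / L
  z <- pmax(c(z0, z1, z2), 0)
  tot <- sum(z)
  z <- if (tot > 0) z / tot else c(1, 0, 0)
  list(Z0 = z[1L], Z1 = z[2L], Z2 = z[3L], PI_HAT = 0.5 * z[2L] + z[3L])
}

#' IBS and method-of-moments IBD for all pairs
#'
#' Vectorized all-pairs version of [ibs_counts()] and [mom_ibd()]: for
#' every unordered pair of individuals, IBS class counts and `DST` over
#' the loci called in both, and the IBD state probabilities `Z0/Z1/Z2`
#' and `PI_HAT`. With `freqs = "sample"` the finite-sample correction
#' uses each locus's own called-allele count.
#'
#' @param gm A [genotype_matrix()].
#' @param freqs `"sample"` or a per-locus ALT frequency vector (see
#'   [build_grms()]).
#' @return Data frame with one row per pair: `id1`, `id2`, `ibs0`,
#'   `ibs1`, `ibs2`, `n_shared`, `DST`, `Z0`, `Z1`, `Z2`, `PI_HAT`.
#' @export
ibd_ibs_pairs <- function(gm, freqs = "sample") {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- n_samples(gm)
  if (n < 2L) stop("at least two individuals are required")
  sample_freqs <- identical(freqs, "sample")
  p <- if (sample_freqs) allele_freqs(gm) else as.numeric(freqs)
  if (length(p) != n_loci(gm)) stop("`freqs` must have one entry per locus")
  check_poly(p)
  s <- if (sample_freqs) 2 * colSums(!is.na(gm$calls)) else NULL
  e <- ibs_expectations(p, s)

  x <- gm$calls
  obs <- !is.na(x)
  g0 <- (obs & x == 0L) + 0
  g1 <- (obs & x == 1L) + 0
  g2 <- (obs & x == 2L) + 0
  C <- obs + 0
  ibs0 <- tcrossprod(g0, g2)
  ibs0 <- ibs0 + t(ibs0)
  ibs2 <- tcrossprod(g0) + tcrossprod(g1) + tcrossprod(g2)
  n_shared <- tcrossprod(C)
  ibs1 <- n_shared - ibs0 - ibs2
  wsum <- function(w) tcrossprod(C, sweep(C, 2L, w, "*"))
  E00 <- wsum(e$e00); E10 <- wsum(e$e10); E20 <- wsum(e$e20)
  E11 <- wsum(e$e11); E21 <- wsum(e$e21)

  idx <- pair_index(n)
  z <- lapply(seq_len(nrow(idx)), function(k) {
    ij <- idx[k, ]
    invert_ibd(ibs0[ij[1L], ij[2L]], ibs1[ij[1L], ij[2L]], ibs2[ij[1L], ij[2L]],
               E00[ij[1L], ij[2L]], E10[ij[1L], ij[2L]], E20[ij[1L], ij[2L]],
               E11[ij[1L], ij[2L]], E21[ij[1L], ij[2L]],
               n_shared[ij[1L], ij[2L]])
  })
  data.frame(
    id1 = gm$samples[idx[, 1L]], id2 = gm$samples[idx[, 2L]],
    ibs0 = ibs0[idx], ibs1 = ibs1[idx], ibs2 = ibs2[idx],
    n_shared = n_shared[idx],
    DST = (ibs2[idx] + 0.5 * ibs1[idx]) / n_shared[idx],
    Z0 = vapply(z, `[[`, numeric(1), "Z0"),
    Z1 = vapply(z, `[[`, numeric(1), "Z1"),
    Z2 = vapply(z, `[[`, numeric(1), "Z2"),
    PI_HAT = vapply(z, `[[`, numeric(1), "PI_HAT"),
    stringsAsFactors = FALSE
  )
}

#' Full pairwise relatedness table
#'
#' Assembles the per-pair record used by the population-level analyses:
#' coancestry `theta` and dominance coefficient `dom` from the GRMs, IBD
#' state probabilities and `PI_HAT`, IBS counts and `DST`, and -- when
#' sample metadata are supplied -- the population labels and the
#' between-individual geographic distance `dist_km` (absolute river-km
#' difference of the sampling locations; 0 within a location).
#'
#' @param gm A [genotype_matrix()].
#' @param meta Optional sample metadata data frame
#'   (see [read_sample_table()]) covering all samples of `gm`.
#' @param freqs `"sample"` or a per-locus frequency vector, used for both
#'   the GRMs and the IBD inversion.
#' @param rel Optional precomputed `relationship_matrices` (must match
#'   `gm` and `freqs`).
#' @return Data frame with one row per unordered pair and columns `id1`,
#'   `id2`, `pop1`, `pop2`, `theta`, `dom`, `Z0`, `Z1`, `Z2`, `PI_HAT`,
#'   `DST`, `dist_km`, plus the raw `ibs0`, `ibs1`, `ibs2`, `n_shared`
#'   counts. Without `meta` the population and distance columns are `NA`.
#' @export
pair_table <- function(gm, meta = NULL, freqs = "sample", rel = NULL) {
  if (is.null(rel)) rel <- build_grms(gm, freqs = freqs)
  th <- coancestry(rel)
  dm <- dominance_coefficients(rel)
  ii <- ibd_ibs_pairs(gm, freqs = freqs)
  out <- data.frame(
    id1 = th$id1, id2 = th$id2,
    pop1 = NA_character_, pop2 = NA_character_,
    theta = th$theta, dom = dm$dom,
    Z0 = ii$Z0, Z1 = ii$Z1, Z2 = ii$Z2, PI_HAT = ii$PI_HAT,
    DST = ii$DST, dist_km = NA_real_,
    ibs0 = ii$ibs0, ibs1 = ii$ibs1, ibs2 = ii$ibs2, n_shared = ii$n_shared,
    stringsAsFactors = FALSE
  )
  if (!is.null(meta)) {
    miss <- setdiff(gm$samples, meta$sample_id)
    if (length(miss)) stop("metadata missing for sample(s): ",
                           paste(miss, collapse = ", "))
    at <- match(out$id1, meta$sample_id)
    bt <- match(out$id2, meta$sample_id)
    out$pop1 <- meta$population[at]
    out$pop2 <- meta$population[bt]
    out$dist_km <- abs(meta$river_km[at] - meta$river_km[bt])
  }
  out
}
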