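#' Genotype matrix container
#'
#' The substrate of every estimator in the package: an n-individual by
#' m-locus matrix of ALT-allele dosages. Each call is the count of ALT
#' alleles carried by the individual at the locus (0, 1 or 2), with `NA`
#' for missing genotypes. The orientation is fixed once and for all:
#' allele frequency `p` always refers to the ALT allele, and minor allele
#' frequency is `min(p, 1 - p)`.
#'
#' @param calls Integer matrix, individuals in rows, loci in columns;
#'   entries in \{0, 1, 2, NA\}.
#' @param loci Data frame describing the loci, one row per column of
#'   `calls`, with columns `id`, `chrom`, `pos`, `ref`, `alt` and
#'   (optionally) `qual`. `qual` may be `NA` where the source carried no
#'   quality score.
#' @param samples Character vector of unique sample ids, one per row of
#'   `calls`; defaults to `rownames(calls)`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls` (dimnamed integer matrix), `loci` and `samples`.
#' @examples
#' gm <- genotype_matrix(
#'   rbind(F1 = c(0L, 1L), F2 = c(2L, NA)),
#'   loci = data.frame(id = c("s1", "s2"), chrom = "chr1", pos = c(100L, 200L),
#'                     ref = "A", alt = "G", qual = c(50, 60))
#' )
#' n_samples(gm)
#' @export
genotype_matrix <- function(calls, loci, samples = rownames(calls)) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) stop("sample ids are required (rownames of `calls` or `samples`)")
  samples <- as.character(samples)
  if (nrow(calls) < 1L) stop("at least one individual is required")
  if (length(samples) != nrow(calls)) stop("length of `samples` must equal nrow(calls)")
  if (anyDuplicated(samples)) stop("duplicate sample ids: ",
                                   paste(unique(samples[duplicated(samples)]), collapse = ", "))
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  required <- c("id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols)) stop("`loci` lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!"qual" %in% names(loci)) loci$qual <- NA_real_
  if (nrow(loci) != ncol(calls)) stop("nrow(loci) must equal ncol(calls)")
  if (anyDuplicated(loci$id)) stop("duplicate locus ids")
  if (nrow(loci) > 0L) {
    if (any(loci$pos < 1L)) stop("locus positions must be >= 1 (1-based)")
    if (any(loci$ref == loci$alt)) stop("REF and ALT must differ")
    bad <- !is.na(calls) & (calls < 0L | calls > 2L)
    if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  }
  dimnames(calls) <- list(samples, loci$id)
  structure(list(calls = calls, loci = loci, samples = samples),
            class = "genotype_matrix")
}

#' @rdname genotype_matrix
#' @param x,gm A `genotype_matrix`.
#' @export
n_samples <- function(gm) length(gm$samples)

#' @rdname genotype_matrix
#' @export
n_loci <- function(gm) nrow(gm$loci)

#' @rdname genotype_matrix
#' @param keep Logical or integer index of loci to retain (in order).
#' @export
subset_loci <- function(gm, keep) {
  genotype_matrix(gm$calls[, keep, drop = FALSE], gm$loci[keep, , drop = FALSE],
                  gm$samples)
}

#' Number of individuals with a missing call at each locus
#' @param gm A `genotype_matrix`.
#' @return Integer vector, one entry per locus.
#' @export
missing_counts <- function(gm) colSums(is.na(gm$calls))

#' @param ... Ignored.
#' @rdname genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.2f%% missing)\n",
              n_samples(x), n_loci(x),
              if (length(x$calls)) 100 * mean(is.na(x$calls)) else 0))
  invisible(x)
}
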