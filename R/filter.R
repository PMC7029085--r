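#' ALT allele frequency at one locus
#'
#' @param calls Vector of dosage codes (0/1/2, `NA` = missing) for one locus.
#' @return List with `p_alt` (ALT-allele frequency among called
#'   individuals) and `n_called` (number of non-missing genotypes).
#' @examples
#' allele_frequency(c(2, 1, NA, 0, 1))  # p = 4/8
#' @export
allele_frequency <- function(calls) {
  ok <- !is.na(calls)
  n <- sum(ok)
  if (n == 0L) stop("all genotypes missing at this locus")
  list(p_alt = sum(calls[ok]) / (2 * n), n_called = n)
}

# ALT frequency for every locus of a genotype_matrix (NA where all missing).
allele_freqs <- function(gm) {
  n_called <- colSums(!is.na(gm$calls))
  p <- colSums(gm$calls, na.rm = TRUE) / (2 * n_called)
  p[n_called == 0L] <- NA_real_
  unname(p)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on one biallelic locus, conditioning on the
#' observed allele counts: the p-value is the summed probability of all
#' heterozygote counts whose conditional probability does not exceed that
#' of the observed count (the "no more probable" rule; no mid-p
#' correction). Probabilities follow the exact conditional distribution of
#' the heterozygote count given the allele counts; with the minor-allele
#' count `nm` and `N` individuals,
#' `P(het = h) = C * 2^h * N! / (nAA! nAa! naa!)` normalized over all `h`
#' with the parity of `nm`.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (homozygote, heterozygote,
#'   other homozygote); non-negative, summing to at least 1. The test is
#'   symmetric in `n_AA` and `n_aa`.
#' @return p-value in (0, 1]. A monomorphic locus (one possible
#'   configuration) returns exactly 1.
#' @examples
#' hwe_exact_p(10, 0, 0)   # monomorphic: 1
#' hwe_exact_p(3, 5, 2)
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(is.na(counts)) || any(counts < 0) || !all(is_whole(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  counts <- round(counts)
  n <- sum(counts)
  if (n < 1L) stop("at least one genotype is required")
  nA <- 2L * counts[1L] + counts[2L]
  na <- 2L * counts[3L] + counts[2L]
  nm <- min(nA, na)                       # minor allele count
  h <- seq.int(nm %% 2L, nm, by = 2L)     # feasible heterozygote counts
  # log conditional probability (up to a constant) of each h
  logp <- h * log(2) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((na - h) / 2 + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[match(counts[2L], h)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

#' Locus filter criteria
#'
#' The four per-locus retention rules applied jointly to a genotype
#' matrix: site quality, minor allele frequency, exact HWE test p-value,
#' and number of individuals with missing genotypes. The defaults are the
#' standard stringency for a reduced-representation SNP panel on a sample
#' of a few dozen individuals: QUAL >= 30, MAF >= 5%, HWE p >= 0.01, and
#' at most 4 individuals missing per locus.
#'
#' @param min_qual Minimum QUAL; loci with no quality score pass this rule.
#' @param min_maf Minimum minor allele frequency, in \[0, 0.5\].
#' @param min_hwe_p Minimum exact HWE p-value, in \[0, 1\].
#' @param max_missing Maximum missing genotypes per locus. An integer >= 1
#'   is an absolute count of individuals; a value strictly between 0 and 1
#'   is interpreted as a maximum missing fraction of the sample.
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(min_qual = 30, min_maf = 0.05, min_hwe_p = 0.01,
                            max_missing = 4) {
  stopifnot(min_maf >= 0, min_maf <= 0.5, min_hwe_p >= 0, min_hwe_p <= 1,
            max_missing >= 0)
  structure(list(min_qual = min_qual, min_maf = min_maf,
                 min_hwe_p = min_hwe_p, max_missing = max_missing),
            class = "filter_criteria")
}

#' Apply locus filters to a genotype matrix
#'
#' Evaluates all four criteria of [filter_criteria()] on the input matrix
#' in a single pass (frequencies are not recomputed after removals) and
#' retains loci passing all of them, preserving their order. For the
#' report, criteria are checked in the fixed order QUAL, MAF, HWE,
#' missingness, and a failed locus is attributed to the first criterion it
#' fails. A locus with no called genotypes fails the MAF rule (its
#' frequency is undefined).
#'
#' @param gm A [genotype_matrix()].
#' @param criteria A [filter_criteria()] object.
#' @return List with `genotypes` (the filtered `genotype_matrix`) and
#'   `report`, a `filter_report`: per-locus data frame (`id`, `pass`,
#'   `failed` = first failed criterion or `NA`) with per-criterion failure
#'   totals in attribute `"totals"`.
#' @export
filter_loci <- function(gm, criteria = filter_criteria()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(criteria, "filter_criteria"))
  m <- n_loci(gm)
  n <- n_samples(gm)
  if (m == 0L) {
    report <- empty_filter_report()
    return(list(genotypes = gm, report = report))
  }
  qual_ok <- is.na(gm$loci$qual) | gm$loci$qual >= criteria$min_qual

  p <- allele_freqs(gm)
  maf <- pmin(p, 1 - p)
  maf_ok <- !is.na(maf) & maf >= criteria$min_maf

  hwe_p <- vapply(seq_len(m), function(k) {
    x <- gm$calls[, k]
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(1)
    hwe_exact_p(sum(x == 0L), sum(x == 1L), sum(x == 2L))
  }, numeric(1))
  hwe_ok <- hwe_p >= criteria$min_hwe_p

  miss <- missing_counts(gm)
  max_miss <- criteria$max_missing
  if (max_miss > 0 && max_miss < 1) max_miss <- max_miss * n
  miss_ok <- miss <= max_miss

  pass <- qual_ok & maf_ok & hwe_ok & miss_ok
  failed <- rep(NA_character_, m)
  failed[!miss_ok] <- "missing"
  failed[!hwe_ok] <- "hwe"
  failed[!maf_ok] <- "maf"
  failed[!qual_ok] <- "qual"

  report <- structure(
    data.frame(id = gm$loci$id, pass = pass, failed = failed,
               stringsAsFactors = FALSE),
    totals = c(qual = sum(failed == "qual", na.rm = TRUE),
               maf = sum(failed == "maf", na.rm = TRUE),
               hwe = sum(failed == "hwe", na.rm = TRUE),
               missing = sum(failed == "missing", na.rm = TRUE),
               passed = sum(pass)),
    class = c("filter_report", "data.frame")
  )
  list(genotypes = subset_loci(gm, pass), report = report)
}

empty_filter_report <- function() {
  structure(
    data.frame(id = character(), pass = logical(), failed = character(),
               stringsAsFactors = FALSE),
    totals = c(qual = 0L, maf = 0L, hwe = 0L, missing = 0L, passed = 0L),
    class = c("filter_report", "data.frame")
  )
}

#' @param x A `filter_report`.
#' @param ... Ignored.
#' @rdname filter_loci
#' @export
print.filter_report <- function(x, ...) {
  tot <- attr(x, "totals")
  cat(sprintf("filter_report: %d of %d loci retained\n", tot[["passed"]], nrow(x)))
  cat(sprintf("  removed: qual %d, maf %d, hwe %d, missing %d\n",
              tot[["qual"]], tot[["maf"]], tot[["hwe"]], tot[["missing"]]))
  invisible(x)
}
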