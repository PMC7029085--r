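# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the implementation it checks.

# HWE exact probabilities by the upward recurrence on the heterozygote
# count (the package uses closed-form log-gamma terms instead):
# P(h+2)/P(h) = 4 * hom1(h) * hom2(h) / ((h+1)(h+2)).
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  nm <- min(nA, na)
  hs <- seq.int(nm %% 2L, nm, by = 2L)
  prob <- numeric(length(hs))
  prob[1L] <- 1
  if (length(hs) > 1L) {
    for (k in 2:length(hs)) {
      h <- hs[k - 1L]
      prob[k] <- prob[k - 1L] * 4 * ((nA - h) / 2) * ((na - h) / 2) /
        ((h + 1) * (h + 2))
    }
  }
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_Aa, hs)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Element-by-element GRM accumulation with explicit pairwise-complete
# bookkeeping (the package uses zero-filled cross products).
oracle_grm <- function(calls, p) {
  n <- nrow(calls)
  A <- D <- matrix(NA_real_, n, n)
  wcode <- function(x, pk) switch(x + 1L, -2 * pk^2, 2 * pk * (1 - pk),
                                  -2 * (1 - pk)^2)
  for (i in seq_len(n)) {
    for (j in i:n) {
      sa <- sd <- 0
      cnt <- 0L
      for (k in seq_len(ncol(calls))) {
        xi <- calls[i, k]
        xj <- calls[j, k]
        if (is.na(xi) || is.na(xj)) next
        pk <- p[k]
        qk <- 1 - pk
        sa <- sa + (xi - 2 * pk) * (xj - 2 * pk) / (2 * pk * qk)
        sd <- sd + wcode(xi, pk) * wcode(xj, pk) / (2 * pk * qk)^2
        cnt <- cnt + 1L
      }
      A[i, j] <- A[j, i] <- sa / cnt
      D[i, j] <- D[j, i] <- sd / cnt
    }
  }
  list(A = A, D = D)
}

# Exact pedigree coefficients by exhaustive enumeration of all
# 2^(2 * n_nonfounders) Mendelian transmission patterns, with founder
# alleles carrying unique labels.
oracle_pedigree_enum <- function(ped, i, j) {
  ids <- ped$id
  n <- length(ids)
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  founders <- which(is.na(si))
  nonf <- which(!is.na(si))        # topologically ordered by pedigree()
  nm <- 2L * length(nonf)
  stopifnot(nm <= 16L)
  npat <- 2L^nm
  ii <- match(i, ids)
  jj <- match(j, ids)
  f_sum <- Fi_sum <- Fj_sum <- d_sum <- 0
  base1 <- integer(n)
  base2 <- integer(n)
  base1[founders] <- 2L * founders - 1L
  base2[founders] <- 2L * founders
  for (pat in 0:(npat - 1L)) {
    bits <- as.integer(intToBits(pat))[seq_len(nm)]
    a1 <- base1
    a2 <- base2
    b <- 1L
    for (k in nonf) {
      a1[k] <- if (bits[b] == 0L) a1[si[k]] else a2[si[k]]
      b <- b + 1L
      a2[k] <- if (bits[b] == 0L) a1[di[k]] else a2[di[k]]
      b <- b + 1L
    }
    ai <- c(a1[ii], a2[ii])
    aj <- c(a1[jj], a2[jj])
    f_sum <- f_sum + mean(outer(ai, aj, "=="))
    Fi_sum <- Fi_sum + (ai[1L] == ai[2L])
    Fj_sum <- Fj_sum + (aj[1L] == aj[2L])
    d_sum <- d_sum + ((a1[ii] == a1[jj] && a2[ii] == a2[jj]) ||
                        (a1[ii] == a2[jj] && a2[ii] == a1[jj]))
  }
  list(kinship = f_sum / npat, F_i = Fi_sum / npat, F_j = Fj_sum / npat,
       dominance = d_sum / npat)
}

# Random genotype matrix with missingness, for property sweeps.
random_gm <- function(n, m, miss = 0.1, seed = NULL) {
  snpkin:::with_seed(seed, {
    p <- runif(m, 0.15, 0.85)
    calls <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
    calls[matrix(runif(n * m) < miss, n, m)] <- NA_integer_
    # redraw columns until every locus is polymorphic in-sample and fully
    # informative for at least one individual pair
    repeat {
      n_called <- colSums(!is.na(calls))
      tot <- colSums(calls, na.rm = TRUE)
      bad <- which(n_called == 0L | tot == 0L | tot == 2L * n_called)
      if (!length(bad)) break
      for (k in bad) {
        calls[, k] <- rbinom(n, 2L, p[k])
        calls[runif(n) < miss, k] <- NA_integer_
      }
    }
    loci <- data.frame(id = sprintf("L%03d", seq_len(m)), chrom = "1",
                       pos = seq_len(m), ref = "A", alt = "G",
                       stringsAsFactors = FALSE)
    gm <- genotype_matrix(calls, loci, samples = sprintf("I%02d", seq_len(n)))
    attr(gm, "true_freqs") <- p
    gm
  })
}

all_templates <- c("unrelated", "parent_offspring", "full_sibs", "half_sibs",
                   "first_cousins", "double_first_cousins",
                   "first_cousin_mating", "half_sib_mating", "full_sib_mating")
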