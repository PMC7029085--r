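---
title: "Estimating genomic inbreeding and relatedness without pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genomic inbreeding and relatedness without pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpkin)
```

## The problem

Conservation management of small, isolated populations — the motivating
case is a critically endangered salmonid sampled at three locations along
one river — needs two quantities that classically require pedigree
records: how inbred each individual is, and how related each pair of
individuals is. Wild fish have no pedigrees. With a few thousand
genome-wide SNPs both quantities can be estimated directly from
genotypes, and mate selection can then avoid pairing hidden relatives.

`snpkin` implements that workflow end to end: locus filtering, genomic
relationship matrices, individual inbreeding, pairwise coancestry,
dominance, IBS and method-of-moments IBD, a low-dimensional MDS view,
per-location comparisons, and an isolation-by-distance test. Because no
truth is observable for wild data, the package carries its own
validation engine: a gene-dropping pedigree simulator whose exact
expectations (computed by the classical kinship recursion) serve as the
oracle for every estimator.

## Model

Genotypes are ALT-allele dosages $x \in \{0,1,2\}$. All estimators use
within-SNP standardization: each SNP is scaled by its own
Hardy–Weinberg variance rather than pooling variances across SNPs. With
per-locus ALT frequency $p_k$ ($q_k = 1-p_k$):

* **Additive GRM** $A_{ij} = \frac{1}{m_{ij}} \sum_k
  \frac{(x_{ik}-2p_k)(x_{jk}-2p_k)}{2p_kq_k}$. The diagonal has
  expectation $1+F_i$, so the genomic inbreeding coefficient is
  $F_i = A_{ii}-1$; the coancestry (kinship) coefficient of a pair is
  $\theta_{ij} = A_{ij}/2$.
* **Dominance GRM** $D_{ij} = \frac{1}{m_{ij}} \sum_k
  \frac{w_{ik}w_{jk}}{(2p_kq_k)^2}$ with codes $w = -2p^2,\, 2pq,\,
  -2q^2$ for $x = 0,1,2$. This coding is zero-mean under HWE and gives
  the classical expectations $E[D] = 1/4$ for full sibs and $1/16$ for
  double first cousins, the only non-inbred relationships with nonzero
  dominance relatedness.
* **IBS**: per pair, loci are classed by dosage distance (0/1/2 shared
  alleles); $DST = (\mathrm{ibs2} + \mathrm{ibs1}/2)/n$ and the IBS
  distance for MDS is $1 - DST$.
* **Method-of-moments IBD**: observed IBS class counts are inverted
  against their expectations conditional on sharing 0, 1 or 2 alleles
  IBD. When frequencies are estimated from the sample, each frequency
  polynomial (e.g. $p^2q^2$) is replaced by its unbiased
  falling-factorial estimator from the allele counts, the standard
  finite-sample correction. Estimates are clamped to the probability
  simplex; $\hat\pi = Z_1/2 + Z_2$.
* **Exact HWE test**: the two-sided conditional exact test on the
  heterozygote count given the allele counts, summing all
  configurations no more probable than the observed one (no mid-p).
  With $n \approx 43$ the asymptotic chi-square test is unreliable;
  the exact test is the field standard at this size.

A deliberate pair of estimators is exposed for inbreeding: the GRM
diagonal (`grm_F`) and the heterozygosity-excess method-of-moments
estimator (`het_F`). They agree in expectation but respond differently
to frequency error, which is useful diagnostically.

## Parameters that matter

* **Filter thresholds** (`filter_criteria()`): QUAL ≥ 30, MAF ≥ 5%,
  HWE exact p ≥ 0.01, ≤ 4 individuals missing per locus. These are the
  conventional stringency for a reduced-representation panel on ~43
  individuals; all four are applied in a single pass on the input
  matrix (frequencies are not recomputed after removals), and a failed
  locus is attributed to the first criterion it fails, in the order
  QUAL, MAF, HWE, missingness. The missingness cap also accepts a
  fraction (values in (0,1)).
* **Allele frequencies** (`freqs` argument throughout): `"sample"`
  computes ALT frequencies from all individuals including the focal
  ones. This is the convention real studies use and it carries a known
  small-sample bias: because each locus's sample frequencies absorb the
  focal genotypes, the additive GRM rows sum to zero and the mean
  off-diagonal $\theta$ of even a completely unrelated sample is
  strictly negative (about $-1/(n-1)$). The package reports such
  negative estimates unchanged — they are the correct reading of
  "unrelated" — and the calibration test asserts the sign. Passing a
  numeric vector (e.g. simulation truth) removes the bias; a
  leave-out-the-focal-pair re-estimation is *not* implemented, a known
  limitation.
* **Missing data**: pairwise-complete accumulation everywhere (a locus
  missing in either member is dropped for that pair and the pair's
  denominator shrinks). At ≤ 4/43 missing per locus this is nearly
  indistinguishable from mean imputation but is exactly testable
  against a brute-force oracle and introduces no imputation bias.
* **Group comparisons** (`compare_groups()`): one-way fixed-effect
  model $y = \mu + \mathrm{population} + e$, all pairwise contrasts on
  the pooled variance, compact-letter display at $\alpha = 0.05$.
  Unadjusted contrasts are the default because that is how such tables
  are conventionally lettered; `adjust = "tukey"` is available since
  the choice is genuinely ambiguous.
* **Isolation by distance** (`regress_on_distance()`): OLS of pairwise
  $\theta$ on the river-km distance between sampling locations, plus a
  Mantel permutation test (default 9,999 permutations, observed
  statistic included, one-sided in the direction of the observed
  correlation). The OLS p-value ignores the non-independence of pairs
  sharing an individual; the Mantel test permutes individuals and is
  the one to trust.

## The simulator and what it does (not) emulate

`make_pedigree()` builds canonical minimal pedigrees (unrelated,
parent–offspring, full/half sibs, first cousins, double first cousins,
and the first-cousin-, half-sib- and full-sib-mating templates),
replicated with disjoint founders. `gene_drop()` draws founder alleles
independently per locus at Uniform[0.1, 0.9] frequencies and transmits
one allele per parent uniformly — unlinked loci, no mutation, no
selection, matching how reduced-representation markers are treated by
the estimators themselves. `expected_coefficients()` returns the exact
pedigree kinship, inbreeding and dominance expectations via the tabular
recursion; the test suite checks it against exhaustive enumeration of
all Mendelian transmission patterns. The dominance expectation formula
assumes non-inbred pair members; for inbred members the value is
flagged approximate rather than silently returned.

`make_study_fixture()` emulates the study design: 43 individuals in
locations A/B/C of sizes 11/20/12 at river km 5/17/25; 16,500
pre-filter loci (chosen so the default filters retain ~15k, the scale
of the real panel); inbred individuals embedded with the frequencies
the real sample showed (3 first-cousin-mating and 2 half-sib-mating
offspring in A, 2 half-sib-mating in B, 1 in C) plus one sampled
half-sib pair each in A and B; genotype missingness 1% capped at 4 per
locus, and 3% of loci with QUAL below 30 so every filter criterion does
real work. Population structure comes from Balding–Nichols drift of
each location's founder pool from a common ancestral pool
($F_{ST}$ = 0.06 for A, 0 for B, 0.015 for C), reproducing the observed
pattern — location A genetically separate, B and C intermingled — and a
monotone decline of $\theta$ with distance.

What the simulator does **not** emulate: linkage and LD (real SLAF
markers are approximately but not exactly unlinked), uneven marker
coverage along the genome, genotyping error, and reference-genome
artefacts. Passing the recovery tests therefore shows the estimators
are correct under their own assumptions, not that those assumptions
hold for any particular real data set.

## Numerical choices

* Monomorphic loci under the chosen frequencies are a hard error in the
  GRM builders (their standardized codes are undefined); filter first.
* The HWE test computes conditional probabilities from log-gamma terms
  and normalizes; the "no more probable" comparison uses a $1 + 10^{-7}$
  relative tolerance so ties are included, as in the standard
  implementation of this test.
* MDS eigenvalues are sorted descending (LAPACK order, deterministic);
  axes with non-positive eigenvalues are zeroed and the count of
  negative eigenvalues reported. Axis signs are arbitrary, so tests
  compare distances or absolute geometry only.
* IBD moment estimates are clamped: negative state probabilities are
  set to zero and the triple renormalized to sum to one exactly.
* Simulation problem sizes used in the validation suite: 200 replicate
  families × 20,000 SNPs for the four headline recovery checks (the
  Monte-Carlo standard error of each mean is ~0.002, an order of
  magnitude inside the ±0.01 acceptance band), 500 founders × 20,000
  SNPs for the null calibration, and smaller per-module sweeps chosen
  to keep each property unambiguous at negligible cost.

## Worked validation summary

The quantities below are recomputed by `scripts/acceptance.R` and the
test suite; the vignette states no number the code does not itself
produce.

* Mean $F$ of simulated first-cousin-mating offspring → 1/16; of
  half-sib-mating offspring → 1/8 (true founder frequencies).
* Mean $D$ of full-sib pairs → 1/4; of double-first-cousin pairs →
  1/16.
* Mean $\hat\pi$ orders full sibs > half sibs > first cousins >
  unrelated, and $\hat\pi \approx 2\theta$ for non-inbred pairs.
* 500 unrelated HWE individuals: mean off-diagonal $\theta$ within
  ±0.01 of zero with true frequencies, strictly negative with sample
  frequencies.
* The synthetic study fixture passes the full pipeline with the correct
  pair combinatorics (55/190/66 within, 220/132/240 between), embedded
  relatives ranked above all unrelated pairs by both $\theta$ and
  $\hat\pi$, and a significantly negative $\theta$–distance Mantel test.

## Known limitations

Frequencies always include the focal individuals (no leave-one-out
option); dominance expectations for inbred pairs are approximate;
no LD pruning, BCF support, multi-allelic decomposition, imputation,
variance-component estimation or $F_{ST}$ machinery — those are either
upstream of this package's scope or explicitly out of it.
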