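toy_gm <- function(calls, m = ncol(calls)) {
  loci <- data.frame(id = sprintf("L%02d", seq_len(m)), chrom = "1",
                     pos = seq_len(m), ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  genotype_matrix(calls, loci, samples = rownames(calls) %||%
                    sprintf("I%02d", seq_len(nrow(calls))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("single-locus arithmetic is forced by the standardized coding", {
  gm <- toy_gm(rbind(a = 2L, b = 0L), m = 1L)
  rel <- build_grms(gm, freqs = 0.5)
  expect_equal(unname(rel$A["a", "a"]), 2)    # (2-1)^2 / 0.5
  expect_equal(unname(rel$A["a", "b"]), -2)   # so theta = -1, F = 1
  expect_equal(unname(grm_inbreeding(rel)["a"]), 1)
  expect_equal(coancestry(rel)$theta, -1)

  both_het <- toy_gm(rbind(a = 1L, b = 1L), m = 1L)
  reld <- build_grms(both_het, freqs = 0.5)
  expect_equal(unname(reld$D["a", "b"]), 1)   # (0.5 * 0.5) / 0.25
})

test_that("additive and dominance codes have zero mean under HWE at any frequency", {
  for (p in c(0.1, 0.25, 0.5, 0.8)) {
    q <- 1 - p
    gfreq <- c(q^2, 2 * p * q, p^2)
    expect_equal(sum(gfreq * additive_codes(0:2, p)), 0, tolerance = 1e-12)
    expect_equal(sum(gfreq * dominance_codes(0:2, p)), 0, tolerance = 1e-12)
  }
  expect_equal(additive_codes(1L, 0.5), 0)  # x = 2p exactly
  expect_error(additive_codes(0:2, 1), "strictly")
  expect_error(dominance_codes(0:2, 0), "strictly")
})

test_that("GRMs equal the brute-force summation oracle on random matrices", {
  for (seed in 1:6) {
    n <- sample(3:10, 1)
    m <- sample(5:50, 1)
    gm <- random_gm(n, m, miss = 0.12, seed = 100 + seed)
    p <- attr(gm, "true_freqs")
    rel <- build_grms(gm, freqs = p)
    orc <- oracle_grm(gm$calls, p)
    expect_lt(max(abs(rel$A - orc$A)), 1e-12)
    expect_lt(max(abs(rel$D - orc$D)), 1e-12)
    expect_lt(max(abs(rel$A - t(rel$A))), 1e-10)
    expect_lt(max(abs(rel$D - t(rel$D))), 1e-10)
  }
})

test_that("a duplicated individual has off-diagonal equal to its diagonal", {
  gm0 <- random_gm(4, 40, miss = 0, seed = 7)
  calls <- rbind(gm0$calls, dup = gm0$calls[1, ])
  gm <- toy_gm(calls)
  rel <- build_grms(gm, freqs = attr(gm0, "true_freqs"))
  expect_equal(rel$A[1, 5], rel$A[1, 1], tolerance = 1e-12)
  expect_equal(rel$D[1, 5], rel$D[1, 1], tolerance = 1e-12)
})

test_that("monomorphic loci are rejected with their ids", {
  calls <- rbind(a = c(0L, 1L), b = c(0L, 2L))
  gm <- toy_gm(calls)
  expect_error(build_grms(gm, freqs = "sample"), "L01")
  expect_error(build_grms(gm, freqs = c(0, 0.5)), "monomorphic")
})

test_that("coancestry with true frequencies recovers the parent-offspring expectation", {
  res <- simulate_pedigree_recovery("parent_offspring", n_replicates = 30L,
                                    n_loci = 4000L, seed = 21L)
  expect_lt(abs(mean(res$theta) - 0.25), 0.02)
  # parent-offspring pairs have no dominance relationship
  expect_lt(abs(mean(res$dominance)), 0.02)
})

test_that("heterozygosity-excess F behaves as the formula dictates", {
  # individual heterozygous everywhere: observed homozygosity below expectation
  calls <- rbind(het = rep(1L, 20), a = rep(0L, 20), b = rep(2L, 20),
                 c = rep(c(0L, 2L), 10))
  gm <- toy_gm(calls)
  f <- het_inbreeding(gm, freqs = rep(0.5, 20))
  expect_lt(f[["het"]], 0)
  expect_true(all(f <= 1))

  # two-locus hand computation with known frequencies (no correction)
  gm2 <- toy_gm(rbind(x = c(0L, 1L), y = c(2L, 2L)))
  p <- c(0.3, 0.6)
  ehom <- sum(1 - 2 * p * (1 - p))
  f2 <- het_inbreeding(gm2, freqs = p)
  expect_equal(unname(f2["x"]), (1 - ehom) / (2 - ehom), tolerance = 1e-12)
  expect_equal(unname(f2["y"]), (2 - ehom) / (2 - ehom), tolerance = 1e-12)
})

test_that("heterozygosity-excess F is centred near zero for unrelated HWE individuals", {
  ped <- make_pedigree("unrelated", n_replicates = 50L)
  gm <- gene_drop(ped, sim_config(n_loci = 3000L, seed = 31L))
  f <- het_inbreeding(gm, freqs = "sample")
  expect_lt(abs(mean(f)), 0.02)
})

test_that("inbreeding classes follow the nearest pedigree expectation", {
  got <- classify_inbreeding(c(0.0625, 0.01, 0.125, -0.05, 0.3, NA))
  expect_equal(as.character(got),
               c("first_cousin_mating", "noninbred", "half_sib_mating",
                 "noninbred", "full_sib_mating", NA))
  # midpoint boundaries
  expect_equal(as.character(classify_inbreeding(c(0.031, 0.032))),
               c("noninbred", "first_cousin_mating"))
})

test_that("inbreeding_table assembles both estimators with classes", {
  gm <- random_gm(6, 60, miss = 0.05, seed = 5)
  tab <- inbreeding_table(gm, freqs = attr(gm, "true_freqs"))
  expect_named(tab, c("sample", "grm_F", "het_F", "class"))
  expect_equal(tab$sample, gm$samples)
  expect_true(all(is.finite(tab$grm_F)))
})
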