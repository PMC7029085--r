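test_that("IBS class counts follow the dosage-distance rule", {
  x <- c(0, 1, 2, 1)
  same <- ibs_counts(x, x)
  expect_equal(same[c("ibs0", "ibs1", "ibs2", "n_shared", "dst")],
               list(ibs0 = 0L, ibs1 = 0L, ibs2 = 4L, n_shared = 4L, dst = 1))
  opp <- ibs_counts(c(0, 0, 2), c(2, 2, 0))
  expect_equal(opp$ibs0, 3L)
  expect_equal(opp$dst, 0)
  # per-locus IBS classes of (0,1,2,1) vs (2,1,1,0) are (0,2,1,1)
  mixed <- ibs_counts(c(0, 1, 2, 1), c(2, 1, 1, 0))
  expect_equal(mixed[c("ibs0", "ibs1", "ibs2")],
               list(ibs0 = 1L, ibs1 = 2L, ibs2 = 1L))
  expect_equal(mixed$dst, (1 + 0.5 * 2) / 4)
  # missing loci drop out of the shared set
  withmiss <- ibs_counts(c(0, NA, 2), c(2, 1, NA))
  expect_equal(withmiss$n_shared, 1L)
  expect_equal(withmiss$ibs0, 1L)
})

test_that("a duplicated individual is detected as PI_HAT ~ 1", {
  gm <- gene_drop(make_pedigree("unrelated"), sim_config(n_loci = 5000L, seed = 41L))
  p <- attr(gm, "true_freqs")
  z <- mom_ibd(gm$calls[1, ], gm$calls[1, ], p)
  expect_gt(z$Z2, 0.95)
  expect_gt(z$PI_HAT, 0.97)
})

test_that("method-of-moments IBD recovers parent-offspring and unrelated expectations", {
  ped <- make_pedigree("parent_offspring")
  gm <- gene_drop(ped, sim_config(n_loci = 8000L, seed = 43L))
  p <- attr(gm, "true_freqs")
  z <- mom_ibd(gm$calls["r001_F1", ], gm$calls["r001_O1", ], p)
  expect_gt(z$Z1, 0.95)
  expect_lt(abs(z$PI_HAT - 0.5), 0.03)

  gm0 <- gene_drop(make_pedigree("unrelated"), sim_config(n_loci = 8000L, seed = 44L))
  z0 <- mom_ibd(gm0$calls[1, ], gm0$calls[2, ], attr(gm0, "true_freqs"))
  expect_gt(z0$Z0, 0.9)
  expect_lt(z0$PI_HAT, 0.05)
})

test_that("IBD state probabilities live on the simplex after constraint", {
  gm <- random_gm(8, 300, miss = 0.1, seed = 45)
  pairs <- ibd_ibs_pairs(gm, freqs = "sample")
  expect_equal(pairs$Z0 + pairs$Z1 + pairs$Z2, rep(1, nrow(pairs)),
               tolerance = 1e-12)
  expect_true(all(pairs$Z0 >= 0 & pairs$Z1 >= 0 & pairs$Z2 >= 0))
  expect_true(all(pairs$PI_HAT >= 0 & pairs$PI_HAT <= 1))
  expect_true(all(pairs$ibs0 + pairs$ibs1 + pairs$ibs2 == pairs$n_shared))
  expect_true(all(pairs$DST >= 0 & pairs$DST <= 1))
})

test_that("the all-pairs path agrees with the single-pair estimator", {
  gm <- random_gm(6, 400, miss = 0, seed = 46)
  pairs <- ibd_ibs_pairs(gm, freqs = "sample")
  p <- snpkin:::allele_freqs(gm)
  for (r in sample(nrow(pairs), 5)) {
    i <- pairs$id1[r]
    j <- pairs$id2[r]
    sc <- mom_ibd(gm$calls[i, ], gm$calls[j, ], p, n_samples = n_samples(gm))
    expect_equal(pairs$Z0[r], sc$Z0, tolerance = 1e-10)
    expect_equal(pairs$PI_HAT[r], sc$PI_HAT, tolerance = 1e-10)
    ic <- ibs_counts(gm$calls[i, ], gm$calls[j, ])
    expect_equal(pairs$ibs0[r], ic$ibs0)
    expect_equal(pairs$DST[r], ic$dst)
  }
})

test_that("mean PI_HAT orders pedigree classes correctly", {
  mean_pihat <- function(template, seed) {
    vals <- numeric(0)
    ped <- make_pedigree(template, n_replicates = 25L)
    gm <- gene_drop(ped, sim_config(n_loci = 2500L, seed = seed))
    p <- attr(gm, "true_freqs")
    fp <- attr(ped, "focal_pairs")
    for (r in seq_len(nrow(fp))) {
      z <- mom_ibd(gm$calls[fp[r, 1L], ], gm$calls[fp[r, 2L], ], p)
      vals <- c(vals, z$PI_HAT)
    }
    mean(vals)
  }
  fs <- mean_pihat("full_sibs", 51)
  hs <- mean_pihat("half_sibs", 52)
  fc <- mean_pihat("first_cousins", 53)
  un <- mean_pihat("unrelated", 54)
  expect_gt(fs, hs)
  expect_gt(hs, fc)
  expect_gt(fc, un)
  expect_lt(abs(fs - 0.5), 0.05)
  expect_lt(abs(hs - 0.25), 0.05)
})

test_that("PI_HAT approximates twice the GRM coancestry for non-inbred pairs", {
  res <- simulate_pedigree_recovery("full_sibs", n_replicates = 25L,
                                    n_loci = 3000L, seed = 55L)
  ped <- make_pedigree("full_sibs", n_replicates = 25L)
  gm <- gene_drop(ped, sim_config(n_loci = 3000L,
                                  seed = (55L + 7919L) %% 2147483647L))
  p <- attr(gm, "true_freqs")
  fp <- attr(ped, "focal_pairs")
  pihat <- vapply(seq_len(nrow(fp)), function(r) {
    mom_ibd(gm$calls[fp[r, 1L], ], gm$calls[fp[r, 2L], ], p)$PI_HAT
  }, numeric(1))
  expect_lt(abs(mean(pihat) - 2 * mean(res$theta)), 0.03)
})

test_that("pair_table merges relatedness, IBD and metadata", {
  gm <- random_gm(5, 200, miss = 0.05, seed = 47)
  meta <- data.frame(sample_id = gm$samples,
                     population = c("A", "A", "B", "B", "B"),
                     river_km = c(5, 5, 17, 17, 17))
  pt <- pair_table(gm, meta, freqs = attr(gm, "true_freqs"))
  expect_equal(nrow(pt), choose(5, 2))
  expect_named(pt, c("id1", "id2", "pop1", "pop2", "theta", "dom", "Z0", "Z1",
                     "Z2", "PI_HAT", "DST", "dist_km", "ibs0", "ibs1", "ibs2",
                     "n_shared"))
  expect_equal(sort(unique(pt$dist_km)), c(0, 12))
  expect_error(pair_table(gm, meta[-1, ], freqs = attr(gm, "true_freqs")),
               "metadata missing")
})
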