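test_that("templates build the canonical minimal pedigrees with focal flags", {
  fs <- make_pedigree("full_sibs")
  expect_equal(nrow(fs), 4L)
  expect_equal(sum(is.na(fs$sire)), 2L)
  expect_equal(attr(fs, "focal_pairs")[1, ], c("r001_S1", "r001_S2"))

  fcm <- make_pedigree("first_cousin_mating")
  expect_equal(nrow(fcm), 9L)                 # 4 founders, 2 sibs, 2 cousins, 1 offspring
  expect_equal(sum(is.na(fcm$sire)), 4L)
  expect_equal(attr(fcm, "focal_ids"), "r001_O1")

  hsm <- make_pedigree("half_sib_mating")
  shared <- intersect(hsm$sire[hsm$id %in% c("r001_H1", "r001_H2")],
                      hsm$sire[hsm$id %in% c("r001_H1", "r001_H2")])
  expect_equal(shared, "r001_F1")             # one shared parent

  expect_error(make_pedigree("cousins_thrice_removed"), "arg")

  # replicates have disjoint founders
  two <- make_pedigree("full_sibs", n_replicates = 2L)
  expect_equal(nrow(two), 8L)
  expect_equal(nrow(attr(two, "focal_pairs")), 2L)
  expect_length(intersect(two$id[startsWith(two$id, "r001")],
                          two$id[startsWith(two$id, "r002")]), 0L)
})

test_that("pedigree validation rejects cycles, half-parents and unknown parents", {
  expect_error(pedigree(c("a", "b"), c(NA, "c"), c(NA, "a")), "not in pedigree")
  expect_error(pedigree(c("a", "b"), c(NA, "a"), c(NA, NA)), "two parents or none")
  expect_error(pedigree(c("a", "b"), c("b", "a"), c("b", "a")), "cycle")
})

test_that("expected coefficients reproduce the classical pedigree values", {
  ec_fs <- expected_coefficients(make_pedigree("full_sibs"), "r001_S1", "r001_S2")
  expect_equal(ec_fs$kinship, 1 / 4)
  expect_equal(ec_fs$dominance, 1 / 4)

  ec_dfc <- expected_coefficients(make_pedigree("double_first_cousins"),
                                  "r001_X", "r001_Y")
  expect_equal(ec_dfc$kinship, 1 / 8)
  expect_equal(ec_dfc$dominance, 1 / 16)

  fcm <- make_pedigree("first_cousin_mating")
  ec_fc <- expected_coefficients(fcm, "r001_C1", "r001_C2")
  expect_equal(ec_fc$kinship, 1 / 16)          # first cousins
  K <- kinship_matrix(fcm)
  expect_equal(2 * K["r001_O1", "r001_O1"] - 1, 1 / 16)  # offspring F

  hsm <- make_pedigree("half_sib_mating")
  K2 <- kinship_matrix(hsm)
  expect_equal(2 * K2["r001_O1", "r001_O1"] - 1, 1 / 8)

  # parent-offspring: kinship 1/4, no dominance (one member is a founder)
  po <- expected_coefficients(make_pedigree("parent_offspring"),
                              "r001_F1", "r001_O1")
  expect_equal(po$kinship, 1 / 4)
  expect_equal(po$dominance, 0)
})

test_that("dominance involving an inbred individual is flagged approximate", {
  ped <- pedigree(
    id   = c("F1", "F2", "S1", "S2", "O1", "O2"),
    sire = c(NA, NA, "F1", "F1", "S1", "S1"),
    dam  = c(NA, NA, "F2", "F2", "S2", "S2")
  )
  ec <- expected_coefficients(ped, "O1", "O2")   # full sibs from a sib mating
  expect_false(ec$dominance_exact)
  expect_equal(ec$F_i, 1 / 4)
})

test_that("expected coefficients match exhaustive transmission enumeration on small templates", {
  for (template in c("parent_offspring", "full_sibs", "half_sibs")) {
    ped <- make_pedigree(template)
    fp <- attr(ped, "focal_pairs")[1, ]
    ec <- expected_coefficients(ped, fp[1], fp[2])
    orc <- oracle_pedigree_enum(ped, fp[1], fp[2])
    expect_equal(ec$kinship, orc$kinship, label = template)
    expect_equal(ec$dominance, orc$dominance, label = template)
    expect_equal(ec$F_i, orc$F_i, label = template)
  }
})

test_that("gene dropping is deterministic given a seed, down to VCF bytes", {
  ped <- make_pedigree("half_sibs", n_replicates = 3L)
  cfg <- sim_config(n_loci = 200L, seed = 77L, missing_rate = 0.05,
                    max_missing = 2L)
  g1 <- gene_drop(ped, cfg)
  g2 <- gene_drop(ped, cfg)
  expect_identical(g1$calls, g2$calls)
  f1 <- tempfile()
  f2 <- tempfile()
  write_vcf(g1, f1)
  write_vcf(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(all(missing_counts(g1) <= 2L))
})

test_that("founder heterozygosity tracks 2pq", {
  ped <- make_pedigree("unrelated", n_replicates = 100L)
  gm <- gene_drop(ped, sim_config(n_loci = 500L, seed = 78L))
  p <- attr(gm, "true_freqs")
  het <- colMeans(gm$calls == 1L)
  expect_lt(mean(abs(het - 2 * p * (1 - p))), 0.05)
  expect_lt(abs(mean(het) - mean(2 * p * (1 - p))), 0.01)
})

test_that("realized focal kinship converges to the pedigree expectation", {
  res <- simulate_pedigree_recovery("half_sibs", n_replicates = 40L,
                                    n_loci = 3000L, seed = 79L)
  expect_lt(abs(mean(res$theta) - 1 / 8), 0.015)
})

test_that("the study fixture has the study's shape", {
  fx <- make_study_fixture(n_loci = 2500L, seed = 5L)
  expect_equal(n_samples(fx$genotypes), 43L)
  expect_equal(as.vector(table(fx$meta$population)), c(11L, 20L, 12L))
  expect_equal(sort(unique(fx$meta$river_km)), c(5, 17, 25))
  expect_true(all(missing_counts(fx$genotypes) <= 4L))
  expect_equal(nrow(fx$truth$inbred), 8L)      # 3 + 2 in A, 2 in B, 1 in C
  expect_equal(sum(fx$truth$inbred$expected_F == 1 / 16), 3L)
  expect_equal(sum(fx$truth$inbred$expected_F == 1 / 8), 5L)
  expect_equal(nrow(fx$truth$related_pairs), 2L)
  # deterministic given the seed
  fx2 <- make_study_fixture(n_loci = 2500L, seed = 5L)
  expect_identical(fx$genotypes$calls, fx2$genotypes$calls)
})

test_that("an embedded duplicate is detected by PI_HAT ~ 1", {
  fx <- make_study_fixture(n_loci = 3000L, seed = 6L, add_duplicate = TRUE)
  dup <- fx$truth$duplicate_pair
  gm <- fx$genotypes
  keep <- snpkin:::allele_freqs(gm)
  ok <- keep > 0 & keep < 1
  gm <- subset_loci(gm, ok)
  z <- mom_ibd(gm$calls[dup[1], ], gm$calls[dup[2], ],
               snpkin:::allele_freqs(gm), n_samples = 43)
  expect_gt(z$PI_HAT, 0.95)
})

test_that("fixture files round-trip through the standard readers", {
  out <- file.path(tempdir(), "fxout")
  fx <- make_study_fixture(n_loci = 400L, seed = 8L, out_dir = out)
  gm <- read_vcf(file.path(out, "genotypes.vcf"))
  meta <- read_sample_table(file.path(out, "samples.tsv"))
  expect_identical(gm$calls, fx$genotypes$calls)
  expect_equal(meta$sample_id, fx$meta$sample_id)
  expect_equal(meta$river_km, fx$meta$river_km)
})
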