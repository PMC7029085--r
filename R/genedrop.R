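#' Simulation configuration for gene dropping
#'
#' Parameters of the synthetic-data generator. Loci are unlinked
#' biallelic SNPs; founder ALT frequencies are drawn per locus from a
#' uniform law on `freq_range` (default \[0.1, 0.9\], so that a 5% MAF
#' filter rarely removes loci by sampling noise alone) unless an explicit
#' `freqs` vector is supplied. A fixed `seed` makes the generated
#' genotypes, and any VCF written from them, byte-identical across runs.
#'
#' @param n_loci Number of loci.
#' @param freq_range Lower/upper bound of the uniform founder-frequency
#'   law.
#' @param freqs Optional explicit per-locus founder frequencies
#'   (overrides `freq_range`).
#' @param missing_rate Per-genotype missingness probability (default 0).
#' @param max_missing Cap on missing genotypes per locus (default `Inf`);
#'   set to 4 to emulate the post-filter structure of a 43-individual
#'   study panel.
#' @param seed Integer seed (`NULL` = use the current RNG stream).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_loci = 1000L, freq_range = c(0.1, 0.9), freqs = NULL,
                       missing_rate = 0, max_missing = Inf, seed = NULL) {
  stopifnot(n_loci >= 1L, length(freq_range) == 2L,
            freq_range[1L] > 0, freq_range[2L] < 1,
            freq_range[1L] <= freq_range[2L],
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(freqs)) {
    stopifnot(length(freqs) == n_loci)
    check_poly(freqs)
  }
  structure(list(n_loci = as.integer(n_loci), freq_range = freq_range,
                 freqs = freqs, missing_rate = missing_rate,
                 max_missing = max_missing, seed = seed),
            class = "sim_config")
}

#' Gene dropping through a pedigree
#'
#' Simulates genotypes by Mendelian transmission: founder alleles are
#' drawn independently per locus at the founder frequency, and each
#' transmission passes one of the parent's two alleles chosen uniformly
#' at random, independently across loci (no linkage). Missing genotypes,
#' if requested, are masked at random per locus up to the configured cap.
#'
#' @param ped A [pedigree()].
#' @param config A [sim_config()].
#' @return A [genotype_matrix()] (one row per pedigree member, loci named
#'   `snp00001`...) with attributes `"true_freqs"` (the founder ALT
#'   frequencies used) and `"pedigree"`.
#' @examples
#' ped <- make_pedigree("full_sibs")
#' gm <- gene_drop(ped, sim_config(n_loci = 100, seed = 1))
#' @export
gene_drop <- function(ped, config = sim_config()) {
  stopifnot(inherits(ped, "pedigree"), inherits(config, "sim_config"))
  with_seed(config$seed, {
    m <- config$n_loci
    n <- nrow(ped)
    p <- config$freqs %||% stats::runif(m, config$freq_range[1L], config$freq_range[2L])
    a1 <- matrix(0L, n, m)
    a2 <- matrix(0L, n, m)
    si <- match(ped$sire, ped$id)
    di <- match(ped$dam, ped$id)
    for (k in seq_len(n)) {
      if (is.na(si[k])) {
        a1[k, ] <- stats::rbinom(m, 1L, p)
        a2[k, ] <- stats::rbinom(m, 1L, p)
      } else {
        pick <- stats::runif(m) < 0.5
        tmp <- a2[si[k], ]
        tmp[pick] <- a1[si[k], pick]
        a1[k, ] <- tmp
        pick <- stats::runif(m) < 0.5
        tmp <- a2[di[k], ]
        tmp[pick] <- a1[di[k], pick]
        a2[k, ] <- tmp
      }
    }
    calls <- a1 + a2
    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
      cap <- config$max_missing
      if (is.finite(cap)) {
        over <- which(colSums(mask) > cap)
        for (k in over) {
          hit <- which(mask[, k])
          mask[hit[-sample.int(length(hit), cap)], k] <- FALSE
        }
      }
      calls[mask] <- NA_integer_
    }
    loci <- data.frame(id = sprintf("snp%05d", seq_len(m)), chrom = "sim",
                       pos = seq_len(m), ref = "A", alt = "G",
                       qual = NA_real_, stringsAsFactors = FALSE)
    gm <- genotype_matrix(calls, loci, samples = ped$id)
    attr(gm, "true_freqs") <- p
    attr(gm, "pedigree") <- ped
    gm
  })
}

#' Recover pedigree expectations by replicated gene dropping
#'
#' The validation engine behind the package's simulation checks: a
#' relationship template is gene-dropped in many independent replicate
#' families, the within-SNP-standardized relationship matrices are built
#' with the true founder frequencies, and the focal entries are
#' collected. With enough loci their means recover the classical
#' pedigree expectations (e.g. mean `F` of first-cousin-mating offspring
#' = 1/16, mean dominance of full-sib pairs = 1/4).
#'
#' Replicates are processed in batches so memory stays modest; every
#' relationship-matrix entry involves only the two individuals concerned,
#' so batching does not change any focal value.
#'
#' @param template A [make_pedigree()] template name.
#' @param n_replicates Number of replicate families (default 200).
#' @param n_loci Loci per replicate (default 20000).
#' @param seed Integer seed.
#' @param batch_size Replicates per batch (default 50).
#' @return List with `F` (focal-individual inbreeding estimates, for the
#'   inbred-mating templates), `theta` and `dominance` (focal-pair
#'   estimates, for the pair templates), each a numeric vector with one
#'   entry per replicate, plus `template`, `n_loci`, `n_replicates`.
#' @export
simulate_pedigree_recovery <- function(template, n_replicates = 200L,
                                       n_loci = 20000L, seed = NULL,
                                       batch_size = 50L) {
  stopifnot(n_replicates >= 1L, batch_size >= 1L)
  out_F <- numeric(0)
  out_theta <- numeric(0)
  out_dom <- numeric(0)
  done <- 0L
  b <- 0L
  while (done < n_replicates) {
    b <- b + 1L
    nb <- min(batch_size, n_replicates - done)
    ped <- make_pedigree(template, n_replicates = nb)
    batch_seed <- if (is.null(seed)) NULL else (seed + 7919L * b) %% 2147483647L
    gm <- gene_drop(ped, sim_config(n_loci = n_loci, seed = batch_seed))
    rel <- build_grms(gm, freqs = attr(gm, "true_freqs"))
    fi <- attr(ped, "focal_ids")
    if (length(fi)) out_F <- c(out_F, unname(grm_inbreeding(rel)[fi]))
    fp <- attr(ped, "focal_pairs")
    if (nrow(fp)) {
      out_theta <- c(out_theta, rel$A[fp] / 2)
      out_dom <- c(out_dom, rel$D[fp])
    }
    done <- done + nb
  }
  list(F = out_F, theta = out_theta, dominance = out_dom,
       template = template, n_loci = n_loci, n_replicates = n_replicates)
}

#' Synthetic study fixture: 43 individuals, three river locations
#'
#' Generates a full synthetic data set shaped like a small isolated
#' river population sampled at three locations: 43 diploid individuals
#' in populations A/B/C of sizes 11/20/12 positioned at river km
#' 5/17/25, genotyped at unlinked biallelic SNPs. Population structure
#' is created by drifting each location's founder allele frequencies
#' away from a common ancestral pool with a Balding-Nichols Beta model
#' (location A strongly, C slightly, B not at all), which reproduces the
#' observed pattern of one location separating from the other two.
#'
#' Relatives are embedded the way the real sample shows them: offspring
#' of first-cousin matings (3 in A) and of half-sib matings (2 in A, 2 in
#' B, 1 in C), plus one sampled half-sib pair in A and one in B; all
#' other individuals are unrelated founders of their location. Ancestors
#' are not part of the sample. Per-locus QUAL scores (a few below 30) and
#' random missingness capped at 4 individuals per locus exercise the
#' locus filters; at the default 16,500 input loci about 15,000 pass the
#' default criteria.
#'
#' @param n_loci Number of simulated loci before filtering.
#' @param seed Integer seed (required: the fixture is meant to be
#'   reproducible).
#' @param missing_rate Per-genotype missingness probability.
#' @param fst Named vector of per-population drift levels (Balding-
#'   Nichols F_ST against the ancestral pool).
#' @param low_qual_rate Fraction of loci given QUAL below 30.
#' @param add_duplicate Replace the last C individual's genotypes with a
#'   copy of the first C individual's (for detectability checks)?
#' @param out_dir If non-`NULL`, write `genotypes.vcf`, `samples.tsv` and
#'   `truth_inbred.tsv` / `truth_pairs.tsv` there.
#' @return List with `genotypes` (a [genotype_matrix()] of the 43 sampled
#'   individuals), `meta` (sample metadata data frame) and `truth` (list:
#'   `inbred` data frame of embedded inbred individuals with expected
#'   `F`; `related_pairs` data frame of embedded pairs with expected
#'   kinship; `ancestral_freqs`; `pop_freqs` matrix; `duplicate_pair`).
#' @export
make_study_fixture <- function(n_loci = 16500L, seed = 1L,
                               missing_rate = 0.01,
                               fst = c(A = 0.06, B = 0, C = 0.015),
                               low_qual_rate = 0.03,
                               add_duplicate = FALSE, out_dir = NULL) {
  sizes <- c(A = 11L, B = 20L, C = 12L)
  river_km <- c(A = 5, B = 17, C = 25)
  with_seed(seed, {
    m <- as.integer(n_loci)
    p0 <- stats::runif(m, 0.1, 0.9)
    pop_freqs <- sapply(names(sizes), function(pop) {
      f <- fst[[pop]]
      if (f <= 0) return(p0)
      drifted <- stats::rbeta(m, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
      pmin(pmax(drifted, 1e-4), 1 - 1e-4)
    })

    # embedded pedigree units per population (ancestors unsampled)
    units <- list(
      A = c(rep("first_cousin_mating", 3L), rep("half_sib_mating", 2L),
            "half_sib_pair", rep("unrelated_one", 4L)),
      B = c(rep("half_sib_mating", 2L), "half_sib_pair",
            rep("unrelated_one", 16L)),
      C = c("half_sib_mating", rep("unrelated_one", 11L))
    )

    all_calls <- NULL
    meta <- list()
    inbred <- list()
    rel_pairs <- list()
    for (pop in names(sizes)) {
      res <- drop_population_units(units[[pop]], pop, pop_freqs[, pop], m)
      stopifnot(nrow(res$calls) == sizes[[pop]])
      all_calls <- rbind(all_calls, res$calls)
      meta[[pop]] <- data.frame(sample_id = rownames(res$calls),
                                population = pop, river_km = river_km[[pop]],
                                stringsAsFactors = FALSE)
      inbred[[pop]] <- res$inbred
      rel_pairs[[pop]] <- res$pairs
    }
    meta <- do.call(rbind, meta)
    rownames(meta) <- NULL

    dup <- NULL
    if (add_duplicate) {
      c_ids <- meta$sample_id[meta$population == "C"]
      dup <- c(c_ids[1L], c_ids[length(c_ids)])
      all_calls[dup[2L], ] <- all_calls[dup[1L], ]
    }

    if (missing_rate > 0) {
      mask <- matrix(stats::runif(length(all_calls)) < missing_rate,
                     nrow(all_calls), ncol(all_calls))
      over <- which(colSums(mask) > 4L)
      for (k in over) {
        hit <- which(mask[, k])
        mask[hit[-sample.int(length(hit), 4L)], k] <- FALSE
      }
      all_calls[mask] <- NA_integer_
    }

    qual <- round(stats::runif(m, 31, 200), 1)
    low <- stats::runif(m) < low_qual_rate
    qual[low] <- round(stats::runif(sum(low), 10, 29.5), 1)
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), character(1))
    chrom <- sprintf("chr%02d", 1L + (seq_len(m) - 1L) %% 30L)
    pos <- 100L + 50L * ((seq_len(m) - 1L) %/% 30L)
    loci <- data.frame(id = sprintf("snp%05d", seq_len(m)), chrom = chrom,
                       pos = pos, ref = unname(ref), alt = unname(alt),
                       qual = qual, stringsAsFactors = FALSE)
    gm <- genotype_matrix(all_calls, loci, samples = rownames(all_calls))

    truth <- list(
      inbred = do.call(rbind, inbred),
      related_pairs = do.call(rbind, rel_pairs),
      ancestral_freqs = p0, pop_freqs = pop_freqs,
      duplicate_pair = dup
    )
    rownames(truth$inbred) <- rownames(truth$related_pairs) <- NULL

    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_vcf(gm, file.path(out_dir, "genotypes.vcf"))
      utils::write.table(meta, file.path(out_dir, "samples.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(truth$inbred, file.path(out_dir, "truth_inbred.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(truth$related_pairs,
                         file.path(out_dir, "truth_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(genotypes = gm, meta = meta, truth = truth)
  })
}

# Gene-drop the listed pedigree units for one population and return the
# sampled individuals' calls (rows named <pop><index>), the embedded
# inbred individuals and the embedded related sampled pairs.
drop_population_units <- function(unit_names, pop, p, m) {
  calls <- NULL
  ids <- character(0)
  inbred <- data.frame(id = character(0), template = character(0),
                       expected_F = numeric(0), stringsAsFactors = FALSE)
  pairs <- data.frame(id1 = character(0), id2 = character(0),
                      relationship = character(0), expected_kinship = numeric(0),
                      stringsAsFactors = FALSE)
  counter <- 0L
  next_id <- function() {
    counter <<- counter + 1L
    sprintf("%s%02d", pop, counter)
  }
  cfg <- function() sim_config(n_loci = m, freqs = p)
  for (u in unit_names) {
    if (u == "unrelated_one") {
      ped <- pedigree("X1")
      gm <- gene_drop(ped, cfg())
      id <- next_id()
      row <- gm$calls["X1", , drop = FALSE]
      rownames(row) <- id
      calls <- rbind(calls, row)
    } else if (u == "half_sib_pair") {
      ped <- make_pedigree("half_sibs")
      gm <- gene_drop(ped, cfg())
      id1 <- next_id(); id2 <- next_id()
      rows <- gm$calls[attr(ped, "focal_pairs")[1L, ], , drop = FALSE]
      rownames(rows) <- c(id1, id2)
      calls <- rbind(calls, rows)
      pairs <- rbind(pairs, data.frame(id1 = id1, id2 = id2,
                                       relationship = "half_sibs",
                                       expected_kinship = 1 / 8,
                                       stringsAsFactors = FALSE))
    } else {
      ped <- make_pedigree(u)
      gm <- gene_drop(ped, cfg())
      id <- next_id()
      row <- gm$calls[attr(ped, "focal_ids")[1L], , drop = FALSE]
      rownames(row) <- id
      calls <- rbind(calls, row)
      ec <- expected_coefficients(ped, attr(ped, "focal_pairs")[1L, 1L],
                                  attr(ped, "focal_pairs")[1L, 2L])
      inbred <- rbind(inbred, data.frame(id = id, template = u,
                                         expected_F = ec$kinship,
                                         stringsAsFactors = FALSE))
    }
  }
  list(calls = calls, inbred = inbred, pairs = pairs)
}
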