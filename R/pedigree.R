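#' Pedigree container
#'
#' A sex-agnostic directed acyclic pedigree: each individual has either
#' two recorded parents or none (founder). Used to drive gene dropping
#' and to compute exact pedigree expectations of kinship, inbreeding and
#' dominance coefficients.
#'
#' @param id Character vector of unique individual ids.
#' @param sire,dam Parent ids (`NA` for founders; both present or both
#'   absent). Referenced parents must appear in `id`.
#' @return Object of class `c("pedigree", "data.frame")` with columns
#'   `id`, `sire`, `dam`, ordered so that parents precede offspring.
#' @export
pedigree <- function(id, sire = NA_character_, dam = NA_character_) {
  ped <- data.frame(id = as.character(id),
                    sire = as.character(sire), dam = as.character(dam),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ped$id)) stop("duplicate individual ids")
  half <- xor(is.na(ped$sire), is.na(ped$dam))
  if (any(half)) stop("individuals must have two parents or none: ",
                      paste(ped$id[half], collapse = ", "))
  parents <- stats::na.omit(c(ped$sire, ped$dam))
  unknown <- setdiff(parents, ped$id)
  if (length(unknown)) stop("referenced parent(s) not in pedigree: ",
                            paste(unique(unknown), collapse = ", "))
  ord <- topo_order(ped)
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn topological sort; errors on cycles (an individual being its own
# ancestor).
topo_order <- function(ped) {
  n <- nrow(ped)
  placed <- rep(FALSE, n)
  ord <- integer(0)
  repeat {
    ready <- which(!placed &
                     (is.na(ped$sire) | ped$sire %in% ped$id[placed]) &
                     (is.na(ped$dam) | ped$dam %in% ped$id[placed]))
    if (!length(ready)) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  if (length(ord) < n) stop("pedigree contains a cycle involving: ",
                            paste(ped$id[!placed], collapse = ", "))
  ord
}

#' @param x A `pedigree`.
#' @param ... Ignored.
#' @rdname pedigree
#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals (%d founders)\n",
              nrow(x), sum(is.na(x$sire))))
  fp <- attr(x, "focal_pairs")
  fi <- attr(x, "focal_ids")
  if (!is.null(fp) && nrow(fp)) cat("  focal pairs:", nrow(fp), "\n")
  if (!is.null(fi) && length(fi)) cat("  focal individuals:", length(fi), "\n")
  invisible(x)
}

#' Canonical relationship-template pedigrees
#'
#' Builds the minimal pedigree realizing a classical relationship (or
#' inbred-mating) template, optionally replicated with disjoint founders.
#' The individuals or pairs whose coefficients the template is about are
#' flagged in attributes `"focal_pairs"` (2-column character matrix) and
#' `"focal_ids"` (character vector, for the inbred-mating templates).
#'
#' Templates and their classical expectations (kinship f of the focal
#' pair, or inbreeding F of the focal offspring):
#' `unrelated` (f = 0), `parent_offspring` (f = 1/4), `full_sibs`
#' (f = 1/4, dominance 1/4), `half_sibs` (f = 1/8), `first_cousins`
#' (f = 1/16), `double_first_cousins` (f = 1/8, dominance 1/16),
#' `first_cousin_mating` (focal offspring F = 1/16), `half_sib_mating`
#' (F = 1/8), `full_sib_mating` (F = 1/4).
#'
#' @param template Template name (see above).
#' @param n_replicates Number of disjoint copies (default 1); replicate
#'   ids are prefixed `r001_`, `r002_`, ...
#' @return A [pedigree()] with focal attributes.
#' @export
make_pedigree <- function(template = c("unrelated", "parent_offspring",
                                       "full_sibs", "half_sibs",
                                       "first_cousins", "double_first_cousins",
                                       "first_cousin_mating", "half_sib_mating",
                                       "full_sib_mating"),
                          n_replicates = 1L) {
  template <- match.arg(template)
  stopifnot(n_replicates >= 1L)
  unit <- pedigree_unit(template)
  rows <- list()
  fp <- list()
  fi <- character(0)
  for (r in seq_len(n_replicates)) {
    pre <- sprintf("r%03d_", r)
    tag <- function(x) ifelse(is.na(x), NA_character_, paste0(pre, x))
    rows[[r]] <- data.frame(id = tag(unit$ped$id), sire = tag(unit$ped$sire),
                            dam = tag(unit$ped$dam), stringsAsFactors = FALSE)
    if (!is.null(unit$focal_pair)) {
      fp[[length(fp) + 1L]] <- tag(unit$focal_pair)
    }
    if (!is.null(unit$focal_id)) fi <- c(fi, tag(unit$focal_id))
  }
  all_rows <- do.call(rbind, rows)
  ped <- pedigree(all_rows$id, all_rows$sire, all_rows$dam)
  attr(ped, "focal_pairs") <- if (length(fp)) do.call(rbind, fp) else
    matrix(character(0), 0L, 2L)
  attr(ped, "focal_ids") <- fi
  attr(ped, "template") <- template
  ped
}

pedigree_unit <- function(template) {
  P <- function(...) {
    d <- do.call(rbind, lapply(list(...), function(r) {
      data.frame(id = r[1L], sire = r[2L], dam = r[3L], stringsAsFactors = FALSE)
    }))
    d$sire[d$sire == "-"] <- NA_character_
    d$dam[d$dam == "-"] <- NA_character_
    d
  }
  switch(template,
    unrelated = list(
      ped = P(c("F1", "-", "-"), c("F2", "-", "-")),
      focal_pair = c("F1", "F2")),
    parent_offspring = list(
      ped = P(c("F1", "-", "-"), c("F2", "-", "-"), c("O1", "F1", "F2")),
      focal_pair = c("F1", "O1")),
    full_sibs = list(
      ped = P(c("F1", "-", "-"), c("F2", "-", "-"),
              c("S1", "F1", "F2"), c("S2", "F1", "F2")),
      focal_pair = c("S1", "S2")),
    half_sibs = list(
      ped = P(c("F1", "-", "-"), c("F2", "-", "-"), c("F3", "-", "-"),
              c("H1", "F1", "F2"), c("H2", "F1", "F3")),
      focal_pair = c("H1", "H2")),
    first_cousins = list(
      ped = P(c("G1", "-", "-"), c("G2", "-", "-"),
              c("M1", "-", "-"), c("M2", "-", "-"),
              c("P1", "G1", "G2"), c("P2", "G1", "G2"),
              c("C1", "P1", "M1"), c("C2", "P2", "M2")),
      focal_pair = c("C1", "C2")),
    double_first_cousins = list(
      ped = P(c("A", "-", "-"), c("B", "-", "-"),
              c("C", "-", "-"), c("D", "-", "-"),
              c("S1", "A", "B"), c("S2", "A", "B"),
              c("T1", "C", "D"), c("T2", "C", "D"),
              c("X", "S1", "T1"), c("Y", "S2", "T2")),
      focal_pair = c("X", "Y")),
    first_cousin_mating = list(
      ped = P(c("G1", "-", "-"), c("G2", "-", "-"),
              c("M1", "-", "-"), c("M2", "-", "-"),
              c("P1", "G1", "G2"), c("P2", "G1", "G2"),
              c("C1", "P1", "M1"), c("C2", "P2", "M2"),
              c("O1", "C1", "C2")),
      focal_pair = c("C1", "C2"), focal_id = "O1"),
    half_sib_mating = list(
      ped = P(c("F1", "-", "-"), c("F2", "-", "-"), c("F3", "-", "-"),
              c("H1", "F1", "F2"), c("H2", "F1", "F3"),
              c("O1", "H1", "H2")),
      focal_pair = c("H1", "H2"), focal_id = "O1"),
    full_sib_mating = list(
      ped = P(c("F1", "-", "-"), c("F2", "-", "-"),
              c("S1", "F1", "F2"), c("S2", "F1", "F2"),
              c("O1", "S1", "S2")),
      focal_pair = c("S1", "S2"), focal_id = "O1")
  )
}

#' Pedigree kinship matrix
#'
#' Exact kinship (coancestry) coefficients from the standard tabular
#' recursion: founders are unrelated and non-inbred
#' (`f(i,i) = 1/2`), and for an individual `j` with parents `s`, `d`
#' appearing after `i`, `f(i,j) = (f(i,s) + f(i,d))/2` and
#' `f(j,j) = (1 + f(s,d))/2`.
#'
#' @param ped A [pedigree()].
#' @return Symmetric matrix of kinship coefficients with id dimnames.
#' @export
kinship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  for (j in seq_len(n)) {
    if (is.na(si[j])) {
      K[j, j] <- 0.5
    } else {
      K[j, j] <- 0.5 * (1 + K[si[j], di[j]])
      for (i in seq_len(j - 1L)) {
        K[i, j] <- K[j, i] <- 0.5 * (K[i, si[j]] + K[i, di[j]])
      }
    }
  }
  K
}

#' Exact pedigree expectations for a pair
#'
#' Classical quantitative-genetic expectations for two pedigree members:
#' kinship `f_ij`, individual inbreeding coefficients (`F = f(sire, dam)`,
#' 0 for founders), the additive relationship `a_ij = 2 f_ij`, and the
#' dominance relationship
#' `d_ij = f(s_i, s_j) f(d_i, d_j) + f(s_i, d_j) f(d_i, s_j)`
#' (0 when either member is a founder). The dominance formula assumes a
#' non-inbred pair; if either member is inbred the value is returned but
#' flagged as approximate in `dominance_exact`.
#'
#' @param ped A [pedigree()].
#' @param i,j Individual ids.
#' @return List with `kinship`, `F_i`, `F_j`, `additive`, `dominance`,
#'   `dominance_exact`.
#' @export
expected_coefficients <- function(ped, i, j) {
  stopifnot(inherits(ped, "pedigree"))
  if (!all(c(i, j) %in% ped$id)) stop("unknown individual id")
  K <- kinship_matrix(ped)
  parent <- function(id, which) ped[[which]][match(id, ped$id)]
  inb <- function(id) {
    s <- parent(id, "sire")
    if (is.na(s)) 0 else K[s, parent(id, "dam")]
  }
  si <- parent(i, "sire"); di <- parent(i, "dam")
  sj <- parent(j, "sire"); dj <- parent(j, "dam")
  dom <- if (is.na(si) || is.na(sj) || i == j) {
    if (i == j) NA_real_ else 0
  } else {
    K[si, sj] * K[di, dj] + K[si, dj] * K[di, sj]
  }
  F_i <- inb(i)
  F_j <- inb(j)
  list(kinship = K[i, j], F_i = F_i, F_j = F_j,
       additive = 2 * K[i, j], dominance = dom,
       dominance_exact = !(F_i > 0 || F_j > 0))
}
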