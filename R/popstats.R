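#' Per-group summary statistics
#'
#' Mean, sample standard deviation (n - 1 denominator), minimum and
#' maximum of a statistic per group, plus an overall row. Groups of one
#' observation get `NA` standard deviation.
#'
#' @param values Numeric vector.
#' @param labels Group label per value.
#' @param total Include an overall `"Total"` row? Default `TRUE`.
#' @return Data frame with columns `group`, `n`, `mean`, `sd`, `min`,
#'   `max`.
#' @export
summarize_groups <- function(values, labels, total = TRUE) {
  stopifnot(length(values) == length(labels))
  labels <- as.character(labels)
  one <- function(v, lab) {
    v <- v[!is.na(v)]
    data.frame(group = lab, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_,
               stringsAsFactors = FALSE)
  }
  parts <- lapply(sort(unique(labels)), function(g) one(values[labels == g], g))
  if (total) parts <- c(parts, list(one(values, "Total")))
  do.call(rbind, parts)
}

#' Pair-class label for a pair of population labels
#'
#' Within-population pairs are labelled by the population itself;
#' between-population pairs by the two labels joined with `-` in sorted
#' order (so `"B", "A"` and `"A", "B"` both give `"A-B"`).
#'
#' @param pop1,pop2 Population labels of the two pair members.
#' @return Character vector of pair-class labels.
#' @export
pair_class <- function(pop1, pop2) {
  ifelse(pop1 == pop2, pop1,
         paste(pmin(pop1, pop2), pmax(pop1, pop2), sep = "-"))
}

#' Expected pair counts from group sizes
#'
#' Combinatorial check values for pair tables: `n(n-1)/2` pairs within
#' each group and `n_a * n_b` between each pair of groups.
#'
#' @param sizes Named integer vector of group sizes.
#' @return List with named vectors `within` and `between` (between names
#'   as `"A-B"` etc., sorted).
#' @export
pair_group_counts <- function(sizes) {
  stopifnot(!is.null(names(sizes)))
  within <- sizes * (sizes - 1) / 2
  gs <- sort(names(sizes))
  between <- numeric(0)
  if (length(gs) >= 2L) {
    idx <- pair_index(length(gs))
    between <- sizes[gs[idx[, 1L]]] * sizes[gs[idx[, 2L]]]
    names(between) <- paste(gs[idx[, 1L]], gs[idx[, 2L]], sep = "-")
  }
  list(within = within, between = between)
}

#' Pairwise group comparisons with compact letter display
#'
#' Fits the one-way fixed-effect model `y = mu + group + e` and tests all
#' pairwise group contrasts with the pooled residual variance. By default
#' the contrast p-values are unadjusted; `adjust = "tukey"` applies
#' Tukey's honest significant difference instead. Groups sharing no
#' common letter differ significantly at level `alpha`.
#'
#' @param values Numeric vector of observations.
#' @param labels Group label per observation.
#' @param alpha Significance level for the letter display (default 0.05).
#' @param adjust `"none"` (pairwise t tests on the pooled variance) or
#'   `"tukey"`.
#' @return List with `p_values` (symmetric matrix of contrast p-values),
#'   `letters` (named character vector), `means`, `anova_p` (overall
#'   F-test p-value) and `model` (the fitted `lm`). Groups with fewer
#'   than 2 observations are dropped with a warning.
#' @export
compare_groups <- function(values, labels, alpha = 0.05,
                           adjust = c("none", "tukey")) {
  adjust <- match.arg(adjust)
  stopifnot(length(values) == length(labels))
  labels <- as.character(labels)
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]
  labels <- labels[ok]
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("group(s) with fewer than 2 observations excluded: ",
            paste(small, collapse = ", "))
    keep <- !labels %in% small
    values <- values[keep]
    labels <- labels[keep]
  }
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("at least two groups with >= 2 observations are required")
  g <- factor(labels, levels = groups)
  fit <- stats::lm(values ~ g)
  anova_tab <- stats::anova(fit)
  means <- tapply(values, g, mean)

  k <- length(groups)
  pmat <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  diag(pmat) <- 1
  if (adjust == "none") {
    pt <- stats::pairwise.t.test(values, g, p.adjust.method = "none",
                                 pool.sd = TRUE)$p.value
    for (a in rownames(pt)) for (b in colnames(pt)) {
      if (!is.na(pt[a, b])) pmat[a, b] <- pmat[b, a] <- pt[a, b]
    }
  } else {
    tk <- stats::TukeyHSD(stats::aov(values ~ g))$g
    cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (r in seq_along(cmp)) {
      a <- cmp[[r]][1L]; b <- cmp[[r]][2L]
      pmat[a, b] <- pmat[b, a] <- tk[r, "p adj"]
    }
  }
  letters_out <- cld_letters(pmat, means, alpha)
  list(p_values = pmat, letters = letters_out, means = means,
       anova_p = anova_tab[["Pr(>F)"]][1L], model = fit)
}

# Compact letter display: letters = maximal cliques of the
# "not significantly different" graph, ordered by descending group mean.
cld_letters <- function(pmat, means, alpha) {
  groups <- names(means)[order(-means)]
  k <- length(groups)
  nonsig <- pmat[groups, groups, drop = FALSE] >= alpha
  diag(nonsig) <- TRUE
  cliques <- list()
  for (code in seq_len(2^k) - 1L) {
    members <- which(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0L)
    if (!length(members)) next
    sub <- nonsig[members, members, drop = FALSE]
    if (!all(sub)) next
    maximal <- all(vapply(setdiff(seq_len(k), members), function(extra) {
      !all(nonsig[c(members, extra), c(members, extra)])
    }, logical(1)))
    if (maximal) cliques[[length(cliques) + 1L]] <- members
  }
  cliques <- cliques[order(vapply(cliques, min, integer(1)))]
  out <- stats::setNames(rep("", k), groups)
  for (ci in seq_along(cliques)) {
    out[cliques[[ci]]] <- paste0(out[cliques[[ci]]], letters[ci])
  }
  out[names(means)]
}

#' Regression of coancestry on geographic distance
#'
#' Isolation-by-distance test: ordinary least squares of pairwise
#' coancestry `theta` on the between-individual distance `dist_km`,
#' reported together with a Mantel permutation test. Pairs sharing an
#' individual are not independent, so the OLS p-value is
#' anti-conservative by construction; the Mantel test permutes
#' individuals and is the dependence-robust companion. Its p-value is
#' one-sided in the direction of the observed correlation, with the
#' observed statistic included in the permutation distribution (so
#' `p >= 1/(n_perm + 1)`).
#'
#' @param pairs A [pair_table()] with `theta` and `dist_km` filled in.
#' @param n_perm Number of Mantel permutations (default 9999).
#' @param seed Optional seed for the permutations.
#' @return An object of class `distance_regression`: list with `slope`,
#'   `intercept`, `r` (Pearson correlation), `p_ols`, `p_mantel`,
#'   `mantel_r`, `n_pairs`.
#' @export
regress_on_distance <- function(pairs, n_perm = 9999L, seed = NULL) {
  stopifnot(all(c("id1", "id2", "theta", "dist_km") %in% names(pairs)))
  if (any(is.na(pairs$dist_km)) || any(is.na(pairs$theta))) {
    stop("`theta` and `dist_km` must be complete")
  }
  if (length(unique(pairs$dist_km)) < 3L) {
    stop("at least 3 distinct pair distances are required")
  }
  fit <- stats::lm(theta ~ dist_km, data = pairs)
  co <- summary(fit)$coefficients

  ids <- unique(c(pairs$id1, pairs$id2))
  n <- length(ids)
  i <- match(pairs$id1, ids)
  j <- match(pairs$id2, ids)
  dm <- tm <- matrix(0, n, n)
  dm[cbind(i, j)] <- dm[cbind(j, i)] <- pairs$dist_km
  tm[cbind(i, j)] <- tm[cbind(j, i)] <- pairs$theta
  mt <- with_seed(seed, vegan::mantel(stats::as.dist(dm), stats::as.dist(tm),
                                      method = "pearson", permutations = n_perm))
  r_obs <- unname(mt$statistic)
  perm <- mt$perm
  p_mantel <- if (r_obs >= 0) {
    (1 + sum(perm >= r_obs)) / (length(perm) + 1)
  } else {
    (1 + sum(perm <= r_obs)) / (length(perm) + 1)
  }
  structure(list(slope = unname(co["dist_km", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 r = stats::cor(pairs$theta, pairs$dist_km),
                 p_ols = unname(co["dist_km", "Pr(>|t|)"]),
                 p_mantel = p_mantel, mantel_r = r_obs,
                 n_pairs = nrow(pairs)),
            class = "distance_regression")
}

#' @param x A `distance_regression`.
#' @param ... Ignored.
#' @rdname regress_on_distance
#' @export
print.distance_regression <- function(x, ...) {
  cat(sprintf("theta ~ distance: slope %.3g (r = %.3f), OLS p = %.3g, Mantel p = %.3g (%d pairs)\n",
              x$slope, x$r, x$p_ols, x$p_mantel, x$n_pairs))
  invisible(x)
}
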