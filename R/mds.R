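#' Classical (metric) multidimensional scaling
#'
#' Torgerson's classical scaling of a symmetric distance matrix: the
#' squared distances are double-centered with the centering projector `J
#' = I - 11'/n`, `B = -J D^2 J / 2` is eigendecomposed, and the
#' coordinates are the leading eigenvectors scaled by the square roots of
#' their (non-negative) eigenvalues. Eigenvalues are returned in
#' descending order; any non-positive eigenvalue among the requested
#' dimensions yields an all-zero axis, and the count of negative
#' eigenvalues overall is reported. Axis signs are not identifiable.
#'
#' @param d Symmetric non-negative distance matrix with zero diagonal
#'   (or a `dist` object).
#' @param k Number of dimensions to return (`k <= n - 1`).
#' @return An object of class `mds_result`: list with `coordinates`
#'   (n x k, columns `C1..Ck`), `eigenvalues` (first k, descending),
#'   `n_negative_eigenvalues`, and `distance_matrix_used`.
#' @examples
#' d <- as.matrix(dist(cbind(c(0, 3, 0), c(0, 0, 4))))
#' classical_mds(d, k = 2)$eigenvalues
#' @export
classical_mds <- function(d, k = 3L) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("`d` must be a square matrix")
  n <- nrow(d)
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  if (any(d < 0)) stop("distances must be non-negative")
  if (k < 1L || k > n - 1L) stop("`k` must be between 1 and n - 1")
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (d * d) %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- eg$values
  coords <- eg$vectors[, seq_len(k), drop = FALSE]
  scale <- sqrt(pmax(ev[seq_len(k)], 0))
  coords <- sweep(coords, 2L, scale, "*")
  coords[, scale == 0] <- 0
  dimnames(coords) <- list(rownames(d), paste0("C", seq_len(k)))
  structure(list(coordinates = coords,
                 eigenvalues = ev[seq_len(k)],
                 n_negative_eigenvalues = sum(ev < -1e-9 * max(abs(ev), 1)),
                 distance_matrix_used = d),
            class = "mds_result")
}

#' @param x An `mds_result`.
#' @param ... Ignored.
#' @rdname classical_mds
#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("mds_result: %d points in %d dimensions\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("  eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

#' IBS distance matrix from a pair table
#'
#' The conventional IBS distance between two individuals is one minus
#' their allele-sharing fraction: `d_ij = 1 - DST_ij`, with a zero
#' diagonal. This is the matrix the MDS embedding operates on.
#'
#' @param pairs A [pair_table()] (or any data frame with `id1`, `id2`,
#'   `DST`).
#' @param ids Optional id ordering for the output; defaults to first
#'   appearance order in the pair table.
#' @return Symmetric distance matrix with dimnames `ids`.
#' @export
ibs_distance <- function(pairs, ids = NULL) {
  stopifnot(all(c("id1", "id2", "DST") %in% names(pairs)))
  if (is.null(ids)) ids <- unique(c(pairs$id1, pairs$id2))
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(pairs$id1, ids)
  j <- match(pairs$id2, ids)
  if (any(is.na(i)) || any(is.na(j))) stop("pair table contains ids absent from `ids`")
  d[cbind(i, j)] <- 1 - pairs$DST
  d[cbind(j, i)] <- 1 - pairs$DST
  d
}
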