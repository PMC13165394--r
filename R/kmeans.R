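# Deterministic k-means with NANI initialization: the first seed is the
# global medoid (row minimizing total Euclidean distance to all rows),
# the remaining seeds are chosen farthest-point style. No randomness
# anywhere; identical input gives bit-identical output.

#' NANI initialization indices
#'
#' Deterministic seed selection for k-means: the first seed is the global
#' medoid of the data (the row minimizing the sum of Euclidean distances
#' to all rows), and each subsequent seed is the row maximizing its
#' minimum distance to the seeds already chosen (farthest-point
#' spanning). All ties break to the lowest row index, so the selection is
#' fully reproducible.
#'
#' @param X Numeric matrix (rows = observations).
#' @param k Number of seeds, `1 <= k <= nrow(X)`.
#' @return Integer vector of `k` row indices.
#' @export
#' @examples
#' X <- matrix(c(0, 10, 11), ncol = 1)
#' nani_init(X, 2)  # medoid (10) first, then the farthest point (0)
nani_init <- function(X, k) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  n <- nrow(X)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n)
    stop("'k' must be in 1..", n)
  k <- as.integer(k)
  D <- as.matrix(stats::dist(X))
  idx <- integer(k)
  idx[1L] <- which.min(rowSums(D))
  if (k > 1L) {
    mind <- D[, idx[1L]]
    for (j in 2:k) {
      mind[idx[seq_len(j - 1L)]] <- -Inf
      idx[j] <- which.max(mind)
      mind <- pmin(mind, D[, idx[j]])
    }
  }
  idx
}

# squared Euclidean distances rows(X) x rows(C)
.sqdist <- function(X, C) {
  d2 <- matrix(rowSums(X^2), nrow(X), nrow(C)) -
    2 * X %*% t(C) +
    matrix(rowSums(C^2), nrow(X), nrow(C), byrow = TRUE)
  pmax(d2, 0)
}

# Lloyd iterations from given seed rows; deterministic
.lloyd <- function(X, init_idx, max_iter = 300L, tol = 1e-8) {
  n <- nrow(X)
  k <- length(init_idx)
  centroids <- X[init_idx, , drop = FALSE]
  labels <- integer(n)
  inertia <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- .sqdist(X, centroids)
    new_labels <- max.col(-d2, ties.method = "first")
    # refill any empty cluster with the point farthest from its centroid
    sizes <- tabulate(new_labels, nbins = k)
    while (any(sizes == 0L)) {
      j <- which(sizes == 0L)[1L]
      assigned <- d2[cbind(seq_len(n), new_labels)]
      movable <- which(sizes[new_labels] > 1L)
      far <- movable[which.max(assigned[movable])]
      new_labels[far] <- j
      sizes <- tabulate(new_labels, nbins = k)
    }
    centroids <- rowsum(X, new_labels) / sizes
    new_inertia <- sum(.sqdist(X, centroids)[cbind(seq_len(n), new_labels)])
    stable <- identical(new_labels, labels)
    converged <- stable ||
      (is.finite(inertia) &&
         abs(inertia - new_inertia) <= tol * max(inertia, .Machine$double.eps))
    labels <- new_labels
    inertia <- new_inertia
    if (converged || iter >= max_iter) break
  }
  # a final pass that only confirms the assignment is not counted
  list(k = k, centroids = centroids, labels = labels,
       inertia = inertia, init_indices = as.integer(init_idx),
       n_iter = if (stable && iter > 1L) iter - 1L else iter)
}

#' Deterministic k-means clustering
#'
#' Lloyd's algorithm started from [nani_init()] seeds. Convergence is
#' declared when the assignment stabilizes or the relative inertia change
#' drops below `tol` (default 1e-8), with a hard cap of `max_iter`
#' iterations. Should a cluster empty out mid-run, it is refilled with
#' the point currently farthest from its assigned centroid. The whole
#' procedure involves no randomness: the same data and `k` always give
#' the same model.
#'
#' @param X Numeric matrix of observations (typically retained-PC
#'   scores).
#' @param k Number of clusters, `k <= nrow(X)`.
#' @param max_iter Iteration cap (default 300).
#' @param tol Relative inertia convergence tolerance (default 1e-8).
#' @return Object of class `nani_kmeans`: list with `k`, `centroids`
#'   (k x d), `labels` (in 1..k), `inertia`, `init_indices`, `n_iter`.
#' @export
#' @examples
#' X <- matrix(c(0, 1, 10, 11), ncol = 1)
#' kmeans_fit(X, 2)$centroids
kmeans_fit <- function(X, k, max_iter = 300L, tol = 1e-8) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  if (anyNA(X)) stop("'X' contains missing values")
  fit <- .lloyd(X, nani_init(X, k), max_iter = max_iter, tol = tol)
  class(fit) <- "nani_kmeans"
  fit
}

#' @export
print.nani_kmeans <- function(x, ...) {
  cat(sprintf(
    "Deterministic k-means (NANI init): k = %d, %d points, inertia %.4g, %d iterations\n",
    x$k, length(x$labels), x$inertia, x$n_iter))
  cat("  cluster sizes:", tabulate(x$labels, nbins = x$k), "\n")
  invisible(x)
}
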