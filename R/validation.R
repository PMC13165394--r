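# Cluster validation protocol: mean silhouette, minimum pairwise
# inter-cluster Mahalanobis separation under the pooled within-cluster
# covariance, a k-scan with a fixed acceptance threshold, and k
# selection.

#' Mean silhouette coefficient
#'
#' Average over all points of `s_i = (b_i - a_i) / max(a_i, b_i)`, where
#' `a_i` is the mean Euclidean distance of point i to the other members
#' of its own cluster and `b_i` the smallest mean distance to any other
#' cluster. Points in singleton clusters contribute `s_i = 0`, as do
#' points with `a_i = b_i = 0`.
#'
#' @param X Numeric matrix of observations.
#' @param labels Cluster assignment (integer or factor), at least two
#'   distinct non-empty clusters.
#' @param D Optional precomputed distance matrix (`as.matrix(dist(X))`),
#'   to amortize repeated calls on the same data.
#' @return Mean silhouette, a scalar in \[-1, 1\].
#' @export
#' @examples
#' X <- matrix(c(0, 1, 10, 11), ncol = 1)
#' silhouette_mean(X, c(1, 1, 2, 2))  # 0.8997...
silhouette_mean <- function(X, labels, D = NULL) {
  labels <- as.integer(factor(labels))
  n <- length(labels)
  k <- max(labels)
  if (k < 2L) stop("at least 2 clusters are required")
  if (is.null(D)) D <- as.matrix(stats::dist(X))
  if (nrow(D) != n) stop("'labels' length does not match the data")
  sizes <- tabulate(labels, nbins = k)
  # A[i, g] = total distance from point i to the members of cluster g
  A <- D %*% outer(labels, seq_len(k), "==")
  a <- ifelse(sizes[labels] > 1L,
              A[cbind(seq_len(n), labels)] / (sizes[labels] - 1L), 0)
  Am <- sweep(A, 2, sizes, "/")
  Am[cbind(seq_len(n), labels)] <- Inf
  b <- apply(Am, 1, min)
  denom <- pmax(a, b)
  s <- ifelse(denom > 0, (b - a) / denom, 0)
  s[sizes[labels] == 1L] <- 0
  mean(s)
}

#' Minimum inter-cluster Mahalanobis separation
#'
#' Minimum over all cluster pairs of the Mahalanobis distance between
#' their centroids, `sqrt(t(c_g - c_h) %*% solve(S) %*% (c_g - c_h))`,
#' where `S` is the pooled within-cluster covariance (deviations from
#' each cluster centroid, divided by n - k over the clusters entering
#' the pool). Clusters of size 1 do not contribute to the pooling but
#' their centroids still enter the pairwise minimum. `S` is regularized
#' by `eps * trace(S) / d` on the diagonal, which perturbs the metric by
#' less than 1e-6 on well-conditioned data.
#'
#' @param X Numeric matrix of observations.
#' @param labels Cluster assignment with at least two clusters.
#' @param eps Relative ridge regularization (default 1e-8).
#' @return Minimum pairwise separation (scalar, >= 0).
#' @export
min_mahalanobis_separation <- function(X, labels, eps = 1e-8) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  labels <- as.integer(factor(labels))
  n <- nrow(X); d <- ncol(X)
  k <- max(labels)
  if (k < 2L) stop("at least 2 clusters are required")
  sizes <- tabulate(labels, nbins = k)
  centroids <- rowsum(X, labels) / sizes
  pooled <- which(sizes >= 2L)
  if (!length(pooled))
    stop("all clusters are singletons; pooled covariance undefined")
  dev <- X - centroids[labels, , drop = FALSE]
  dev <- dev[labels %in% pooled, , drop = FALSE]
  S <- crossprod(dev) / (nrow(dev) - length(pooled))
  S <- S + diag(eps * sum(diag(S)) / d, d)
  Sinv <- solve(S)
  best <- Inf
  for (g in seq_len(k - 1L)) for (h in (g + 1L):k) {
    delta <- centroids[g, ] - centroids[h, ]
    best <- min(best, sqrt(max(0, drop(delta %*% Sinv %*% delta))))
  }
  best
}

#' Scan cluster counts with the validation protocol
#'
#' For each candidate k, fits the deterministic NANI k-means
#' ([kmeans_fit()]), records the mean silhouette and the minimum
#' inter-cluster Mahalanobis separation, and flags the partition as
#' accepted when the separation exceeds the threshold (default 3.0,
#' roughly three standard deviations in multivariate space). The NANI
#' seed ordering and the distance matrix are computed once and shared
#' across the scan, so the whole table is deterministic and reasonably
#' cheap.
#'
#' @param X Numeric matrix of observations (typically retained-PC
#'   scores).
#' @param k_range Candidate cluster counts (default `2:18`); all must be
#'   `<= nrow(X) - 1`.
#' @param threshold Mahalanobis acceptance threshold (default 3.0).
#' @param silhouette_components Optional number of leading columns of `X`
#'   to use for the silhouette (e.g. 2 for a PC1-PC2 robustness check);
#'   default all columns.
#' @return Object of class `des_scan`: data frame with columns `k`,
#'   `silhouette`, `min_mahalanobis`, `accepted`, and attributes
#'   `threshold` and `models` (the fitted `nani_kmeans` objects, named by
#'   k).
#' @seealso [select_k()], [plot.des_scan()]
#' @export
scan_k <- function(X, k_range = 2:18, threshold = 3.0,
                   silhouette_components = NULL) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  n <- nrow(X)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L)) stop("'k_range' must start at 2")
  if (max(k_range) > n - 1L)
    stop("max(k_range) = ", max(k_range), " exceeds n - 1 = ", n - 1L)
  if (!is.finite(threshold) || threshold <= 0)
    stop("'threshold' must be positive")
  Xs <- if (is.null(silhouette_components)) X else
    X[, seq_len(silhouette_components), drop = FALSE]
  D <- as.matrix(stats::dist(Xs))
  seed_order <- nani_init(X, max(k_range))
  models <- vector("list", length(k_range))
  names(models) <- as.character(k_range)
  rows <- lapply(seq_along(k_range), function(i) {
    k <- k_range[i]
    fit <- tryCatch(.lloyd(X, seed_order[seq_len(k)]),
                    error = function(e)
                      stop(sprintf("k = %d: %s", k, conditionMessage(e)),
                           call. = FALSE))
    class(fit) <- "nani_kmeans"
    models[[i]] <<- fit
    data.frame(k = k,
               silhouette = silhouette_mean(Xs, fit$labels, D = D),
               min_mahalanobis =
                 min_mahalanobis_separation(X, fit$labels))
  })
  out <- do.call(rbind, rows)
  out$accepted <- out$min_mahalanobis > threshold
  attr(out, "threshold") <- threshold
  attr(out, "models") <- models
  class(out) <- c("des_scan", "data.frame")
  out
}

#' @export
print.des_scan <- function(x, ...) {
  cat(sprintf(
    "Cluster-count scan (k = %d..%d), Mahalanobis threshold %.2f, %d of %d accepted\n",
    min(x$k), max(x$k), attr(x, "threshold"), sum(x$accepted), nrow(x)))
  print(data.frame(k = x$k, silhouette = round(x$silhouette, 4),
                   min_mahalanobis = round(x$min_mahalanobis, 3),
                   accepted = x$accepted), row.names = FALSE, ...)
  invisible(x)
}

#' Plot a k-scan
#'
#' Two stacked panels: mean silhouette versus k, and minimum Mahalanobis
#' separation versus k with the acceptance threshold as a dashed line.
#'
#' @param x A `des_scan`.
#' @param ... Passed to the panel plots.
#' @export
plot.des_scan <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$k, x$silhouette, type = "b", pch = 19,
                 xlab = "number of clusters k",
                 ylab = "mean silhouette", ...)
  graphics::plot(x$k, x$min_mahalanobis, type = "b", pch = 19,
                 xlab = "number of clusters k",
                 ylab = "min Mahalanobis separation", ...)
  graphics::abline(h = attr(x, "threshold"), lty = 2)
  invisible(x)
}

#' Select the cluster count from a scan
#'
#' Policy `"max_silhouette_accepted"` (default) returns the accepted k
#' with the highest silhouette, breaking ties toward the smaller k.
#' Policy `"fixed"` validates a user-supplied k against the scan's
#' acceptance flags (a warning is raised when the chosen partition fails
#' the separation criterion).
#'
#' @param scan A `des_scan`.
#' @param policy Selection policy.
#' @param k Required for `policy = "fixed"`.
#' @return The selected k (integer).
#' @export
select_k <- function(scan, policy = c("max_silhouette_accepted", "fixed"),
                     k = NULL) {
  policy <- match.arg(policy)
  stopifnot(inherits(scan, "des_scan"))
  if (policy == "fixed") {
    if (is.null(k)) stop("'k' must be supplied for policy = 'fixed'")
    row <- which(scan$k == k)
    if (!length(row)) stop("k = ", k, " was not scanned")
    if (!scan$accepted[row])
      warning("k = ", k, " fails the Mahalanobis acceptance criterion")
    return(as.integer(k))
  }
  acc <- scan[scan$accepted, , drop = FALSE]
  if (!nrow(acc))
    stop("no scanned k satisfies the Mahalanobis separation threshold ",
         attr(scan, "threshold"),
         "; review the threshold or the feature space")
  best <- acc$k[order(-acc$silhouette, acc$k)][1L]
  as.integer(best)
}
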