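# Independent brute-force oracles, deliberately written as plain loops
# over the textbook definitions so they share no code path with the
# package implementations they check.

# mean silhouette by direct enumeration of the definition
brute_silhouette <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(sapply(setdiff(own, i), function(j)
      sqrt(sum((X[i, ] - X[j, ])^2))))
    b <- Inf
    for (g in setdiff(unique(labels), labels[i])) {
      members <- which(labels == g)
      b <- min(b, mean(sapply(members, function(j)
        sqrt(sum((X[i, ] - X[j, ])^2)))))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# min pairwise centroid Mahalanobis distance under pooled covariance,
# by explicit accumulation
brute_min_mahalanobis <- function(X, labels, eps = 1e-8) {
  X <- as.matrix(X)
  d <- ncol(X)
  groups <- sort(unique(labels))
  cents <- lapply(groups, function(g)
    colMeans(X[labels == g, , drop = FALSE]))
  S <- matrix(0, d, d)
  npool <- 0L; kpool <- 0L
  for (gi in seq_along(groups)) {
    rows <- which(labels == groups[gi])
    if (length(rows) < 2L) next
    kpool <- kpool + 1L; npool <- npool + length(rows)
    for (i in rows) {
      dev <- X[i, ] - cents[[gi]]
      S <- S + outer(dev, dev)
    }
  }
  S <- S / (npool - kpool)
  S <- S + diag(eps * sum(diag(S)) / d, d)
  best <- Inf
  for (gi in seq_along(groups)) for (hi in seq_along(groups)) {
    if (hi <= gi) next
    delta <- cents[[gi]] - cents[[hi]]
    best <- min(best, sqrt(drop(t(delta) %*% solve(S) %*% delta)))
  }
  best
}

# NANI seed selection by exhaustive search over the definition
brute_nani <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  dist_ij <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  totals <- sapply(seq_len(n), function(i)
    sum(sapply(seq_len(n), function(j) dist_ij(i, j))))
  idx <- which.min(totals)
  while (length(idx) < k) {
    cand <- setdiff(seq_len(n), idx)
    mind <- sapply(cand, function(i)
      min(sapply(idx, function(j) dist_ij(i, j))))
    idx <- c(idx, cand[which.max(mind)])
  }
  idx
}

# best 2-cluster partition of a tiny 1-D sample by exhaustion
brute_best_2partition_inertia <- function(x) {
  n <- length(x)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    grp <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    if (!any(grp) || all(grp)) next
    ss <- sum((x[grp] - mean(x[grp]))^2) +
      sum((x[!grp] - mean(x[!grp]))^2)
    best <- min(best, ss)
  }
  best
}

random_labeled_instance <- function(n, d, k) {
  X <- matrix(rnorm(n * d), n, d)
  labels <- sample.int(k, n, replace = TRUE)
  # guarantee every cluster non-empty
  labels[seq_len(k)] <- seq_len(k)
  list(X = X, labels = labels)
}
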