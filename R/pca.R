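# Correlation-based PCA of the descriptor space, with a frozen
# standardizer for out-of-sample projection and tools for interpreting
# and comparing loadings.

#' Fit a correlation PCA of the descriptor space
#'
#' Standardizes the 20 descriptors to zero mean and unit sample standard
#' deviation (ddof = 1) and eigendecomposes the resulting correlation
#' matrix. The training means and standard deviations are frozen inside
#' the model, so new systems are always projected in the training frame
#' (see [predict.des_pca()]).
#'
#' Component signs are fixed deterministically: each loading vector is
#' flipped so that its largest-magnitude entry is positive (first feature
#' index on ties). Exactly degenerate eigenvalues are ordered by the
#' magnitude of their first-feature loading. By default the first five
#' components are retained, matching the interpretation of the descriptor
#' space as five thermodynamic axes; alternatively `cumvar_target`
#' retains the smallest number of components whose cumulative explained
#' variance reaches the target.
#'
#' @param x A `des_table`, or a data frame / matrix whose columns are the
#'   feature set.
#' @param n_retained Number of components to retain (default 5).
#' @param cumvar_target If non-`NULL`, overrides `n_retained` with the
#'   smallest k reaching this cumulative explained-variance fraction.
#' @return Object of class `des_pca` with elements `loadings` (p x p,
#'   orthonormal columns), `explained_variance_ratio`, `n_retained`,
#'   `center`, `scale`, `feature_order` and in-sample `scores`
#'   (n x n_retained).
#' @export
#' @examples
#' sim <- simulate_des_systems(latent_spec(200, seed = 7))
#' pca <- des_pca(sim$table)
#' cumulative_variance(pca, 5)
des_pca <- function(x, n_retained = 5, cumvar_target = NULL) {
  m <- if (is.matrix(x)) x else
    if (all(des_features() %in% names(x))) des_feature_matrix(x) else
      as.matrix(x)
  storage.mode(m) <- "double"
  if (is.null(colnames(m)))
    colnames(m) <- paste0("V", seq_len(ncol(m)))
  n <- nrow(m); p <- ncol(m)
  if (n < 2) stop("at least 2 rows are required")
  center <- colMeans(m)
  scl <- apply(m, 2, stats::sd)
  const <- which(scl < .Machine$double.eps^0.5 * pmax(abs(center), 1))
  if (length(const))
    stop("constant feature column: ", colnames(m)[const[1L]])
  z <- sweep(sweep(m, 2, center), 2, scl, "/")
  cc <- crossprod(z) / (n - 1)
  eig <- eigen(cc, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  # order exact ties by first-feature loading magnitude (largest first)
  ord <- order(-vals, -abs(vecs[1L, ]))
  vals <- vals[ord]; vecs <- vecs[, ord, drop = FALSE]
  # sign convention: largest-|loading| entry positive, first index on ties
  for (j in seq_len(p)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  ratio <- vals / sum(vals)
  if (!is.null(cumvar_target)) {
    n_retained <- which(cumsum(ratio) >= cumvar_target - 1e-12)[1L]
    if (is.na(n_retained)) n_retained <- p
  }
  n_retained <- as.integer(n_retained)
  if (n_retained < 1 || n_retained > p)
    stop("'n_retained' must be in 1..", p)
  if (n < n_retained + 1)
    stop("need at least n_retained + 1 rows")
  dimnames(vecs) <- list(colnames(m), paste0("PC", seq_len(p)))
  scores <- z %*% vecs[, seq_len(n_retained), drop = FALSE]
  rownames(scores) <- rownames(m)
  structure(list(loadings = vecs,
                 explained_variance_ratio = ratio,
                 n_retained = n_retained,
                 center = center, scale = scl,
                 feature_order = colnames(m),
                 scores = scores),
            class = "des_pca")
}

#' @export
print.des_pca <- function(x, ...) {
  p <- length(x$explained_variance_ratio)
  cat(sprintf("Correlation PCA: %d features, %d retained components\n",
              p, x$n_retained))
  evr <- x$explained_variance_ratio[seq_len(x$n_retained)]
  cat("  explained variance: ",
      paste(sprintf("PC%d %.1f%%", seq_along(evr), 100 * evr),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  cumulative (retained): %.1f%%\n",
              100 * sum(evr)))
  invisible(x)
}

#' Cumulative explained variance
#'
#' Partial sum of the explained-variance ratios of the first `k`
#' components; non-decreasing in `k` and equal to 1 at `k = p`.
#'
#' @param model A `des_pca`.
#' @param k Number of leading components, `1 <= k <= p`.
#' @return Scalar in \[0, 1\].
#' @export
cumulative_variance <- function(model, k) {
  stopifnot(inherits(model, "des_pca"))
  p <- length(model$explained_variance_ratio)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > p)
    stop("'k' must be in 1..", p)
  sum(model$explained_variance_ratio[seq_len(k)])
}

#' Project systems onto a fitted PCA model
#'
#' Standardizes new rows with the frozen training means and standard
#' deviations and multiplies by the retained loading vectors. Training
#' rows reproduce their in-sample scores exactly; the model is never
#' refit.
#'
#' @param object A `des_pca`.
#' @param newdata A `des_table`, data frame or matrix carrying all
#'   training features.
#' @param n_components Number of leading components to return (default
#'   `object$n_retained`).
#' @param ... Unused.
#' @return Score matrix (rows x n_components).
#' @export
predict.des_pca <- function(object, newdata,
                            n_components = object$n_retained, ...) {
  feats <- object$feature_order
  m <- if (is.matrix(newdata)) newdata else {
    missing <- setdiff(feats, names(newdata))
    if (length(missing))
      stop("missing feature columns: ", paste(missing, collapse = ", "))
    mm <- as.matrix(as.data.frame(newdata)[, feats])
    if ("system_id" %in% names(newdata))
      rownames(mm) <- as.character(newdata$system_id)
    mm
  }
  if (ncol(m) != length(feats))
    stop("'newdata' must carry ", length(feats), " feature columns")
  if (!is.null(colnames(m)) && !identical(colnames(m), feats))
    m <- m[, feats, drop = FALSE]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing values in 'newdata'")
  z <- sweep(sweep(m, 2, object$center), 2, object$scale, "/")
  z %*% object$loadings[, seq_len(n_components), drop = FALSE]
}

#' Classify a loading magnitude
#'
#' Bins loading values by absolute magnitude into the interpretation
#' classes used when reading the descriptor axes: `strong` for
#' `|value| >= 0.45`, `moderate` for `0.31 <= |value| < 0.45`, else
#' `negligible`.
#'
#' @param value Numeric vector of loadings, each with `|value| <= 1`.
#' @return Factor with levels `negligible`, `moderate`, `strong`.
#' @export
#' @examples
#' classify_loading(c(0.38, 0.47, -0.30))
classify_loading <- function(value) {
  if (any(!is.finite(value)) || any(abs(value) > 1 + 1e-12))
    stop("loadings must be finite with |value| <= 1")
  a <- abs(value)
  factor(ifelse(a >= 0.45, "strong",
                ifelse(a >= 0.31, "moderate", "negligible")),
         levels = c("negligible", "moderate", "strong"))
}

#' Loading persistence between two PCA fits
#'
#' Measures how well the leading loading vectors of one fit are preserved
#' in another (e.g. full vs dry vs wet subsets, or split halves). The
#' first `k` components of each model are matched one-to-one greedily by
#' absolute cosine similarity (largest first), and the matched
#' similarities are reported per component of `model_a`.
#'
#' @param model_a,model_b Two `des_pca` fits on the same feature set.
#' @param k Number of leading components to match (default: the smaller
#'   `n_retained`).
#' @return Numeric vector of length `k`, absolute cosine similarities in
#'   \[0, 1\], named by `model_a` components.
#' @export
loading_persistence <- function(model_a, model_b,
                                k = min(model_a$n_retained,
                                        model_b$n_retained)) {
  stopifnot(inherits(model_a, "des_pca"), inherits(model_b, "des_pca"))
  if (!identical(model_a$feature_order, model_b$feature_order))
    stop("models were fit on different feature sets")
  A <- model_a$loadings[, seq_len(k), drop = FALSE]
  B <- model_b$loadings[, seq_len(k), drop = FALSE]
  S <- abs(crossprod(A, B))          # loading columns are unit length
  out <- numeric(k)
  rows <- seq_len(k); cols <- seq_len(k)
  for (step in seq_len(k)) {
    idx <- which(S == max(S[rows, cols, drop = FALSE])[1L], arr.ind = TRUE)
    idx <- idx[idx[, 1] %in% rows & idx[, 2] %in% cols, , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    out[i] <- S[i, j]
    rows <- setdiff(rows, i); cols <- setdiff(cols, j)
  }
  names(out) <- colnames(A)
  out
}

#' Serialize / load a PCA model as JSON
#'
#' Writes the frozen standardizer, full loading matrix,
#' explained-variance spectrum, retained-component count and feature
#' order at full precision, so a saved model projects new systems
#' identically after reload.
#'
#' @param model A `des_pca`.
#' @param path File path.
#' @return `read_des_pca` returns the restored `des_pca` (without
#'   in-sample scores); `write_des_pca` returns `path` invisibly.
#' @export
write_des_pca <- function(model, path) {
  stopifnot(inherits(model, "des_pca"))
  obj <- list(type = "des_pca", sign_convention = "max-abs-positive",
              feature_order = model$feature_order,
              center = unname(model$center), scale = unname(model$scale),
              loadings = unname(model$loadings),
              explained_variance_ratio = model$explained_variance_ratio,
              n_retained = model$n_retained)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_des_pca
#' @export
read_des_pca <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "des_pca")) stop("not a serialized des_pca")
  L <- as.matrix(obj$loadings)
  dimnames(L) <- list(obj$feature_order,
                      paste0("PC", seq_len(ncol(L))))
  structure(list(loadings = L,
                 explained_variance_ratio =
                   as.numeric(obj$explained_variance_ratio),
                 n_retained = as.integer(obj$n_retained),
                 center = stats::setNames(as.numeric(obj$center),
                                          obj$feature_order),
                 scale = stats::setNames(as.numeric(obj$scale),
                                         obj$feature_order),
                 feature_order = obj$feature_order,
                 scores = NULL),
            class = "des_pca")
}
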