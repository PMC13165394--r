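# The fitted taxonomy model: correlation PCA of the descriptor table,
# deterministic k-means in the retained-PC space, validation scan,
# mechanistic regime names for the clusters, and frozen-model
# classification of new systems.

.regime_levels <- c("interaction_driven", "destabilization_driven",
                    "high_barrier", "weak_interaction", "failure",
                    "intermediate")

#' Fit a solvation-regime taxonomy
#'
#' The main fitting function of the package. Standardizes the 20
#' descriptors and fits a correlation PCA ([des_pca()]), runs the
#' cluster-count validation scan in the retained-PC space ([scan_k()]),
#' selects k ([select_k()]), fits the deterministic NANI k-means
#' ([kmeans_fit()]) and names the resulting clusters mechanistically
#' ([label_regimes()]). The fitted object is frozen: new systems are
#' classified by projection and nearest centroid without refitting
#' anything (see [predict.des_taxonomy()]).
#'
#' @param table A `des_table` (see [as_des_table()],
#'   [simulate_des_systems()]).
#' @param n_retained Retained principal components (default 5).
#' @param cumvar_target Optional cumulative-variance retention rule
#'   passed to [des_pca()].
#' @param k Fixed cluster count; when `NULL` (default) k is chosen as
#'   the accepted scan entry with the highest silhouette.
#' @param k_range Candidate cluster counts for the scan (default
#'   `2:18`).
#' @param threshold Mahalanobis acceptance threshold (default 3.0).
#' @param z_high,z_low Standardized-centroid cutoffs for "high" / "low"
#'   coordinates in the regime rules (defaults +0.5 / -0.5).
#' @return Object of class `des_taxonomy` with elements `pca`
#'   (`des_pca`), `scan` (`des_scan`), `clusters` (`nani_kmeans`),
#'   `regimes` (named character vector, one regime per cluster), `k`,
#'   `scores` (training scores), `system_id`, `is_wet` and `hulls`
#'   (training PC1-PC2 convex hulls per cluster).
#' @export
#' @examples
#' sim <- simulate_des_systems(latent_spec(300, seed = 11))
#' fit <- des_taxonomy(sim$table, k_range = 2:8)
#' summary(fit)
des_taxonomy <- function(table, n_retained = 5, cumvar_target = NULL,
                         k = NULL, k_range = 2:18, threshold = 3.0,
                         z_high = 0.5, z_low = -0.5) {
  table <- as_des_table(table)
  pca <- des_pca(table, n_retained = n_retained,
                 cumvar_target = cumvar_target)
  scores <- pca$scores
  scan <- scan_k(scores, k_range = k_range, threshold = threshold)
  k_sel <- if (is.null(k)) select_k(scan) else
    select_k(scan, policy = "fixed", k = k)
  clusters <- kmeans_fit(scores, k_sel)
  regimes <- label_regimes(clusters$centroids, z_high = z_high,
                           z_low = z_low)
  hulls <- lapply(seq_len(k_sel), function(j) {
    pts <- scores[clusters$labels == j, 1:2, drop = FALSE]
    pts[grDevices::chull(pts), , drop = FALSE]
  })
  structure(list(pca = pca, scan = scan, clusters = clusters,
                 regimes = regimes, k = k_sel, scores = scores,
                 system_id = table$system_id, is_wet = table$is_wet,
                 hulls = hulls, z_high = z_high, z_low = z_low),
            class = "des_taxonomy")
}

#' Name clusters by their position in PC space
#'
#' Assigns a mechanistic regime to every cluster from the standardized
#' coordinates of its centroid (z-scored per component across clusters,
#' so "high" and "low" are scale-free: high means z >= `z_high`, low
#' means z <= `z_low`). The rules, applied in order with ties broken by
#' lowest cluster index:
#'
#' * `interaction_driven` -- the cluster with the top PC1 coordinate
#'   (strongest solvation driving force), provided it stands out
#'   (z >= `z_high`);
#' * `failure` -- the cluster with the lowest PC1 coordinate
#'   (z <= `z_low`), combined with high PC3 (electrostatic mismatch) and
#'   low PC4 (weak hydrogen-bond network cohesion) whenever those axes
#'   exist;
#' * `destabilization_driven` -- among the remaining clusters, the one
#'   with the bottom PC2 coordinate (z <= `z_low`: reduced API
#'   stability);
#' * `high_barrier` -- remaining clusters with high PC1 and high PC2
#'   (favorable interactions defeated by API stability);
#' * `weak_interaction` -- remaining clusters with low PC1 and mid-to-
#'   high PC2;
#' * `intermediate` -- everything else (including all clusters when the
#'   centroids are degenerate).
#'
#' The naming depends only on centroid geometry, so it is invariant to
#' permutations of the cluster indices.
#'
#' @param centroids k x d matrix of cluster centroids in retained-PC
#'   space (d >= 2).
#' @param z_high,z_low Cutoffs on the standardized coordinates.
#' @return Named character vector of length k (names `"1"`.. `"k"`).
#' @export
label_regimes <- function(centroids, z_high = 0.5, z_low = -0.5) {
  centroids <- as.matrix(centroids)
  k <- nrow(centroids); d <- ncol(centroids)
  if (d < 2) stop("regime naming requires at least 2 PC dimensions")
  z <- apply(centroids, 2, function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-12) rep(0, length(v)) else
      (v - mean(v)) / s
  })
  z <- matrix(z, nrow = k)
  regime <- rep("intermediate", k)
  taken <- rep(FALSE, k)
  top1 <- which.max(z[, 1])
  if (z[top1, 1] >= z_high) {
    regime[top1] <- "interaction_driven"; taken[top1] <- TRUE
  }
  low1 <- which.min(z[, 1])
  if (!taken[low1] && z[low1, 1] <= z_low &&
      (d < 3 || z[low1, 3] >= z_high) &&
      (d < 4 || z[low1, 4] <= z_low)) {
    regime[low1] <- "failure"; taken[low1] <- TRUE
  }
  open <- which(!taken)
  if (length(open)) {
    bot2 <- open[which.min(z[open, 2])]
    if (z[bot2, 2] <= z_low) {
      regime[bot2] <- "destabilization_driven"; taken[bot2] <- TRUE
    }
  }
  for (j in which(!taken)) {
    if (z[j, 1] >= z_high && z[j, 2] >= z_high) {
      regime[j] <- "high_barrier"
    } else if (z[j, 1] <= z_low && z[j, 2] > z_low) {
      regime[j] <- "weak_interaction"
    }
  }
  stats::setNames(regime, as.character(seq_len(k)))
}

#' Classify new systems with a frozen taxonomy
#'
#' Projects new descriptor rows onto the fitted PCA space with the
#' frozen training standardizer, assigns each to the nearest cluster
#' centroid (Euclidean, retained-PC space) and attaches the regime name.
#' Nothing is refit; training rows reproduce their training cluster
#' exactly. Because the published score maps delimit clusters with
#' convex hulls, membership of each point in its assigned cluster's
#' training PC1-PC2 hull is also reported as a secondary indicator.
#'
#' @param object A `des_taxonomy`.
#' @param newdata A `des_table` (or data frame with the 20 features).
#' @param ... Unused.
#' @return Data frame with `system_id`, the retained PC scores,
#'   `cluster`, `regime`, `distance_to_centroid` and `in_hull`.
#' @export
predict.des_taxonomy <- function(object, newdata, ...) {
  scores <- predict(object$pca, newdata)
  d2 <- .sqdist(scores, object$clusters$centroids)
  cl <- max.col(-d2, ties.method = "first")
  in_hull <- vapply(seq_len(nrow(scores)), function(i) {
    .point_in_convex_polygon(scores[i, 1:2], object$hulls[[cl[i]]])
  }, logical(1))
  out <- data.frame(
    system_id = if (!is.null(rownames(scores))) rownames(scores) else
      if (is.data.frame(newdata) && "system_id" %in% names(newdata))
        as.character(newdata$system_id) else
          sprintf("row%d", seq_len(nrow(scores))),
    cluster = cl,
    regime = unname(object$regimes[as.character(cl)]),
    distance_to_centroid = sqrt(d2[cbind(seq_len(nrow(scores)), cl)]),
    in_hull = in_hull,
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(scores, row.names = FALSE))
}

# convex polygon membership (vertices in hull order); boundary counts as
# inside, degenerate hulls (< 3 vertices) return FALSE
.point_in_convex_polygon <- function(pt, poly) {
  m <- nrow(poly)
  if (is.null(m) || m < 3) return(FALSE)
  sgn <- 0
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    cr <- (poly[j, 1] - poly[i, 1]) * (pt[2] - poly[i, 2]) -
      (poly[j, 2] - poly[i, 2]) * (pt[1] - poly[i, 1])
    if (abs(cr) < 1e-12) next
    s <- sign(cr)
    if (sgn == 0) sgn <- s else if (s != sgn) return(FALSE)
  }
  TRUE
}

#' Hydration occupancy of the regimes
#'
#' Cross-tabulates regime assignments against the dry/wet condition and
#' reports counts together with per-condition fractions (each condition
#' column sums to 1). This is the summary behind statements like "the
#' failure regime is largely unpopulated by wet systems".
#'
#' @param regime Character vector of regime assignments (e.g. the
#'   `regime` column of [predict.des_taxonomy()] output, or
#'   `fitted regimes[labels]`).
#' @param is_wet Logical vector of the same length.
#' @return List with `counts` and `fractions` (regimes x dry/wet
#'   matrices).
#' @export
hydration_occupancy <- function(regime, is_wet) {
  if (!length(regime)) stop("empty assignment vector")
  if (length(regime) != length(is_wet))
    stop("'regime' and 'is_wet' lengths differ")
  regime <- factor(regime, levels = intersect(.regime_levels,
                                              unique(regime)))
  condition <- factor(ifelse(is_wet, "wet", "dry"),
                      levels = c("dry", "wet"))
  counts <- table(regime = regime, condition = condition)
  fractions <- sweep(counts, 2, pmax(colSums(counts), 1L), "/")
  list(counts = unclass(counts), fractions = unclass(fractions))
}

#' @export
print.des_taxonomy <- function(x, ...) {
  cat(sprintf(
    "Solvation-regime taxonomy: %d systems, %d retained PCs, k = %d clusters\n",
    length(x$system_id), x$pca$n_retained, x$k))
  sizes <- tabulate(x$clusters$labels, nbins = x$k)
  for (j in seq_len(x$k))
    cat(sprintf("  C%d: %4d systems  %s\n", j, sizes[j],
                x$regimes[as.character(j)]))
  invisible(x)
}

#' @export
summary.des_taxonomy <- function(object, ...) {
  evr <- object$pca$explained_variance_ratio
  structure(list(n = length(object$system_id),
                 n_retained = object$pca$n_retained,
                 explained = evr[seq_len(object$pca$n_retained)],
                 cumvar = sum(evr[seq_len(object$pca$n_retained)]),
                 k = object$k,
                 scan = object$scan,
                 sizes = tabulate(object$clusters$labels,
                                  nbins = object$k),
                 regimes = object$regimes,
                 silhouette =
                   object$scan$silhouette[object$scan$k == object$k],
                 min_mahalanobis =
                   object$scan$min_mahalanobis[object$scan$k == object$k]),
            class = "summary.des_taxonomy")
}

#' @export
print.summary.des_taxonomy <- function(x, ...) {
  cat(sprintf("Solvation-regime taxonomy of %d API-DES systems\n", x$n))
  cat(sprintf("  PCA: %d retained components, %s (cumulative %.1f%%)\n",
              x$n_retained,
              paste(sprintf("%.1f%%", 100 * x$explained),
                    collapse = " + "),
              100 * x$cumvar))
  cat(sprintf(
    "  clustering: k = %d (silhouette %.3f, min Mahalanobis %.2f)\n",
    x$k,
    if (length(x$silhouette)) x$silhouette else NA_real_,
    if (length(x$min_mahalanobis)) x$min_mahalanobis else NA_real_))
  for (j in seq_len(x$k))
    cat(sprintf("  C%d (%d systems): %s\n", j, x$sizes[j],
                x$regimes[as.character(j)]))
  invisible(x)
}

#' Score plot of a fitted taxonomy
#'
#' PC1-PC2 scatter of the training systems colored by cluster, with the
#' cluster convex hulls outlined. Optionally a numeric response (e.g.
#' `logx_sle`) drives a grey-to-red color ramp instead.
#'
#' @param x A `des_taxonomy`.
#' @param color_by Optional numeric vector (length = training systems).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.des_taxonomy <- function(x, color_by = NULL, ...) {
  sc <- x$scores[, 1:2, drop = FALSE]
  cols <- if (is.null(color_by)) {
    grDevices::hcl.colors(x$k, "Dark 3")[x$clusters$labels]
  } else {
    ramp <- grDevices::colorRamp(c("grey70", "firebrick"))
    v <- (color_by - min(color_by)) / max(diff(range(color_by)), 1e-12)
    grDevices::rgb(ramp(v), maxColorValue = 255)
  }
  graphics::plot(sc, col = cols, pch = 19, cex = 0.6,
                 xlab = "PC1 (solvation driving force)",
                 ylab = "PC2 (API stability / non-ideality)", ...)
  for (j in seq_len(x$k)) {
    h <- x$hulls[[j]]
    if (nrow(h) >= 3) graphics::polygon(h, border = "grey30", lty = 2)
    graphics::text(x$clusters$centroids[j, 1],
                   x$clusters$centroids[j, 2],
                   labels = paste0("C", j), font = 2)
  }
  invisible(x)
}
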