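# Latent-factor synthetic data generator. Emulates the statistical
# structure of a compiled API-DES descriptor collection: 20 correlated
# descriptors driven by 5 latent thermodynamic axes, planted cluster
# regimes, a solubility response tied to the first axis, and a coupling
# knob that concentrates variance onto that axis the way hydration
# compresses the descriptor space of wet systems.

# Evaluate f() under a fixed RNG seed without touching global RNG state.
with_local_seed <- function(seed, f) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  f()
}

#' Default latent loading pattern
#'
#' The 20 x 5 loading matrix used by the synthetic generator. The sign
#' structure mirrors the physical interpretation of the five descriptor
#' axes: axis 1 (solvation driving force) loads positively on
#' `solute_Evdw`, `rel_mu` and `logx_sle` and negatively on
#' `solute_Emisfit`; axis 2 (API thermodynamic stability / non-ideality)
#' on `mu_sat`, `solute_gamma`, `mu_water`, `solute_Etot`, `rel_Etot`;
#' axis 3 (solvent polarity--dispersion balance) positively on `solv_Evdw`
#' and `rel_Emisfit`, negatively on `solv_Emisfit`, `solute_Ehbond`,
#' `rel_Evdw`; axis 4 (hydrogen-bond network strength) on `solv_Etot`,
#' `solv_Ehbond`, `solv_mu`, negatively on `rel_Ehbond`; axis 5 (hydration
#' competition) positively on `rel_mu_water`, negatively on
#' `solute_Ehbond` and `mu_water`. Rows are normalized to unit length so
#' every feature carries the same signal amplitude.
#'
#' @return 20 x 5 numeric matrix with feature row names.
#' @export
default_loadings <- function() {
  feats <- des_features()
  L <- matrix(0, nrow = length(feats), ncol = 5,
              dimnames = list(feats, paste0("F", 1:5)))
  set_l <- function(feat, factor, value) L[feat, factor] <<- value
  # axis 1: solvation driving force
  set_l("solute_Evdw", 1, 0.38); set_l("rel_mu", 1, 0.37)
  set_l("logx_sle", 1, 0.27);    set_l("solute_Emisfit", 1, -0.34)
  # axis 2: API stability / non-ideality
  set_l("mu_sat", 2, 0.40); set_l("solute_gamma", 2, 0.35)
  set_l("mu_water", 2, 0.32); set_l("solute_Etot", 2, 0.31)
  set_l("rel_Etot", 2, 0.34); set_l("mu_self", 2, 0.30)
  # axis 3: polarity-dispersion balance of the solvent
  set_l("solv_Evdw", 3, 0.47); set_l("solv_Emisfit", 3, -0.38)
  set_l("solute_Ehbond", 3, -0.32); set_l("rel_Evdw", 3, -0.36)
  set_l("rel_Emisfit", 3, 0.33)
  # axis 4: hydrogen-bond network strength
  set_l("solv_Etot", 4, 0.55); set_l("solv_Ehbond", 4, 0.47)
  set_l("solv_mu", 4, 0.34); set_l("rel_Ehbond", 4, -0.33)
  # axis 5: hydration competition
  set_l("rel_mu_water", 5, 0.71); set_l("solute_Ehbond", 5, -0.36)
  set_l("mu_water", 5, -0.34)
  # rows scaled to a common signal amplitude; 1.75 puts the cumulative
  # variance captured by the five axes a little above 90% under the
  # default noise level, matching the descriptor collections this
  # generator emulates
  1.75 * L / sqrt(rowSums(L^2))
}

# k cluster means on distinct factor axes at graded radii (regimes differ
# in how extreme they are), scaled so the minimum pairwise Euclidean
# distance in factor space is exactly `separation`
default_cluster_means <- function(k, n_factors, separation) {
  if (k > n_factors)
    stop("default cluster means require k <= n_factors; ",
         "supply 'cluster_means' explicitly")
  radii <- if (k > 1) seq(1, 2, length.out = k) else 1
  m <- matrix(0, k, n_factors)
  m[cbind(seq_len(k), seq_len(k))] <- radii
  if (k > 1) {
    min_pair <- sqrt(radii[1]^2 + radii[2]^2)
    m <- m * (separation / min_pair)
  }
  m
}

#' Specification of a synthetic descriptor dataset
#'
#' Bundles and validates the parameters of the latent-factor generator:
#' the number of systems, the loading matrix tying the 20 descriptors to
#' `n_factors` latent axes, planted cluster means and weights in factor
#' space, the noise scale, the dry/wet coupling knob and the wet fraction.
#'
#' Within a cluster, factor scores are Gaussian around the cluster mean
#' with standard deviation `noise_sd / sqrt(2)` per axis, and independent
#' feature noise with standard deviation `noise_sd` is added on top. The
#' latent scatter is set below the feature noise so that the total
#' within-regime spread observed through the loadings -- latent scatter
#' plus propagated feature noise -- is close to `noise_sd`, which makes
#' `separation` (the minimum pairwise distance between default cluster
#' means) a distance in end-to-end sigma units. The `coupling` knob in
#' \[0, 1\] mixes factors 2..n toward the first (solvation) axis,
#' `z_j <- (1 - coupling) * z_j + coupling * z_1`: at 0 the axes are
#' independent (dry-like), at 1 every descriptor block is driven by the
#' single solvation axis (fully coupled, wet-like), which lowers the
#' effective dimensionality of the generated table.
#'
#' @param n_systems Number of systems to generate.
#' @param n_factors Number of latent axes (default 5).
#' @param loading_matrix 20 x `n_factors` matrix; default
#'   [default_loadings()].
#' @param k Number of planted regimes (default 5).
#' @param cluster_means `k` x `n_factors` matrix; default places the means
#'   on distinct factor axes at minimum pairwise distance `separation`.
#' @param cluster_weights Probability simplex of length `k` (default
#'   uniform).
#' @param noise_sd Positive noise scale (factor scatter and feature
#'   noise); default 0.5.
#' @param separation Minimum pairwise distance between default cluster
#'   means, in factor space; default `8 * noise_sd`. Because the feature
#'   noise adds within-regime spread on top of the latent scatter once
#'   the table is standardized and projected, planting regimes eight
#'   noise units apart keeps them about six effective standard
#'   deviations apart end to end (clearly separated regimes).
#' @param coupling Dry/wet coupling knob in \[0, 1\]; default 0.
#' @param wet_fraction Fraction of systems given a water component
#'   (`x_w > 0`); default 0.
#' @param seed Integer seed; all randomness in the generator flows from
#'   it.
#' @return Object of class `latent_spec`.
#' @seealso [simulate_des_systems()]
#' @export
latent_spec <- function(n_systems, n_factors = 5,
                        loading_matrix = default_loadings(),
                        k = 5, cluster_means = NULL, cluster_weights = NULL,
                        noise_sd = 0.5, separation = 8 * noise_sd,
                        coupling = 0, wet_fraction = 0, seed = 1) {
  if (!is.numeric(n_systems) || n_systems < 1) stop("'n_systems' must be >= 1")
  if (!is.finite(noise_sd) || noise_sd <= 0) stop("'noise_sd' must be > 0")
  if (coupling < 0 || coupling > 1) stop("'coupling' must be in [0, 1]")
  if (wet_fraction < 0 || wet_fraction > 1)
    stop("'wet_fraction' must be in [0, 1]")
  loading_matrix <- as.matrix(loading_matrix)
  if (nrow(loading_matrix) != length(des_features()) ||
      ncol(loading_matrix) != n_factors)
    stop("'loading_matrix' must be ", length(des_features()), " x ",
         n_factors)
  if (any(colSums(abs(loading_matrix)) == 0))
    stop("'loading_matrix' has an all-zero column")
  if (is.null(cluster_means))
    cluster_means <- default_cluster_means(k, n_factors, separation)
  cluster_means <- as.matrix(cluster_means)
  k <- nrow(cluster_means)
  if (k < 1) stop("at least one cluster is required")
  if (ncol(cluster_means) != n_factors)
    stop("'cluster_means' must have ", n_factors, " columns")
  if (is.null(cluster_weights)) cluster_weights <- rep(1 / k, k)
  if (length(cluster_weights) != k || any(cluster_weights < 0) ||
      abs(sum(cluster_weights) - 1) > 1e-9)
    stop("'cluster_weights' must be a length-", k, " probability simplex")
  structure(list(n_systems = as.integer(n_systems),
                 n_factors = as.integer(n_factors),
                 loading_matrix = loading_matrix,
                 k = as.integer(k),
                 cluster_means = cluster_means,
                 cluster_weights = cluster_weights,
                 noise_sd = noise_sd, coupling = coupling,
                 wet_fraction = wet_fraction, seed = as.integer(seed)),
            class = "latent_spec")
}

#' Generate a synthetic descriptor dataset
#'
#' Draws a dataset from a [latent_spec()]: a cluster id per system, factor
#' scores Gaussian around the cluster mean (scaled by the coupling
#' transform), features as `loading_matrix %*% scores` plus independent
#' Gaussian noise, followed by back-filling of the dependent columns
#' (`solv_Etot`, `solv_Emisfit`, `solv_Ehbond`, `solv_Evdw`, `solv_mu`,
#' `mu_water`) from the relative-descriptor identities so that every
#' generated row satisfies them exactly. System metadata (API/HBA/HBD
#' identifiers, molar ratio, `x_w`) is drawn from a small realistic
#' vocabulary; `wet_fraction` of the systems receive a water mole fraction
#' on the 0.1..0.9 grid.
#'
#' @param spec A `latent_spec`.
#' @return Object of class `des_sim`: list with `table` (a `des_table`),
#'   `true_labels`, `true_scores` (n x n_factors matrix of realized
#'   factor values) and `spec`.
#' @export
#' @examples
#' sim <- simulate_des_systems(latent_spec(100, seed = 42))
#' table(sim$true_labels)
simulate_des_systems <- function(spec) {
  stopifnot(inherits(spec, "latent_spec"))
  with_local_seed(spec$seed, function() {
    n <- spec$n_systems
    p <- spec$n_factors
    feats <- des_features()
    labels <- sample.int(spec$k, n, replace = TRUE,
                         prob = spec$cluster_weights)
    z <- spec$cluster_means[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * p, sd = spec$noise_sd / sqrt(2)), n, p)
    # coupling: mix axes 2..p toward the solvation axis, so descriptors
    # driven by different thermodynamic mechanisms become correlated the
    # way hydration couples them; at coupling = 1 a single axis remains
    if (spec$coupling > 0 && p > 1) {
      z[, -1] <- (1 - spec$coupling) * z[, -1, drop = FALSE] +
        spec$coupling * z[, 1]
    }
    f <- z %*% t(spec$loading_matrix) +
      matrix(stats::rnorm(n * length(feats), sd = spec$noise_sd),
             n, length(feats))
    colnames(f) <- feats
    tab <- as.data.frame(f)
    # enforce the relative-descriptor identities exactly by back-filling
    # the solvent block and the aqueous chemical potential
    tab$solv_mu  <- tab$mu_sat - tab$rel_mu
    tab$mu_water <- tab$mu_sat - tab$rel_mu_water
    for (pn in c("Etot", "Emisfit", "Ehbond", "Evdw"))
      tab[[paste0("solv_", pn)]] <-
        tab[[paste0("solute_", pn)]] - tab[[paste0("rel_", pn)]]
    tab$system_id <- sprintf("S%05d", seq_len(n))
    tab$api_id <- sample(sprintf("API%02d", 1:21), n, replace = TRUE)
    tab$hba_id <- sample(c("ChCl", "Men", "Bet"), n, replace = TRUE)
    tab$hbd_id <- sample(c("TRG", "TEG", "DEG", "ETG", "P2D", "B3D"),
                         n, replace = TRUE)
    tab$ratio <- sample(c("1:2", "1:3", "1:4"), n, replace = TRUE)
    tab$temperature <- 298.15
    n_wet <- round(spec$wet_fraction * n)
    wet_rows <- if (n_wet > 0) sample.int(n, n_wet) else integer()
    tab$x_w <- 0
    if (n_wet > 0)
      tab$x_w[wet_rows] <- sample(seq(0.1, 0.9, by = 0.1), n_wet,
                                  replace = TRUE)
    structure(list(table = as_des_table(tab),
                   true_labels = labels,
                   true_scores = z,
                   spec = spec),
              class = "des_sim")
  })
}

#' @export
print.des_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic descriptor dataset: %d systems, %d planted regimes, %d latent axes\n",
    x$spec$n_systems, x$spec$k, x$spec$n_factors))
  cat(sprintf("  noise_sd = %g, coupling = %g, wet fraction = %g, seed = %d\n",
              x$spec$noise_sd, x$spec$coupling, x$spec$wet_fraction,
              x$spec$seed))
  invisible(x)
}

#' Generate component-level system records
#'
#' Draws `n_systems` random API-DES systems at the component level:
#' HBA + HBD + API (plus water for a `wet_fraction` share of systems),
#' mole fractions on the simplex (summing to 1 exactly), per-component
#' interaction energies and chemical potentials in physically plausible
#' ranges (kcal/mol, all attractive), and a matching solute block. The
#' output feeds [assemble_table()] directly.
#'
#' @param n_systems Number of systems.
#' @param wet_fraction Fraction of systems carrying a water component.
#' @param seed Integer seed.
#' @return List with `components` (long format), `solute` and `metadata`
#'   data frames.
#' @export
simulate_component_records <- function(n_systems, wet_fraction = 0,
                                       seed = 1) {
  if (!is.numeric(n_systems) || n_systems < 1)
    stop("'n_systems' must be >= 1")
  with_local_seed(seed, function() {
    hbas <- c("ChCl", "Men", "Bet")
    hbds <- c("TRG", "TEG", "DEG", "ETG", "P2D", "B3D")
    apis <- sprintf("API%02d", 1:21)
    comp_list <- vector("list", n_systems)
    sol_list <- vector("list", n_systems)
    meta_list <- vector("list", n_systems)
    wet <- stats::runif(n_systems) < wet_fraction
    for (i in seq_len(n_systems)) {
      id <- sprintf("S%05d", i)
      roles <- c("HBA", "HBD", "API", if (wet[i]) "water")
      m <- length(roles)
      x <- stats::rexp(m) + 0.05
      x <- x / sum(x)
      x[m] <- 1 - sum(x[-m])          # exact unit sum
      comp_ids <- c(sample(hbas, 1), sample(hbds, 1), sample(apis, 1),
                    if (wet[i]) "water")
      comp_list[[i]] <- data.frame(
        system_id = id, component_id = comp_ids, role = roles,
        mole_fraction = x,
        E_tot = stats::runif(m, -30, -5),
        E_misfit = stats::runif(m, -10, -0.5),
        E_hbond = stats::runif(m, -15, -0.5),
        E_vdw = stats::runif(m, -12, -1),
        mu = stats::runif(m, -15, -1),
        stringsAsFactors = FALSE)
      sol_list[[i]] <- data.frame(
        system_id = id,
        logx_sle = stats::runif(1, -6, 0),
        mu_self = stats::runif(1, -12, -2),
        mu_sat = stats::runif(1, -12, -2),
        mu_water = stats::runif(1, -12, -2),
        solute_Etot = stats::runif(1, -30, -5),
        solute_Emisfit = stats::runif(1, -10, -0.5),
        solute_Ehbond = stats::runif(1, -15, -0.5),
        solute_Evdw = stats::runif(1, -12, -1),
        solute_gamma = stats::runif(1, -2, 6),
        stringsAsFactors = FALSE)
      meta_list[[i]] <- data.frame(
        system_id = id, api_id = comp_ids[3], hba_id = comp_ids[1],
        hbd_id = comp_ids[2],
        ratio = sample(c("1:2", "1:3", "1:4"), 1),
        temperature = 298.15, stringsAsFactors = FALSE)
    }
    list(components = do.call(rbind, comp_list),
         solute = do.call(rbind, sol_list),
         metadata = do.call(rbind, meta_list))
  })
}

#' Generate a synthetic calibration series
#'
#' Simulates absorbance readings `A = slope * C + intercept + noise` at
#' the given concentration levels, for testing calibration fitting and
#' LOD/LOQ estimation.
#'
#' @param slope,intercept Line parameters (absorbance per mg/mL,
#'   absorbance).
#' @param noise_sd Gaussian noise standard deviation (absorbance units);
#'   0 gives points exactly on the line.
#' @param concentrations At least 3 concentration levels (mg/mL).
#' @param seed Integer seed.
#' @return Data frame with columns `conc` and `abs`.
#' @export
simulate_calibration <- function(slope, intercept, noise_sd,
                                 concentrations, seed = 1) {
  if (length(concentrations) < 3)
    stop("at least 3 concentration levels are required")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  with_local_seed(seed, function() {
    data.frame(conc = concentrations,
               abs = slope * concentrations + intercept +
                 stats::rnorm(length(concentrations), sd = noise_sd))
  })
}
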