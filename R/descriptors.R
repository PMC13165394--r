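# Descriptor data model: the 20 COSMO-RS derived features describing one
# API-DES(-water) system, plus the fusion thermodynamics attached as metadata.

#' Canonical descriptor feature order
#'
#' Returns the fixed names, in canonical column order, of the twenty
#' thermodynamic descriptors characterising one API-DES system:
#' the COSMO-RS predicted solubility (`logx_sle`, decadal log of the
#' saturation mole fraction), chemical potentials of the API (pure,
#' saturated, aqueous), the solute interaction-energy decomposition
#' (total, electrostatic misfit, hydrogen bond, van der Waals), the API
#' activity coefficient (`solute_gamma`, natural log scale), the
#' mixture-weighted solvent energies and chemical potential, and the six
#' relative solute-minus-solvent descriptors.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' des_features()
des_features <- function() {
  c("logx_sle", "mu_self", "mu_sat", "mu_water",
    "solute_Etot", "solute_Emisfit", "solute_Ehbond", "solute_Evdw",
    "solute_gamma",
    "solv_Etot", "solv_Emisfit", "solv_Ehbond", "solv_Evdw", "solv_mu",
    "rel_mu", "rel_mu_water",
    "rel_Etot", "rel_Emisfit", "rel_Ehbond", "rel_Evdw")
}

# metadata columns preceding the features in a descriptor table
des_metadata_cols <- function() {
  c("system_id", "api_id", "hba_id", "hbd_id", "ratio",
    "x_w", "is_wet", "temperature")
}

.energy_properties <- c("E_tot", "E_misfit", "E_hbond", "E_vdw", "mu")

#' Mole-fraction weighted mixture property
#'
#' Aggregates a per-component COSMO-RS quantity into a single solvent-phase
#' value as the mole-fraction weighted sum over the mixture components,
#' i.e. `sum(x_i * value_i)`. This is how the solvent-side energies
#' (`solv_Etot`, `solv_Emisfit`, `solv_Ehbond`, `solv_Evdw`) and the solvent
#' chemical potential (`solv_mu`) are formed from component records: three
#' components for a dry DES (HBA, HBD, API) and four when water is present.
#'
#' @param components Data frame with a `mole_fraction` column and the
#'   requested property column. Mole fractions must sum to 1.
#' @param property One of `"E_tot"`, `"E_misfit"`, `"E_hbond"`, `"E_vdw"`,
#'   `"mu"`.
#' @param tol Allowed deviation of the mole-fraction sum from 1.
#' @return The weighted sum (scalar).
#' @export
#' @examples
#' comps <- data.frame(mole_fraction = c(0.2, 0.3, 0.5),
#'                     E_tot = c(-5, -10, -20))
#' aggregate_mixture_property(comps, "E_tot")  # -14
aggregate_mixture_property <- function(components, property, tol = 1e-6) {
  property <- match.arg(property, .energy_properties)
  if (!is.data.frame(components) || nrow(components) == 0L)
    stop("'components' must be a non-empty data frame")
  if (!all(c("mole_fraction", property) %in% names(components)))
    stop("'components' must carry columns 'mole_fraction' and '",
         property, "'")
  x <- components$mole_fraction
  dev <- abs(sum(x) - 1)
  if (dev > tol)
    stop(sprintf(
      "component mole fractions must sum to 1; deviation %.3e exceeds %.0e",
      dev, tol))
  sum(x * components[[property]])
}

#' Fill the relative (solute minus solvent) descriptors
#'
#' Completes a descriptor record by computing the six relative descriptors
#' as exact differences:
#' `rel_mu = mu_sat - solv_mu`, `rel_mu_water = mu_sat - mu_water`, and
#' `rel_E* = solute_E* - solv_E*` for the total, misfit, hydrogen-bond and
#' van der Waals energy contributions. The operation is idempotent.
#'
#' @param record Data frame (one or more rows) holding the solute block
#'   (`mu_sat`, `mu_water`, `solute_Etot`, `solute_Emisfit`,
#'   `solute_Ehbond`, `solute_Evdw`) and solvent block (`solv_mu`,
#'   `solv_Etot`, `solv_Emisfit`, `solv_Ehbond`, `solv_Evdw`).
#' @return `record` with the six `rel_*` columns (re)computed.
#' @export
derive_relative_descriptors <- function(record) {
  need <- c("mu_sat", "mu_water", "solv_mu",
            "solute_Etot", "solute_Emisfit", "solute_Ehbond", "solute_Evdw",
            "solv_Etot", "solv_Emisfit", "solv_Ehbond", "solv_Evdw")
  missing <- setdiff(need, names(record))
  if (length(missing))
    stop("missing required fields: ", paste(missing, collapse = ", "))
  if (anyNA(record[need]))
    stop("required fields contain missing values")
  record$rel_mu       <- record$mu_sat - record$solv_mu
  record$rel_mu_water <- record$mu_sat - record$mu_water
  for (p in c("Etot", "Emisfit", "Ehbond", "Evdw"))
    record[[paste0("rel_", p)]] <-
      record[[paste0("solute_", p)]] - record[[paste0("solv_", p)]]
  record
}

#' Fusion thermodynamics of the solute
#'
#' Computes the entropy and Gibbs free energy of fusion from the melting
#' temperature and enthalpy of fusion, using the standard approximation
#' `dS_fus = dH_fus / T_m` and `dG_fus = dH_fus - T * dS_fus`
#' `= dH_fus * (1 - T / T_m)`. At `T = T_m` the Gibbs energy of fusion is
#' exactly zero.
#'
#' @param dH_fus Enthalpy of fusion (kJ/mol).
#' @param T_m Melting temperature (K), positive.
#' @param T Evaluation temperature (K), positive; defaults to `T_m`.
#' @return List with `dS_fus` (kJ/(mol K)) and `dG_fus` (kJ/mol).
#' @export
#' @examples
#' fusion_gibbs(20, 400, 300)  # dG_fus = 5 kJ/mol
fusion_gibbs <- function(dH_fus, T_m, T = T_m) {
  if (!is.finite(T_m) || T_m <= 0) stop("'T_m' must be positive")
  if (!is.finite(T) || T <= 0) stop("'T' must be positive")
  dS <- dH_fus / T_m
  list(dS_fus = dS, dG_fus = dH_fus - T * dS)
}

#' Assemble a descriptor table from component-level inputs
#'
#' Builds the full 20-descriptor table for a set of API-DES systems from
#' long-format per-component COSMO-RS summaries and a per-system solute
#' block. For each system the five solvent-side descriptors are formed as
#' mole-fraction weighted sums over the mixture components (see
#' [aggregate_mixture_property()]), the water mole fraction `x_w` is read
#' off the water component (0 when absent), and the six relative
#' descriptors are derived exactly (see [derive_relative_descriptors()]).
#'
#' By default the weights are the saturated-mixture mole fractions, i.e.
#' the API (and water, when present) participate in the solvent-phase
#' weighted sums: N = 3 components for dry systems, N = 4 for wet ones.
#' Setting `normalization = "solute_free"` instead renormalizes the
#' non-API components to sum to 1 before weighting.
#'
#' @param components Long-format data frame with columns `system_id`,
#'   `component_id`, `role` (one of `"HBA"`, `"HBD"`, `"API"`, `"water"`),
#'   `mole_fraction`, `E_tot`, `E_misfit`, `E_hbond`, `E_vdw`, `mu`.
#' @param solute Data frame with one row per system: `system_id`,
#'   `logx_sle`, `mu_self`, `mu_sat`, `mu_water`, `solute_Etot`,
#'   `solute_Emisfit`, `solute_Ehbond`, `solute_Evdw`, `solute_gamma`.
#' @param metadata Optional data frame with `system_id`, `api_id`,
#'   `hba_id`, `hbd_id`, `ratio`, `temperature`; identifiers default to
#'   the component records where absent.
#' @param normalization `"saturated"` (default) or `"solute_free"`.
#' @param tol Allowed deviation of per-system mole-fraction sums from 1.
#' @return A `des_table`: data frame with the metadata columns followed by
#'   the 20 features in canonical order (attribute `feature_order`).
#' @seealso [read_descriptor_table()], [simulate_component_records()]
#' @export
assemble_table <- function(components, solute, metadata = NULL,
                           normalization = c("saturated", "solute_free"),
                           tol = 1e-6) {
  normalization <- match.arg(normalization)
  comp_need <- c("system_id", "component_id", "role", "mole_fraction",
                 "E_tot", "E_misfit", "E_hbond", "E_vdw", "mu")
  missing <- setdiff(comp_need, names(components))
  if (length(missing))
    stop("'components' lacks columns: ", paste(missing, collapse = ", "))
  sol_need <- c("system_id", "logx_sle", "mu_self", "mu_sat", "mu_water",
                "solute_Etot", "solute_Emisfit", "solute_Ehbond",
                "solute_Evdw", "solute_gamma")
  missing <- setdiff(sol_need, names(solute))
  if (length(missing))
    stop("'solute' lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(solute$system_id))
    stop("duplicate system_id in 'solute': ",
         solute$system_id[duplicated(solute$system_id)][1L])

  ids <- unique(components$system_id)
  if (!setequal(ids, solute$system_id))
    stop("'components' and 'solute' must cover the same systems")

  rows <- lapply(ids, function(id) {
    cc <- components[components$system_id == id, , drop = FALSE]
    n_comp <- nrow(cc)
    wet <- any(cc$role == "water")
    if (n_comp != if (wet) 4L else 3L)
      stop(sprintf("system '%s': expected %d components, found %d",
                   id, if (wet) 4L else 3L, n_comp))
    x_w <- if (wet) sum(cc$mole_fraction[cc$role == "water"]) else 0
    ww <- cc
    if (normalization == "solute_free") {
      ww <- ww[ww$role != "API", , drop = FALSE]
      ww$mole_fraction <- ww$mole_fraction / sum(ww$mole_fraction)
    }
    solv <- tryCatch(
      vapply(.energy_properties, function(p)
        aggregate_mixture_property(ww, p, tol = tol), numeric(1)),
      error = function(e)
        stop(sprintf("system '%s': %s", id, conditionMessage(e)),
             call. = FALSE))
    data.frame(system_id = id,
               hba_id = cc$component_id[match("HBA", cc$role)],
               hbd_id = cc$component_id[match("HBD", cc$role)],
               api_id_comp = cc$component_id[match("API", cc$role)],
               x_w = x_w, is_wet = x_w > 0,
               solv_Etot = solv[["E_tot"]], solv_Emisfit = solv[["E_misfit"]],
               solv_Ehbond = solv[["E_hbond"]], solv_Evdw = solv[["E_vdw"]],
               solv_mu = solv[["mu"]],
               stringsAsFactors = FALSE)
  })
  agg <- do.call(rbind, rows)

  tab <- merge(agg, solute, by = "system_id", sort = FALSE)
  tab$api_id <- tab$api_id_comp
  tab$ratio <- NA_character_
  tab$temperature <- NA_real_
  if (!is.null(metadata)) {
    for (col in c("api_id", "hba_id", "hbd_id", "ratio", "temperature")) {
      if (col %in% names(metadata)) {
        idx <- match(tab$system_id, metadata$system_id)
        tab[[col]] <- metadata[[col]][idx]
      }
    }
  }
  tab <- derive_relative_descriptors(tab)
  as_des_table(tab)
}

#' Coerce and validate a descriptor table
#'
#' Checks a data frame against the descriptor-table contract -- all 20
#' features present and finite, unique system identifiers, `is_wet`
#' consistent with `x_w`, and the six relative-descriptor identities exact
#' to `tol` -- then fixes the canonical column order and attaches the
#' `des_table` class.
#'
#' @param x Data frame carrying the metadata and feature columns.
#' @param tol Tolerance for the `rel_*` identity checks.
#' @return `x`, column-ordered, with class `des_table`.
#' @export
as_des_table <- function(x, tol = 1e-9) {
  feats <- des_features()
  missing <- setdiff(feats, names(x))
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  if (!"system_id" %in% names(x)) stop("missing 'system_id' column")
  dup <- x$system_id[duplicated(x$system_id)]
  if (length(dup)) stop("duplicate system_id: ", dup[1L])
  for (col in feats)
    if (!all(is.finite(x[[col]])))
      stop("non-finite values in feature '", col, "' (row ",
           which(!is.finite(x[[col]]))[1L], ")")
  if (!"x_w" %in% names(x)) x$x_w <- 0
  x$is_wet <- x$x_w > 0
  for (col in setdiff(des_metadata_cols(), names(x))) x[[col]] <- NA
  err <- check_rel_identities(x, tol)
  if (length(err))
    stop("relative-descriptor identity violated: ", err[1L])
  x <- x[, c(des_metadata_cols(), feats)]
  attr(x, "feature_order") <- feats
  class(x) <- c("des_table", "data.frame")
  x
}

# returns character() when all identities hold, else messages per violation
check_rel_identities <- function(x, tol = 1e-9) {
  pairs <- list(
    rel_mu       = x$mu_sat - x$solv_mu,
    rel_mu_water = x$mu_sat - x$mu_water,
    rel_Etot     = x$solute_Etot - x$solv_Etot,
    rel_Emisfit  = x$solute_Emisfit - x$solv_Emisfit,
    rel_Ehbond   = x$solute_Ehbond - x$solv_Ehbond,
    rel_Evdw     = x$solute_Evdw - x$solv_Evdw)
  msgs <- character()
  for (nm in names(pairs)) {
    dev <- abs(x[[nm]] - pairs[[nm]])
    if (any(dev > tol))
      msgs <- c(msgs, sprintf("%s (row %s, deviation %.3e)", nm,
                              x$system_id[which.max(dev)], max(dev)))
  }
  msgs
}

#' Extract the feature matrix of a descriptor table
#'
#' @param x A `des_table` (or any data frame carrying the 20 feature
#'   columns).
#' @return Numeric matrix, rows named by `system_id` where available,
#'   columns in canonical feature order.
#' @export
des_feature_matrix <- function(x) {
  feats <- des_features()
  missing <- setdiff(feats, names(x))
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  m <- as.matrix(as.data.frame(x)[, feats])
  storage.mode(m) <- "double"
  if ("system_id" %in% names(x)) rownames(m) <- as.character(x$system_id)
  m
}

#' Read / write descriptor tables
#'
#' Descriptor tables are stored as plain CSV with the metadata columns
#' (`system_id`, `api_id`, `hba_id`, `hbd_id`, `ratio`, `x_w`, `is_wet`,
#' `temperature`) followed by the 20 features in canonical order. Values
#' are written with 17 significant digits, enough to reproduce every
#' double exactly, so a save/load round trip is bit-faithful; the table
#' is re-validated on read.
#'
#' @param path File path.
#' @param x A `des_table`.
#' @return `read_descriptor_table` returns a validated `des_table`;
#'   `write_descriptor_table` returns `path` invisibly.
#' @export
read_descriptor_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_des_table(x)
}

#' @rdname read_descriptor_table
#' @export
write_descriptor_table <- function(x, path) {
  x <- as_des_table(x)
  out <- as.data.frame(x)
  for (col in des_features()) out[[col]] <- format(out[[col]], digits = 17)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.des_table <- function(x, ...) {
  cat(sprintf("Descriptor table: %d systems (%d dry, %d wet), %d features\n",
              nrow(x), sum(!x$is_wet), sum(x$is_wet),
              length(des_features())))
  if (nrow(x))
    print(utils::head(as.data.frame(x)[, c("system_id", "api_id", "hba_id",
                                           "hbd_id", "x_w", "logx_sle")]),
          ...)
  invisible(x)
}
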