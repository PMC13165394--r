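# Orchestration: run the full analysis (PCA -> scan -> select -> cluster
# -> regimes) on a descriptor table, optionally split into dry / wet
# subsets, writing plain-text artifacts that are bit-identical across
# reruns.

#' Run the full taxonomy pipeline and write artifacts
#'
#' Executes the analysis end to end on a descriptor table: for each
#' requested subset (`full`, `dry` with `x_w == 0`, `wet` with
#' `x_w > 0`) it fits [des_taxonomy()] and writes, under
#' `out_dir/<subset>/`, the serialized PCA model (`pca.json`), the
#' validation scan (`scan.csv`), the cluster labels (`labels.csv`), the
#' regime assignments of the training systems (`assignments.csv`) and a
#' run summary (`taxonomy.json`: selected k, regimes, centroids,
#' acceptance flags). No stage mutates an upstream artifact, nothing
#' here is randomized, and no timestamps are written, so two runs on the
#' same inputs produce identical files.
#'
#' @param table A `des_table` or a path to a descriptor CSV.
#' @param out_dir Output directory (created if needed).
#' @param subsets Which subsets to run; defaults to `"full"` plus
#'   `"dry"`/`"wet"` whenever both conditions are present. Subsets
#'   smaller than `max(k_range) + 1` rows are skipped with a message.
#' @param n_retained,k,k_range,threshold Passed to [des_taxonomy()].
#' @param quiet Suppress progress messages.
#' @return Named list of `des_taxonomy` fits (invisibly).
#' @export
run_pipeline <- function(table, out_dir, subsets = NULL,
                         n_retained = 5, k = NULL, k_range = 2:18,
                         threshold = 3.0, quiet = FALSE) {
  if (is.character(table)) table <- read_descriptor_table(table)
  table <- as_des_table(table)
  if (max(k_range) > nrow(table) - 1)
    stop("impossible k_range: max(k_range) = ", max(k_range),
         " exceeds n - 1 = ", nrow(table) - 1)
  if (is.null(subsets)) {
    subsets <- "full"
    if (any(table$is_wet) && any(!table$is_wet))
      subsets <- c("full", "dry", "wet")
  }
  say <- function(...) if (!quiet) message(...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fits <- list()
  for (sub in subsets) {
    rows <- switch(sub,
                   full = rep(TRUE, nrow(table)),
                   dry = !table$is_wet,
                   wet = table$is_wet,
                   stop("unknown subset '", sub, "'"))
    tab <- table[rows, , drop = FALSE]
    if (nrow(tab) <= max(k_range)) {
      say("subset '", sub, "': only ", nrow(tab),
          " rows, fewer than max(k_range) + 1; skipped")
      next
    }
    say("subset '", sub, "': ", nrow(tab), " systems")
    fit <- des_taxonomy(tab, n_retained = n_retained, k = k,
                        k_range = k_range, threshold = threshold)
    say("  selected k = ", fit$k, "; regimes: ",
        paste(fit$regimes, collapse = ", "))
    dir.create(file.path(out_dir, sub), showWarnings = FALSE)
    write_des_pca(fit$pca, file.path(out_dir, sub, "pca.json"))
    utils::write.csv(as.data.frame(fit$scan),
                     file.path(out_dir, sub, "scan.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(system_id = fit$system_id,
                 cluster = fit$clusters$labels,
                 regime = unname(fit$regimes[as.character(
                   fit$clusters$labels)])),
      file.path(out_dir, sub, "labels.csv"), row.names = FALSE)
    utils::write.csv(predict(fit, tab),
                     file.path(out_dir, sub, "assignments.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(subset = sub, n = nrow(tab), k = fit$k,
           threshold = threshold,
           accepted_k = fit$scan$k[fit$scan$accepted],
           regimes = as.list(fit$regimes),
           centroids = unname(fit$clusters$centroids),
           inertia = fit$clusters$inertia),
      file.path(out_dir, sub, "taxonomy.json"),
      auto_unbox = TRUE, digits = NA)
    fits[[sub]] <- fit
  }
  invisible(fits)
}
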