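# End-to-end orchestration: join sample spectra with measured chlorophyll,
# run the cross-validated band-pair search per index family, select optimal
# bands by contour centroid, fit the final two-band model, and emit a
# reproducible report. A thin command-line wrapper over these functions
# lives in inst/cli/chlorospec.R.

#' Build and validate a run configuration
#'
#' @param spectra_csv long-format spectra CSV (see [read_spectra()]).
#' @param lcc_csv chlorophyll table CSV (see [read_lcc_table()]).
#' @param out_dir output directory (created if needed); `NULL` disables
#'   file output.
#' @param vis index families to search.
#' @param window_nm increasing two-element search window (nm).
#' @param k CV fold count.
#' @param seed fold-shuffling seed.
#' @param delta top-region R² depth for centroid selection.
#' @return list of class `run_config`.
#' @export
run_config <- function(spectra_csv, lcc_csv, out_dir = NULL,
                       vis = c("ND", "SR", "CI"), window_nm = c(450, 800),
                       k = 10L, seed = 1L, delta = 0.01) {
  vis <- match.arg(vis, VI_KINDS, several.ok = TRUE)
  if (length(window_nm) != 2L || !all(is.finite(window_nm)) ||
      window_nm[1L] >= window_nm[2L])
    stop(sprintf("window_nm must be increasing; got (%s)",
                 paste(window_nm, collapse = ", ")))
  if (k < 2L) stop("k must be at least 2")
  if (!is.finite(delta) || delta < 0) stop("delta must be non-negative")
  for (p in c(spectra_csv, lcc_csv))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  structure(
    list(spectra_csv = spectra_csv, lcc_csv = lcc_csv, out_dir = out_dir,
         vis = vis, window_nm = window_nm, k = as.integer(k),
         seed = as.integer(seed), delta = delta),
    class = "run_config"
  )
}

# join spectra matrix rows with the chlorophyll table by explicit sample_id;
# positional joining is never used
.join_samples <- function(sm, lcc_df) {
  ids_s <- rownames(sm$spectra)
  ids_l <- lcc_df$sample_id
  only_s <- setdiff(ids_s, ids_l)
  only_l <- setdiff(ids_l, ids_s)
  if (length(only_s) || length(only_l))
    stop(sprintf(
      "sample id mismatch between spectra and chlorophyll tables; spectra-only: %s; chlorophyll-only: %s",
      if (length(only_s)) paste(only_s, collapse = ", ") else "(none)",
      if (length(only_l)) paste(only_l, collapse = ", ") else "(none)"))
  common <- ids_s
  list(spectra = sm$spectra[common, , drop = FALSE],
       lcc = lcc_df$lcc_ug_cm2[match(common, ids_l)],
       sample_id = common)
}

#' Run the full optimal-band analysis
#'
#' Executes, per index family: the exhaustive cross-validated band-pair
#' search over the window, centroid selection of the optimal bands, a final
#' full-data model fit at those bands, and a k-fold CV of that final model
#' (same seed). Writes long-format grid CSVs, centroid + model JSON and a
#' run report JSON under `out_dir` when configured. All randomness comes
#' from `config$seed`, so a rerun with the same config is identical.
#'
#' @param config a `run_config`.
#' @return An object of class `run_report`: per-VI list with `grid`,
#'   `centroid`, `model`, `fit`, `cv`, `strength`, plus `provenance`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sm <- spectra_matrix(read_spectra(config$spectra_csv))
  lcc_df <- read_lcc_table(config$lcc_csv)
  joined <- .join_samples(sm, lcc_df)
  if (nrow(joined$spectra) < config$k)
    stop(sprintf("only %d joined samples; need at least k = %d",
                 nrow(joined$spectra), config$k))
  rng <- range(sm$wavelengths)
  if (config$window_nm[1L] < rng[1L] || config$window_nm[2L] > rng[2L])
    stop(sprintf("window (%g, %g) nm outside the data axis [%g, %g] nm",
                 config$window_nm[1L], config$window_nm[2L], rng[1L], rng[2L]))

  per_vi <- list()
  for (vi in config$vis) {
    grid <- pair_search(joined$spectra, sm$wavelengths, joined$lcc, vi,
                        window_nm = config$window_nm, k = config$k,
                        seed = config$seed)
    centroid <- top_region_centroid(grid, config$delta)
    final <- fit_final_model(joined$spectra, sm$wavelengths, joined$lcc, vi,
                             centroid)
    ii <- nearest_band(sm$wavelengths, centroid$cx_nm)
    ij <- nearest_band(sm$wavelengths, centroid$cy_nm)
    x <- compute_vi(joined$spectra[, ii], joined$spectra[, ij], vi)
    cv <- kfold_cv(x, joined$lcc, k = config$k, seed = config$seed)
    per_vi[[vi]] <- list(grid = grid, centroid = centroid,
                         model = final$model, fit = final$fit, cv = cv,
                         strength = strength_label(final$fit$r))
  }
  report <- structure(
    list(results = per_vi,
         provenance = list(
           package = "chlorospec",
           version = as.character(utils::packageVersion("chlorospec")),
           n_samples = length(joined$sample_id),
           k = config$k, seed = config$seed, delta = config$delta,
           window_nm = config$window_nm)),
    class = "run_report"
  )
  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary_rows <- list()
  for (vi in names(report$results)) {
    res <- report$results[[vi]]
    utils::write.csv(grid_to_df(res$grid),
                     file.path(out_dir, sprintf("grid_%s.csv", vi)),
                     row.names = FALSE)
    write_model(res$model, file.path(out_dir, sprintf("model_%s.json", vi)))
    jsonlite::write_json(
      list(centroid = unclass(res$centroid), model = unclass(res$model),
           in_sample = unclass(res$fit),
           cv = list(mean_r2 = res$cv$mean_r2, mean_rmse = res$cv$mean_rmse,
                     k = res$cv$k, seed = res$cv$seed),
           strength = res$strength),
      file.path(out_dir, sprintf("result_%s.json", vi)),
      auto_unbox = TRUE, digits = NA)
    summary_rows[[vi]] <- data.frame(
      vi = vi, lambda_i_nm = res$centroid$cx_nm,
      lambda_j_nm = res$centroid$cy_nm,
      half_width_i_nm = res$centroid$half_width_i_nm,
      half_width_j_nm = res$centroid$half_width_j_nm,
      cv_r2 = res$cv$mean_r2, cv_rmse = res$cv$mean_rmse,
      r = res$fit$r, strength = res$strength,
      slope = res$model$slope, intercept = res$model$intercept)
  }
  utils::write.csv(do.call(rbind, summary_rows),
                   file.path(out_dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> n=%d, k=%d, seed=%d, window %g-%g nm\n",
              x$provenance$n_samples, x$provenance$k, x$provenance$seed,
              x$provenance$window_nm[1L], x$provenance$window_nm[2L]))
  for (vi in names(x$results)) {
    res <- x$results[[vi]]
    cat(sprintf(
      "  %s: optimum (%.1f +/- %.1f, %.1f +/- %.1f) nm  CV R2=%.3f RMSE=%.3f  r=%.3f (%s)\n",
      vi, res$centroid$cx_nm, res$centroid$half_width_i_nm,
      res$centroid$cy_nm, res$centroid$half_width_j_nm,
      res$cv$mean_r2, res$cv$mean_rmse, res$fit$r, res$strength))
  }
  invisible(x)
}

#' Predict a chlorophyll map for a cube with a saved model
#'
#' Segments the cube, applies the two-band model per leaf pixel, writes the
#' map as CSV (`row`, `col`, `lcc_ug_cm2`) when `out_csv` is given, and
#' returns the map with summary statistics.
#'
#' @param cube a `hypercube` or a cube file path.
#' @param model a `prediction_model` or a model JSON path.
#' @param out_csv optional output CSV path.
#' @param ... passed to [segment_leaf()].
#' @return list with `map` (LCC matrix), `mean_lcc`, `sd_lcc`, `n_pixels`.
#' @export
predict_map <- function(cube, model, out_csv = NULL, ...) {
  if (is.character(cube)) cube <- read_cube(cube)
  if (is.character(model)) model <- read_model(model)
  mask <- segment_leaf(cube, ...)
  map <- vi_map(cube, mask, model)
  vals <- map[is.finite(map)]
  if (!is.null(out_csv)) {
    idx <- which(is.finite(map), arr.ind = TRUE)
    utils::write.csv(
      data.frame(row = idx[, 1L], col = idx[, 2L], lcc_ug_cm2 = map[idx]),
      out_csv, row.names = FALSE)
  }
  list(map = map, mean_lcc = mean(vals), sd_lcc = stats::sd(vals),
       n_pixels = length(vals))
}
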