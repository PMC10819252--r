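# Statistical core: simple linear regression of LCC on each two-band
# vegetation index, scored by ten-fold cross-validation over the full
# ordered grid of band pairs, followed by moment-centroid selection of the
# optimal bands from the top-R^2 contour region.

# run code under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simple linear regression with R², RMSE and Pearson r
#'
#' Closed-form ordinary least squares of `y` on `x` with intercept.
#' `R² = 1 - SSres/SStot`; `RMSE = sqrt(mean((y - yhat)^2))` in y-units;
#' `r` is the Pearson correlation. For in-sample simple regression,
#' `R² = r²`.
#'
#' @param x predictor values (n >= 3, non-zero variance).
#' @param y response values (LCC, µg·cm⁻²; non-zero variance).
#' @return An object of class `regression_fit`: list with `slope`,
#'   `intercept`, `r2`, `rmse`, `r`, `n`.
#' @export
ols_fit <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("ols_fit needs at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  syy <- sum((y - ybar)^2)
  if (sxx <= 0) stop("zero predictor variance: regression undefined")
  if (syy <= 0) stop("zero response variance: R-squared undefined")
  sxy <- sum((x - xbar) * (y - ybar))
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  res <- y - (intercept + slope * x)
  ssres <- sum(res^2)
  structure(
    list(slope = slope, intercept = intercept,
         r2 = 1 - ssres / syy,
         rmse = sqrt(ssres / n),
         r = sxy / sqrt(sxx * syy),
         n = n),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "<regression_fit> n=%d  y = %.4g x %+.4g   R2=%.4f RMSE=%.4g r=%.4f\n",
    x$n, x$slope, x$intercept, x$r2, x$rmse, x$r))
  invisible(x)
}

#' Seeded k-fold assignment
#'
#' Shuffles sample indices with the given seed and partitions them into `k`
#' near-equal folds (sizes differ by at most one; each sample appears in
#' exactly one fold).
#'
#' @param n number of samples.
#' @param k number of folds (>= 2).
#' @param seed integer RNG seed.
#' @return integer vector of fold ids (1..k) per sample.
#' @export
make_folds <- function(n, k = 10L, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  if (n < k) stop(sprintf("cannot make %d folds from %d samples", k, n))
  perm <- .with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), length.out = n)
  fold
}

#' k-fold cross-validated simple regression
#'
#' Per fold, an OLS line is fitted on the training samples and scored on the
#' held-out fold: validation R² uses the held-out fold's own mean, and
#' validation RMSE is the root mean squared held-out residual (µg·cm⁻²).
#' Reported means are the unweighted average over folds. With
#' `pooled = TRUE`, metrics are instead computed once over the pooled
#' out-of-fold predictions.
#'
#' @param x predictor values.
#' @param y response values (LCC).
#' @param k fold count (default 10).
#' @param seed shuffling seed, recorded in the result.
#' @param folds optional precomputed fold assignment (overrides `seed`).
#' @param pooled if TRUE, also report pooled-prediction metrics.
#' @return An object of class `cv_result`: `mean_r2`, `mean_rmse`, `k`,
#'   `seed`, `fold_metrics` (data.frame), `folds`, and optionally
#'   `pooled_r2` / `pooled_rmse`.
#' @export
kfold_cv <- function(x, y, k = 10L, seed = 1L, folds = NULL, pooled = FALSE) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < k) stop(sprintf("n = %d is smaller than k = %d", n, k))
  if (is.null(folds)) folds <- make_folds(n, k, seed)
  fm <- data.frame(fold = seq_len(k), n_val = NA_integer_,
                   r2 = NA_real_, rmse = NA_real_)
  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    val <- folds == f
    fit <- ols_fit(x[!val], y[!val])
    yh <- fit$intercept + fit$slope * x[val]
    yv <- y[val]
    ssres <- sum((yv - yh)^2)
    sstot <- sum((yv - mean(yv))^2)
    fm$n_val[f] <- sum(val)
    fm$r2[f] <- 1 - ssres / sstot
    fm$rmse[f] <- sqrt(ssres / sum(val))
    pred[val] <- yh
  }
  out <- structure(
    list(mean_r2 = mean(fm$r2), mean_rmse = mean(fm$rmse), k = k,
         seed = seed, fold_metrics = fm, folds = folds),
    class = "cv_result"
  )
  if (pooled) {
    ssres <- sum((y - pred)^2)
    out$pooled_r2 <- 1 - ssres / sum((y - mean(y))^2)
    out$pooled_rmse <- sqrt(ssres / n)
  }
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> k=%d seed=%d  mean R2=%.4f  mean RMSE=%.4g\n",
              x$k, x$seed, x$mean_r2, x$mean_rmse))
  invisible(x)
}

#' Exhaustive cross-validated band-pair search
#'
#' For every ordered band pair (λi, λj) in the search window, forms the
#' chosen two-band index per sample, regresses LCC on it with k-fold
#' cross-validation (identical fold assignment for all pairs), and stores
#' mean validation R², mean validation RMSE and the full-data Pearson r in
#' band-by-band grids. Degenerate pairs — zero-variance predictors (all
#' diagonals λi = λj) or pairs producing non-finite index values — are
#' excluded and counted.
#'
#' The computation is vectorised over λi for each λj via per-fold sufficient
#' statistics, so the full 351-band grid runs in seconds.
#'
#' @param spectra samples x bands reflectance matrix.
#' @param wavelengths_nm spectral axis (nm), length `ncol(spectra)`.
#' @param lcc per-sample LCC (µg·cm⁻²).
#' @param vi index family (`"ND"`, `"SR"`, `"CI"`).
#' @param window_nm two-element search window (default `c(450, 800)`).
#' @param k fold count (default 10).
#' @param seed fold-shuffling seed, recorded in the result.
#' @return An object of class `band_pair_grid`: `wavelengths` (restricted
#'   axis), matrices `r2`, `rmse`, `r` (rows = λi, cols = λj; `NA` where
#'   excluded), logical `excluded`, integer `n_bad` (offending samples per
#'   pair), plus `vi`, `k`, `seed`, `n`.
#' @export
pair_search <- function(spectra, wavelengths_nm, lcc,
                        vi = c("ND", "SR", "CI"), window_nm = c(450, 800),
                        k = 10L, seed = 1L) {
  vi <- match.arg(vi)
  validate_axis(wavelengths_nm)
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(wavelengths_nm))
    stop("spectra column count must equal axis length")
  n <- nrow(spectra)
  if (length(lcc) != n) stop("lcc length must equal sample count")
  keep <- is.finite(lcc) & apply(spectra, 1L, function(r) all(is.finite(r)))
  if (!all(keep))
    stop(sprintf("%d sample(s) have non-finite spectra or LCC; remove them first",
                 sum(!keep)))
  if (n < k) stop(sprintf("need at least k = %d valid samples, have %d", k, n))
  if (length(window_nm) != 2L || window_nm[1L] >= window_nm[2L])
    stop("window_nm must be an increasing pair")
  idx <- which(wavelengths_nm >= window_nm[1L] & wavelengths_nm <= window_nm[2L])
  if (length(idx) < 2L) stop("search window contains fewer than 2 bands")
  S <- spectra[, idx, drop = FALSE]
  wl <- wavelengths_nm[idx]
  B <- length(idx)
  y <- as.numeric(lcc)

  folds <- make_folds(n, k, seed)
  Fm <- matrix(0, k, n)
  Fm[cbind(folds, seq_len(n))] <- 1
  nv <- as.integer(rowSums(Fm))
  Fy <- drop(Fm %*% y)
  Fy2 <- drop(Fm %*% y^2)
  Ty <- sum(y)
  Syy <- sum((y - mean(y))^2)

  r2g <- matrix(NA_real_, B, B)
  rmseg <- matrix(NA_real_, B, B)
  rg <- matrix(NA_real_, B, B)
  nbad <- matrix(0L, B, B)

  r2f <- matrix(0, k, B)
  rmsef <- matrix(0, k, B)
  for (j in seq_len(B)) {
    Rj <- S[, j]
    X <- switch(vi,
      SR = S / Rj,
      CI = S / Rj - 1,
      ND = (S - Rj) / (S + Rj))
    bad <- !is.finite(X)
    nb <- colSums(bad)
    if (any(nb > 0)) X[bad] <- 0
    X2 <- X * X
    Sx <- Fm %*% X
    Sxx <- Fm %*% X2
    Sxy <- Fm %*% (X * y)
    Tx <- colSums(Sx)
    Txx <- colSums(Sxx)
    Txy <- colSums(Sxy)
    sxx_full <- Txx - Tx^2 / n
    degen <- sxx_full <= 1e-10 * pmax(Txx, .Machine$double.xmin)
    for (f in seq_len(k)) {
      nt <- n - nv[f]
      tx <- Tx - Sx[f, ]
      txx <- Txx - Sxx[f, ]
      txy <- Txy - Sxy[f, ]
      ty <- Ty - Fy[f]
      sxx_t <- txx - tx^2 / nt
      degen <- degen | sxx_t <= 1e-10 * pmax(txx, .Machine$double.xmin)
      b <- (txy - tx * ty / nt) / sxx_t
      a <- ty / nt - b * tx / nt
      vx <- Sx[f, ]; vxx <- Sxx[f, ]; vxy <- Sxy[f, ]
      vy <- Fy[f]; vyy <- Fy2[f]
      ssres <- vyy - 2 * (a * vy + b * vxy) +
        nv[f] * a^2 + 2 * a * b * vx + b^2 * vxx
      sstot <- vyy - vy^2 / nv[f]
      r2f[f, ] <- 1 - ssres / sstot
      rmsef[f, ] <- sqrt(pmax(ssres, 0) / nv[f])
    }
    excl <- nb > 0L | degen
    m_r2 <- colMeans(r2f)
    m_rmse <- colMeans(rmsef)
    r_full <- (Txy - Tx * Ty / n) / sqrt(pmax(sxx_full, 0) * Syy)
    m_r2[excl] <- NA_real_
    m_rmse[excl] <- NA_real_
    r_full[excl] <- NA_real_
    r2g[, j] <- m_r2
    rmseg[, j] <- m_rmse
    rg[, j] <- r_full
    nbad[, j] <- nb
    if (j == 1L) excl_mat <- matrix(FALSE, B, B)
    excl_mat[, j] <- excl
  }

  structure(
    list(vi = vi, wavelengths = wl, r2 = r2g, rmse = rmseg, r = rg,
         excluded = excl_mat, n_bad = nbad, k = k, seed = seed, n = n),
    class = "band_pair_grid"
  )
}

#' @export
print.band_pair_grid <- function(x, ...) {
  best <- which(x$r2 == max(x$r2, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  cat(sprintf(
    "<band_pair_grid> %s, %d x %d bands (%g-%g nm), n=%d, k=%d, seed=%d\n",
    x$vi, length(x$wavelengths), length(x$wavelengths),
    min(x$wavelengths), max(x$wavelengths), x$n, x$k, x$seed))
  cat(sprintf("  max mean validation R2 = %.4f at (%g, %g) nm; %d excluded pairs\n",
              max(x$r2, na.rm = TRUE), x$wavelengths[best[1L]],
              x$wavelengths[best[2L]], sum(x$excluded)))
  invisible(x)
}

#' Long-format data frame of a band-pair grid
#'
#' @param grid a `band_pair_grid`.
#' @return data.frame with columns `vi`, `lambda_i_nm`, `lambda_j_nm`,
#'   `mean_r2`, `mean_rmse`, `r`, `excluded`, `n_bad`.
#' @export
grid_to_df <- function(grid) {
  stopifnot(inherits(grid, "band_pair_grid"))
  B <- length(grid$wavelengths)
  data.frame(
    vi = grid$vi,
    lambda_i_nm = rep(grid$wavelengths, times = B),
    lambda_j_nm = rep(grid$wavelengths, each = B),
    mean_r2 = as.vector(grid$r2),
    mean_rmse = as.vector(grid$rmse),
    r = as.vector(grid$r),
    excluded = as.vector(grid$excluded),
    n_bad = as.vector(grid$n_bad)
  )
}

#' Contour-map image of a band-pair grid
#'
#' Renders the mean validation R² surface with λi horizontal and λj
#' vertical, with contour lines overlaid.
#'
#' @param x a `band_pair_grid`.
#' @param ... passed to [graphics::image()].
#' @export
plot.band_pair_grid <- function(x, ...) {
  graphics::image(x$wavelengths, x$wavelengths, x$r2,
                  xlab = expression(lambda[i] ~ "(nm)"),
                  ylab = expression(lambda[j] ~ "(nm)"),
                  main = sprintf("%s: mean validation R²", x$vi),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::contour(x$wavelengths, x$wavelengths, x$r2, add = TRUE,
                    col = "white")
  invisible(x)
}

#' Optimal bands as the centroid of the top-R² contour region
#'
#' The candidate cells are every non-excluded grid cell whose mean
#' validation R² is within `delta` of the grid maximum (one contour step).
#' By default the selected region is the connected component (8-neighbour
#' connectivity) of those cells that contains the grid maximum — the closed
#' contour around the peak. This matters for the antisymmetric ND index,
#' whose R² surface is exactly mirror-symmetric about the diagonal: the full
#' super-level set always contains both mirrored lobes and its centroid
#' degenerates onto the diagonal, while the connected component isolates one
#' lobe. When the maximum is tied between mirror cells (within 1e-9), the
#' seed cell is taken with λi > λj, the conventional orientation with λi on
#' the NIR side. `connected = FALSE` gives the raw super-level set.
#'
#' With unit weights per cell, the centroid is the arithmetic mean position
#' in wavelength coordinates: `Cx = M10/M00` over λi and `Cy = M01/M00`
#' over λj, where `M00` is the cell count and `M10`, `M01` the first
#' moments. The half-extent of the region per axis is reported as the ±
#' spread.
#'
#' @param grid a `band_pair_grid`.
#' @param delta R² depth of the top region below the maximum (default 0.01).
#' @param connected restrict the region to the connected component holding
#'   the maximum (default TRUE).
#' @return An object of class `centroid_result`: `cx_nm`, `cy_nm` (centroid
#'   λi, λj), moments `m00`, `m10`, `m01`, `region_cells`, `level` (the R²
#'   level defining the region), `half_width_i_nm`, `half_width_j_nm`,
#'   `max_r2`, `delta`, `vi`.
#' @export
top_region_centroid <- function(grid, delta = 0.01, connected = TRUE) {
  stopifnot(inherits(grid, "band_pair_grid"))
  if (!is.finite(delta) || delta < 0) stop("delta must be non-negative")
  vals <- grid$r2
  if (!any(is.finite(vals)))
    stop("all grid cells are excluded; nothing to select")
  mx <- max(vals, na.rm = TRUE)
  level <- mx - delta
  inset <- is.finite(vals) & vals >= level
  if (connected) {
    cand <- which(is.finite(vals) & vals >= mx - 1e-9, arr.ind = TRUE)
    seed_cell <- cand[which.max(grid$wavelengths[cand[, 1L]] -
                                  grid$wavelengths[cand[, 2L]]), ]
    sel <- which(.connected_component(inset, seed_cell), arr.ind = TRUE)
  } else {
    sel <- which(inset, arr.ind = TRUE)
  }
  li <- grid$wavelengths[sel[, 1L]]
  lj <- grid$wavelengths[sel[, 2L]]
  m00 <- nrow(sel)
  m10 <- sum(li)
  m01 <- sum(lj)
  structure(
    list(cx_nm = m10 / m00, cy_nm = m01 / m00,
         m00 = m00, m10 = m10, m01 = m01,
         region_cells = m00, level = level,
         half_width_i_nm = (max(li) - min(li)) / 2,
         half_width_j_nm = (max(lj) - min(lj)) / 2,
         max_r2 = mx, delta = delta, vi = grid$vi),
    class = "centroid_result"
  )
}

#' @export
print.centroid_result <- function(x, ...) {
  cat(sprintf(
    "<centroid_result> %s optimum: lambda_i = %.1f +/- %.1f nm, lambda_j = %.1f +/- %.1f nm (R2 >= %.4f, %d cells)\n",
    x$vi, x$cx_nm, x$half_width_i_nm, x$cy_nm, x$half_width_j_nm,
    x$level, x$region_cells))
  invisible(x)
}

# 8-connected component of TRUE cells in `mask` containing `seed` (i, j)
.connected_component <- function(mask, seed) {
  comp <- matrix(FALSE, nrow(mask), ncol(mask))
  comp[seed[1L], seed[2L]] <- TRUE
  offsets <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                   c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  repeat {
    idx <- which(comp, arr.ind = TRUE)
    grown <- comp
    for (d in seq_len(nrow(offsets))) {
      ii <- idx[, 1L] + offsets[d, 1L]
      jj <- idx[, 2L] + offsets[d, 2L]
      ok <- ii >= 1L & ii <= nrow(mask) & jj >= 1L & jj <= ncol(mask)
      grown[cbind(ii[ok], jj[ok])] <- TRUE
    }
    grown <- grown & mask
    if (identical(grown, comp)) return(comp)
    comp <- grown
  }
}

#' Correlation-strength label for a Pearson r
#'
#' Bins |r| into the conventional five classes: negligible [0, 0.10), weak
#' [0.10, 0.40), moderate [0.40, 0.70), strong [0.70, 0.90), very strong
#' [0.90, 1]. Boundary values go to the higher-strength bin.
#'
#' @param r Pearson correlation in [-1, 1].
#' @return character label.
#' @export
strength_label <- function(r) {
  if (!is.finite(r) || abs(r) > 1 + 1e-12)
    stop("r must lie in [-1, 1]")
  a <- min(abs(r), 1)
  if (a < 0.10) "negligible"
  else if (a < 0.40) "weak"
  else if (a < 0.70) "moderate"
  else if (a < 0.90) "strong"
  else "very strong"
}

#' Fit the final two-band prediction model at the selected bands
#'
#' Full-data OLS of LCC on the chosen index evaluated at the bands nearest
#' the centroid position.
#'
#' @param spectra samples x bands reflectance matrix.
#' @param wavelengths_nm spectral axis (nm).
#' @param lcc per-sample LCC (µg·cm⁻²).
#' @param vi index family.
#' @param centroid a `centroid_result` (or a two-element numeric
#'   `c(lambda_i, lambda_j)` in nm).
#' @return list with `model` (a [prediction_model()]) and `fit` (the
#'   in-sample `regression_fit`).
#' @export
fit_final_model <- function(spectra, wavelengths_nm, lcc,
                            vi = c("ND", "SR", "CI"), centroid) {
  vi <- match.arg(vi)
  spectra <- as.matrix(spectra)
  bands <- if (inherits(centroid, "centroid_result"))
    c(centroid$cx_nm, centroid$cy_nm) else as.numeric(centroid)
  ii <- nearest_band(wavelengths_nm, bands[1L])
  ij <- nearest_band(wavelengths_nm, bands[2L])
  x <- compute_vi(spectra[, ii], spectra[, ij], vi)
  fit <- ols_fit(x, lcc)
  model <- prediction_model(
    vi, wavelengths_nm[ii], wavelengths_nm[ij], fit$slope, fit$intercept,
    meta = list(n = fit$n, in_sample_r2 = fit$r2, in_sample_rmse = fit$rmse,
                r = fit$r))
  list(model = model, fit = fit)
}
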