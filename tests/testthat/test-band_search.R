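test_that("ols_fit is exact on perfect lines", {
  x <- c(1, 2, 3, 5, 8)
  up <- ols_fit(x, 2 * x + 1)
  expect_equal(up$slope, 2, tolerance = 1e-12)
  expect_equal(up$intercept, 1, tolerance = 1e-12)
  expect_equal(up$r2, 1, tolerance = 1e-12)
  expect_equal(up$rmse, 0, tolerance = 1e-10)
  expect_equal(up$r, 1, tolerance = 1e-12)
  down <- ols_fit(x, -3 * x + 5)
  expect_equal(down$r, -1, tolerance = 1e-12)
  expect_equal(down$slope, -3, tolerance = 1e-12)
})

test_that("ols_fit matches the lm/cor oracle on random data", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    x <- rnorm(n)
    y <- rnorm(n, 2 * x)
    fit <- ols_fit(x, y)
    ref <- lm(y ~ x)
    expect_equal(fit$slope, unname(coef(ref)[2]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
    expect_equal(fit$r2, summary(ref)$r.squared, tolerance = 1e-10)
    expect_equal(fit$rmse, sqrt(mean(residuals(ref)^2)), tolerance = 1e-10)
    expect_equal(fit$r, cor(x, y), tolerance = 1e-10)
    # in-sample simple regression: R^2 = r^2
    expect_equal(fit$r2, fit$r^2, tolerance = 1e-10)
  }
})

test_that("degenerate regressions are errors", {
  expect_error(ols_fit(rep(1, 5), 1:5), "predictor variance")
  expect_error(ols_fit(1:5, rep(2, 5)), "response variance")
  expect_error(ols_fit(1:2, 1:2), "at least 3")
})

test_that("fold assignments are balanced partitions", {
  for (seed in 1:20) {
    f <- make_folds(120, 10, seed)
    expect_identical(sort(unique(f)), 1:10)
    expect_true(all(table(f) == 12L))
  }
  f2 <- make_folds(25, 4, 1)
  expect_true(max(table(f2)) - min(table(f2)) <= 1)
  expect_error(make_folds(5, 10), "cannot make")
})

test_that("cross-validation is exact on noiseless linear data and reproducible", {
  x <- seq(0, 1, length.out = 40)
  y <- 7 * x + 2
  for (seed in c(1, 99)) {
    cv <- kfold_cv(x, y, k = 10, seed = seed)
    expect_equal(cv$mean_r2, 1, tolerance = 1e-10)
    expect_equal(cv$mean_rmse, 0, tolerance = 1e-8)
  }
  set.seed(5)
  yn <- y + rnorm(40)
  a <- kfold_cv(x, yn, k = 5, seed = 3)
  b <- kfold_cv(x, yn, k = 5, seed = 3)
  expect_identical(a$fold_metrics, b$fold_metrics)
})

test_that("validation metrics use the held-out fold's own mean", {
  set.seed(8)
  x <- rnorm(30)
  y <- 1.5 * x + rnorm(30, 0, 0.5)
  folds <- make_folds(30, 3, 2)
  cv <- kfold_cv(x, y, k = 3, folds = folds)
  for (f in 1:3) {
    val <- folds == f
    fit <- ols_fit(x[!val], y[!val])
    yh <- fit$intercept + fit$slope * x[val]
    r2_ref <- 1 - sum((y[val] - yh)^2) / sum((y[val] - mean(y[val]))^2)
    expect_equal(cv$fold_metrics$r2[f], r2_ref, tolerance = 1e-12)
    expect_equal(cv$fold_metrics$rmse[f],
                 sqrt(mean((y[val] - yh)^2)), tolerance = 1e-12)
  }
})

test_that("pair_search agrees with a per-pair kfold_cv loop", {
  ds <- generate_dataset(small_config(n_bands = 8L, seed = 4))
  g <- pair_search(ds$spectra, ds$wavelengths, ds$lcc, "ND", k = 10,
                   seed = 21)
  folds <- make_folds(length(ds$lcc), 10, 21)
  for (i in 1:8) for (j in 1:8) {
    if (i == j) {
      expect_true(g$excluded[i, j])
      expect_true(is.na(g$r2[i, j]))
      next
    }
    x <- compute_vi(ds$spectra[, i], ds$spectra[, j], "ND")
    cv <- kfold_cv(x, ds$lcc, k = 10, folds = folds)
    expect_equal(g$r2[i, j], cv$mean_r2, tolerance = 1e-10)
    expect_equal(g$rmse[i, j], cv$mean_rmse, tolerance = 1e-10)
    expect_equal(g$r[i, j], cor(x, ds$lcc), tolerance = 1e-10)
  }
})

test_that("grid structure: dims, window restriction, diagonal exclusion", {
  ds <- generate_dataset(small_config(n_bands = 20L, seed = 2))
  g <- pair_search(ds$spectra, ds$wavelengths, ds$lcc, "ND",
                   window_nm = c(500, 700), seed = 1)
  inwin <- ds$wavelengths[ds$wavelengths >= 500 & ds$wavelengths <= 700]
  expect_equal(g$wavelengths, inwin)
  expect_identical(dim(g$r2), c(length(inwin), length(inwin)))
  expect_true(all(g$excluded[cbind(seq_along(inwin), seq_along(inwin))]))
  # fold reuse: rerunning is bit-identical
  g2 <- pair_search(ds$spectra, ds$wavelengths, ds$lcc, "ND",
                    window_nm = c(500, 700), seed = 1)
  expect_identical(g$r2, g2$r2)
})

test_that("SR and CI grids are identical cell-for-cell (affine equivalence)", {
  ds <- generate_dataset(small_config(n_bands = 15L, seed = 6))
  gsr <- pair_search(ds$spectra, ds$wavelengths, ds$lcc, "SR", seed = 5)
  gci <- pair_search(ds$spectra, ds$wavelengths, ds$lcc, "CI", seed = 5)
  expect_equal(gsr$r2, gci$r2, tolerance = 1e-10)
  expect_equal(gsr$rmse, gci$rmse, tolerance = 1e-10)
  expect_equal(gsr$r, gci$r, tolerance = 1e-10)
  expect_identical(gsr$excluded, gci$excluded)
})

test_that("the planted band pair is found by the noiseless search", {
  cfg <- small_config(n_bands = 40L, seed = 3, noise_sd = 0)
  ds <- generate_dataset(cfg)
  g <- pair_search(ds$spectra, ds$wavelengths, ds$lcc, "ND", seed = 8)
  # ND mirror cells carry identical regressions; orient toward lambda_i > lambda_j
  cand <- which(g$r2 >= max(g$r2, na.rm = TRUE) - 1e-9, arr.ind = TRUE)
  best <- cand[which.max(g$wavelengths[cand[, 1]] -
                           g$wavelengths[cand[, 2]]), ]
  expect_equal(g$wavelengths[best[1]], ds$truth$best_pair_nm[1])
  expect_equal(g$wavelengths[best[2]], ds$truth$best_pair_nm[2])
  expect_gt(max(g$r2, na.rm = TRUE), 0.999)
})

test_that("centroid moments equal brute-force double-loop sums", {
  mkgrid <- function(r2, wl) {
    structure(list(vi = "ND", wavelengths = wl, r2 = r2,
                   rmse = r2 * 0, r = r2 * 0,
                   excluded = !is.finite(r2), n_bad = r2 * 0L,
                   k = 10L, seed = 1L, n = 100L),
              class = "band_pair_grid")
  }
  set.seed(13)
  for (rep in 1:20) {
    B <- sample(8:20, 1)
    wl <- sort(runif(B, 450, 800))
    r2 <- matrix(runif(B * B), B, B)
    diag(r2) <- NA
    g <- mkgrid(r2, wl)
    cen <- top_region_centroid(g, delta = 0.02)
    ref <- brute_centroid(r2, wl, delta = 0.02)
    expect_identical(cen$m00, ref$m00)
    expect_equal(cen$m10, ref$m10, tolerance = 1e-12)
    expect_equal(cen$m01, ref$m01, tolerance = 1e-12)
    expect_equal(cen$cx_nm, ref$cx, tolerance = 1e-12)
    expect_equal(cen$cy_nm, ref$cy, tolerance = 1e-12)
    # centroid lies inside the selected region's bounding box
    expect_true(cen$cx_nm >= min(wl) && cen$cx_nm <= max(wl))
  }

  # single-cell region sits exactly on that cell
  r2 <- matrix(0.1, 5, 5)
  r2[2, 4] <- 0.9
  wl <- c(500, 550, 600, 650, 700)
  cen1 <- top_region_centroid(mkgrid(r2, wl), delta = 0.05)
  expect_equal(c(cen1$cx_nm, cen1$cy_nm), c(550, 650))
  expect_identical(cen1$region_cells, 1L)
  expect_equal(cen1$half_width_i_nm, 0)

  # symmetric plateau centres on its middle
  r2p <- matrix(0, 9, 9)
  r2p[4:6, 2:4] <- 0.8
  wlp <- seq(500, 580, by = 10)
  cenp <- top_region_centroid(mkgrid(r2p, wlp), delta = 0.01)
  expect_equal(c(cenp$cx_nm, cenp$cy_nm), c(540, 520))
  expect_identical(cenp$region_cells, 9L)

  # all-excluded grid errors
  allna <- mkgrid(matrix(NA_real_, 3, 3), c(500, 600, 700))
  expect_error(top_region_centroid(allna), "excluded")
})

test_that("mirror-symmetric ND surfaces resolve to the lambda_i > lambda_j lobe", {
  wl <- seq(500, 580, by = 10)
  r2 <- matrix(0, 9, 9)
  r2[7, 2] <- 0.9; r2[8, 2] <- 0.895   # lobe with lambda_i > lambda_j
  r2[2, 7] <- 0.9; r2[2, 8] <- 0.895   # exact mirror lobe
  g <- structure(list(vi = "ND", wavelengths = wl, r2 = r2, rmse = r2 * 0,
                      r = r2 * 0, excluded = !is.finite(r2), n_bad = r2 * 0L,
                      k = 10L, seed = 1L, n = 100L),
                 class = "band_pair_grid")
  cen <- top_region_centroid(g, delta = 0.01)
  expect_gt(cen$cx_nm, cen$cy_nm)
  expect_identical(cen$region_cells, 2L)
  # raw super-level set keeps both lobes
  cen_raw <- top_region_centroid(g, delta = 0.01, connected = FALSE)
  expect_identical(cen_raw$region_cells, 4L)
})

test_that("correlation strength bins follow the conventional intervals", {
  expect_identical(strength_label(0.87), "strong")
  expect_identical(strength_label(0.05), "negligible")
  expect_identical(strength_label(-0.95), "very strong")
  expect_identical(strength_label(0.25), "weak")
  expect_identical(strength_label(0.55), "moderate")
  # boundaries go to the higher-strength bin
  expect_identical(strength_label(0.10), "weak")
  expect_identical(strength_label(0.40), "moderate")
  expect_identical(strength_label(0.70), "strong")
  expect_identical(strength_label(0.90), "very strong")
  expect_identical(strength_label(1), "very strong")
  expect_error(strength_label(1.2), "-1, 1")
})

test_that("fit_final_model recovers a planted linear law and is permutation-invariant", {
  # construct spectra so that ND at bands (4, 2) is exactly affine in lcc
  wl <- seq(450, 800, length.out = 5)
  n <- 60
  lcc <- seq(4, 23, length.out = n)
  nd <- 0.1 + 0.03 * lcc
  rj <- rep(0.2, n)
  ri <- rj * (1 + nd) / (1 - nd)
  spectra <- cbind(0.3, rj, 0.4, ri, 0.5)
  cen <- structure(list(cx_nm = wl[4], cy_nm = wl[2], vi = "ND"),
                   class = "centroid_result")
  out <- fit_final_model(spectra, wl, lcc, "ND", cen)
  # planted law: lcc = (nd - 0.1) / 0.03
  expect_equal(out$model$slope, 1 / 0.03, tolerance = 1e-8)
  expect_equal(out$model$intercept, -0.1 / 0.03, tolerance = 1e-8)
  expect_equal(out$fit$r2, 1, tolerance = 1e-10)
  expect_equal(sign(out$model$slope), sign(out$fit$r))

  perm <- sample(n)
  out2 <- fit_final_model(spectra[perm, ], wl, lcc[perm], "ND", cen)
  expect_equal(out2$model$slope, out$model$slope, tolerance = 1e-10)
  expect_equal(out2$model$intercept, out$model$intercept, tolerance = 1e-10)
})
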