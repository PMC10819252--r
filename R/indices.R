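# Two-band vegetation indices. Throughout, lambda_i denotes the first
# (conventionally NIR-side) band and lambda_j the second (shorter) band;
# the band-pair search scans the full ordered grid so no orientation is
# assumed a priori.

#' Supported two-band vegetation-index families
#' @export
VI_KINDS <- c("ND", "SR", "CI")

#' Compute a two-band vegetation index
#'
#' `SR = Ri/Rj`, `ND = (Ri - Rj)/(Ri + Rj)`, `CI = Ri/Rj - 1`. Note that
#' CI is an affine function of SR, so the two carry identical information
#' for linear regression.
#'
#' @param r_i reflectance at the first band (vectorised).
#' @param r_j reflectance at the second band.
#' @param kind `"SR"`, `"ND"` or `"CI"`.
#' @return numeric vector of index values.
#' @export
compute_vi <- function(r_i, r_j, kind = c("ND", "SR", "CI")) {
  kind <- match.arg(kind)
  if (length(r_i) != length(r_j))
    stop("r_i and r_j must have equal length")
  if (any(!is.finite(r_i)) || any(!is.finite(r_j)))
    stop("reflectances must be finite")
  denom <- if (kind == "ND") r_i + r_j else r_j
  zero <- which(denom == 0)
  if (length(zero))
    stop(sprintf("%s undefined: zero denominator at sample index %s", kind,
                 paste(utils::head(zero, 5L), collapse = ", ")))
  switch(kind,
    SR = r_i / r_j,
    ND = (r_i - r_j) / (r_i + r_j),
    CI = r_i / r_j - 1)
}

#' Green normalised difference vegetation index
#'
#' The ND index between a near-infrared band (default 788 nm) and a green
#' band (default 575 nm), computed with nearest-band lookup on the spectrum's
#' axis. For non-negative reflectance the value lies in [-1, 1], positive
#' for vegetation (NIR above green).
#'
#' @param spectrum per-band reflectance.
#' @param wavelengths_nm spectral axis (nm).
#' @param green_nm,nir_nm band-centre targets (nm).
#' @return scalar GNDVI value.
#' @export
gndvi <- function(spectrum, wavelengths_nm, green_nm = 575, nir_nm = 788) {
  if (length(spectrum) != length(wavelengths_nm))
    stop("spectrum and axis differ in length")
  ig <- nearest_band(wavelengths_nm, green_nm)
  ii <- nearest_band(wavelengths_nm, nir_nm)
  compute_vi(spectrum[ii], spectrum[ig], "ND")
}

#' Construct a two-band LCC prediction model
#'
#' A linear map from a two-band vegetation index to leaf chlorophyll
#' content: `LCC = slope * VI + intercept` (µg·cm⁻²).
#'
#' @param vi index family, `"ND"`, `"SR"`, `"CI"` or `"GNDVI"` (GNDVI is ND
#'   at fixed green/NIR bands).
#' @param lambda_i_nm,lambda_j_nm band centres (nm), inside 450-800 nm.
#' @param slope µg·cm⁻² per index unit.
#' @param intercept µg·cm⁻².
#' @param meta provenance list.
#' @return An object of class `prediction_model`.
#' @export
prediction_model <- function(vi, lambda_i_nm, lambda_j_nm, slope, intercept,
                             meta = list()) {
  vi <- match.arg(vi, c(VI_KINDS, "GNDVI"))
  for (b in c(lambda_i_nm, lambda_j_nm))
    if (!is.finite(b) || b < 450 || b > 800)
      stop("model bands must lie inside 450-800 nm; got ", b)
  if (!is.finite(slope) || !is.finite(intercept))
    stop("slope and intercept must be finite")
  structure(
    list(vi = vi, lambda_i_nm = lambda_i_nm, lambda_j_nm = lambda_j_nm,
         slope = slope, intercept = intercept, meta = meta),
    class = "prediction_model"
  )
}

#' @export
print.prediction_model <- function(x, ...) {
  cat(sprintf("<prediction_model> LCC = %.4g * %s(%g, %g) %+.4g ug/cm2\n",
              x$slope, x$vi, x$lambda_i_nm, x$lambda_j_nm, x$intercept))
  invisible(x)
}

#' Predict leaf chlorophyll content from an index value
#'
#' Applies a fitted two-band model. Negative predictions (index values below
#' the model's support) are returned as-is; their positions are attached as
#' the `"flagged_negative"` attribute.
#'
#' @param vi_value index value(s).
#' @param model a `prediction_model`.
#' @return predicted LCC (µg·cm⁻²), with attribute `flagged_negative`.
#' @export
predict_lcc <- function(vi_value, model) {
  stopifnot(inherits(model, "prediction_model"))
  out <- model$slope * vi_value + model$intercept
  attr(out, "flagged_negative") <- which(out < 0)
  out
}

#' Per-pixel chlorophyll map from a cube and a two-band model
#'
#' Computes the model's index per masked pixel and maps it to LCC;
#' background pixels are `NA`.
#'
#' @param cube a reflectance `hypercube` whose axis contains the model bands.
#' @param mask a `leaf_mask`.
#' @param model a `prediction_model`.
#' @return numeric matrix of LCC (µg·cm⁻²), `NA` outside the mask, with
#'   attribute `n_negative` (count of negative predictions).
#' @export
vi_map <- function(cube, mask, model) {
  stopifnot(inherits(cube, "hypercube"), inherits(mask, "leaf_mask"),
            inherits(model, "prediction_model"))
  rng <- range(cube$wavelengths)
  for (b in c(model$lambda_i_nm, model$lambda_j_nm))
    if (b < rng[1L] || b > rng[2L])
      stop(sprintf("model band %g nm outside cube axis [%g, %g] nm",
                   b, rng[1L], rng[2L]))
  ii <- nearest_band(cube$wavelengths, model$lambda_i_nm)
  ij <- nearest_band(cube$wavelengths, model$lambda_j_nm)
  ri <- cube$data[, , ii]
  rj <- cube$data[, , ij]
  kind <- if (model$vi == "GNDVI") "ND" else model$vi
  v <- switch(kind,
    SR = ri / rj,
    ND = (ri - rj) / (ri + rj),
    CI = ri / rj - 1)
  out <- model$slope * v + model$intercept
  out[!mask$mask] <- NA_real_
  attr(out, "n_negative") <- sum(out < 0, na.rm = TRUE)
  out
}

#' Serialize / deserialize a prediction model as JSON
#'
#' @param model a `prediction_model`.
#' @param path JSON file path.
#' @return `path` (write) or the model (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "prediction_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  prediction_model(obj$vi, obj$lambda_i_nm, obj$lambda_j_nm, obj$slope,
                   obj$intercept, meta = as.list(obj$meta))
}
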