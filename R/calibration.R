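#' Fit a Lorentzian profile to an atomic emission line
#'
#' Wavelength calibration of the spectrograph uses narrow atomic emission
#' lines from a Hg-Ar pencil lamp; each line is fitted with a Lorentzian
#' profile `offset + amplitude * gamma^2 / ((lambda - center)^2 + gamma^2)`,
#' whose full width at half maximum (`2 * gamma`) estimates the instrument's
#' spectral resolution.
#'
#' @param intensity per-band intensities (arbitrary units).
#' @param wavelengths_nm spectral axis (nm), same length as `intensity`.
#' @param window_nm full width (nm) of the fit window, centred on the
#'   intensity maximum. The window must contain a single dominant peak and
#'   at least 5 samples.
#' @return An object of class `calibration_line`: list with `center_nm`,
#'   `fwhm_nm`, `center_se_nm` (standard error of the centre from the fit
#'   covariance), `amplitude`, `offset`, and `n_points`.
#' @export
fit_lorentzian_line <- function(intensity, wavelengths_nm, window_nm = 10) {
  validate_axis(wavelengths_nm)
  if (length(intensity) != length(wavelengths_nm))
    stop("intensity and wavelength axis differ in length")
  if (!is.finite(window_nm) || window_nm <= 0)
    stop("window_nm must be a positive scalar")
  peak <- which.max(intensity)
  sel <- abs(wavelengths_nm - wavelengths_nm[peak]) <= window_nm / 2
  if (sum(sel) < 5L)
    stop("fit window contains fewer than 5 samples; widen window_nm")
  x <- wavelengths_nm[sel]
  y <- intensity[sel]

  off0 <- min(y)
  amp0 <- max(y) - off0
  c0 <- x[which.max(y)]
  # half width at half maximum from the data
  half <- off0 + amp0 / 2
  above <- x[y >= half]
  g0 <- max((max(above) - min(above)) / 2, mean(diff(x)))
  start <- list(off = off0, amp = amp0, ctr = c0, gam = g0)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ off + amp * gam^2 / ((x - ctr)^2 + gam^2),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop(sprintf(
        "Lorentzian fit failed (%s); initial guess: offset=%.4g amplitude=%.4g center=%.4g gamma=%.4g",
        conditionMessage(e), off0, amp0, c0, g0))
    }
  )
  co <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc))))
    stop(sprintf(
      "degenerate fit covariance; initial guess: offset=%.4g amplitude=%.4g center=%.4g gamma=%.4g",
      off0, amp0, c0, g0))
  structure(
    list(center_nm = unname(co["ctr"]),
         fwhm_nm = 2 * abs(unname(co["gam"])),
         center_se_nm = sqrt(vc["ctr", "ctr"]),
         amplitude = unname(co["amp"]),
         offset = unname(co["off"]),
         n_points = length(x)),
    class = "calibration_line"
  )
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("<calibration_line> center %.4f +/- %.4f nm, FWHM %.4f nm\n",
              x$center_nm, x$center_se_nm, x$fwhm_nm))
  invisible(x)
}

#' Fit a polynomial pixel-to-wavelength mapping
#'
#' Given detector pixel positions of emission lines with known wavelengths,
#' fits a least-squares polynomial map pixel -> nm.
#'
#' @param pixel_positions numeric vector of line positions (detector pixels).
#' @param known_lines_nm numeric vector of the lines' reference wavelengths.
#' @param degree polynomial degree (default 1, a linear dispersion).
#' @return An object of class `axis_calibration`: list with `coefficients`
#'   (intercept first), `residuals_nm` (per line), `degree`, and a `predict`
#'   usable via [predict.axis_calibration()].
#' @export
calibrate_axis <- function(pixel_positions, known_lines_nm, degree = 1L) {
  if (length(pixel_positions) != length(known_lines_nm))
    stop("pixel_positions and known_lines_nm differ in length")
  if (length(known_lines_nm) <= degree)
    stop(sprintf(
      "underdetermined calibration: %d lines cannot constrain a degree-%d polynomial",
      length(known_lines_nm), degree))
  fit <- stats::lm(known_lines_nm ~ stats::poly(pixel_positions, degree,
                                                raw = TRUE))
  structure(
    list(coefficients = unname(stats::coef(fit)),
         residuals_nm = unname(stats::residuals(fit)),
         degree = as.integer(degree)),
    class = "axis_calibration"
  )
}

#' Map detector pixels to wavelengths with a fitted calibration
#'
#' @param object an `axis_calibration`.
#' @param pixels detector pixel positions to map.
#' @param ... unused.
#' @return wavelengths (nm).
#' @export
predict.axis_calibration <- function(object, pixels, ...) {
  drop(outer(pixels, 0:object$degree, `^`) %*% object$coefficients)
}

#' @export
print.axis_calibration <- function(x, ...) {
  cat(sprintf("<axis_calibration> degree %d, max |residual| %.3g nm\n",
              x$degree, max(abs(x$residuals_nm))))
  invisible(x)
}
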