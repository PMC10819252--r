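#' Validate a spectral axis
#'
#' A spectral axis is a plain numeric vector of band-centre wavelengths in
#' nanometres. It must be finite, strictly increasing and of length >= 2;
#' spacing may be non-uniform but must be positive.
#'
#' @param wavelengths_nm numeric vector of band centres (nm).
#' @return The validated vector, invisibly.
#' @export
validate_axis <- function(wavelengths_nm) {
  if (!is.numeric(wavelengths_nm) || length(wavelengths_nm) < 2L)
    stop("spectral axis must be a numeric vector of length >= 2")
  if (!all(is.finite(wavelengths_nm)))
    stop("spectral axis contains non-finite wavelengths")
  if (any(diff(wavelengths_nm) <= 0))
    stop("spectral axis must be strictly increasing")
  invisible(wavelengths_nm)
}

#' Index of the band nearest to a target wavelength
#'
#' Band lookups are nearest-centre; exact ties are broken toward the shorter
#' wavelength.
#'
#' @param wavelengths_nm spectral axis (nm), strictly increasing.
#' @param target_nm scalar target wavelength (nm). Must lie within the axis
#'   range.
#' @return integer band index.
#' @export
nearest_band <- function(wavelengths_nm, target_nm) {
  validate_axis(wavelengths_nm)
  if (!is.finite(target_nm) || length(target_nm) != 1L)
    stop("target_nm must be a finite scalar")
  rng <- range(wavelengths_nm)
  if (target_nm < rng[1L] || target_nm > rng[2L])
    stop(sprintf("target wavelength %.2f nm outside axis range [%.2f, %.2f] nm",
                 target_nm, rng[1L], rng[2L]))
  # which.min returns the first minimiser; axis is increasing, so an exact
  # tie resolves to the shorter wavelength
  which.min(abs(wavelengths_nm - target_nm))
}
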