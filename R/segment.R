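#' Construct a leaf mask
#'
#' Pairs a boolean vegetation mask with an integer sample-label image
#' (0 = background, k = sample id). Labelled pixels must be a subset of
#' mask-true pixels and every label must be non-empty.
#'
#' @param mask logical matrix.
#' @param labels integer matrix of the same dimensions.
#' @return An object of class `leaf_mask`.
#' @export
leaf_mask <- function(mask, labels = NULL) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("mask must be a logical matrix")
  if (is.null(labels)) {
    labels <- matrix(0L, nrow(mask), ncol(mask))
    labels[mask] <- 1L
  }
  if (!identical(dim(mask), dim(labels)))
    stop("mask and labels must share dimensions")
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (any(labels > 0L & !mask))
    stop("labelled pixels must be a subset of mask-true pixels")
  ids <- sort(unique(labels[labels > 0L]))
  structure(list(mask = mask, labels = labels, sample_ids = ids),
            class = "leaf_mask")
}

#' @export
print.leaf_mask <- function(x, ...) {
  cat(sprintf("<leaf_mask> %d x %d, %d vegetation pixels, %d labelled samples\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), length(x$sample_ids)))
  invisible(x)
}

# relabel a label image so ids follow first occurrence in raster (row-major)
# reading order
.relabel_raster_order <- function(lab) {
  order_seen <- unique(as.vector(t(lab)))
  order_seen <- order_seen[order_seen > 0]
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(order_seen)) out[lab == order_seen[i]] <- i
  out
}

#' Segment leaf pixels by an NDVI threshold
#'
#' Vegetation pixels are those whose normalised difference between a
#' near-infrared and a red band exceeds `threshold` (healthy leaf tissue has
#' high NIR and low red reflectance, so its ND is large, while trays and
#' backgrounds sit near zero). Connected components are labelled in raster
#' order; components smaller than `min_pixels` are dropped.
#'
#' @param cube a reflectance `hypercube`.
#' @param red_nm,nir_nm band-centre targets (nm) for the red and NIR bands
#'   (nearest-band lookup).
#' @param threshold ND cut separating vegetation from background.
#' @param min_pixels minimum component size kept as a sample.
#' @return A `leaf_mask`.
#' @export
segment_leaf <- function(cube, red_nm = 670, nir_nm = 780, threshold = 0.3,
                         min_pixels = 10L) {
  stopifnot(inherits(cube, "hypercube"))
  ir <- nearest_band(cube$wavelengths, red_nm)
  ii <- nearest_band(cube$wavelengths, nir_nm)
  red <- cube$data[, , ir]
  nir <- cube$data[, , ii]
  nd <- (nir - red) / (nir + red)
  mask <- is.finite(nd) & nd > threshold
  if (!any(mask))
    stop(sprintf(
      "segmentation produced an empty mask at ND(%g, %g) > %g; lower the threshold or check calibration",
      nir_nm, red_nm, threshold))
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_pixels)
  lab[!(lab %in% keep)] <- 0L
  lab <- .relabel_raster_order(lab)
  leaf_mask(mask, lab)
}

#' Mean reflectance spectrum of a masked region
#'
#' Reduces a sample region to its per-band mean and standard deviation over
#' pixels. Non-finite (invalid) pixel values are excluded band-wise.
#'
#' @param cube a `hypercube`.
#' @param mask a `leaf_mask`.
#' @param sample_id integer label to average over; `NULL` averages over the
#'   whole mask.
#' @return data.frame with columns `wavelength_nm`, `mean_reflectance`,
#'   `sd_reflectance`, `n_pixels`.
#' @export
mean_spectrum <- function(cube, mask, sample_id = NULL) {
  stopifnot(inherits(cube, "hypercube"), inherits(mask, "leaf_mask"))
  if (!identical(dim(cube$data)[1:2], dim(mask$mask)))
    stop("cube and mask spatial dimensions differ")
  sel <- if (is.null(sample_id)) {
    which(mask$mask)
  } else {
    if (!sample_id %in% mask$sample_ids)
      stop("no such sample id in mask: ", sample_id)
    which(mask$labels == sample_id)
  }
  d <- dim(cube$data)
  m <- matrix(cube$data, d[1L] * d[2L], d[3L])[sel, , drop = FALSE]
  mu <- apply(m, 2L, function(v) mean(v[is.finite(v)]))
  sd_ <- apply(m, 2L, function(v) {
    v <- v[is.finite(v)]
    if (length(v) > 1L) stats::sd(v) else 0
  })
  npx <- apply(m, 2L, function(v) sum(is.finite(v)))
  data.frame(wavelength_nm = cube$wavelengths, mean_reflectance = mu,
             sd_reflectance = sd_, n_pixels = npx)
}

#' Extract per-sample mean spectra from a labelled cube
#'
#' @param cube a `hypercube`.
#' @param mask a `leaf_mask` with labelled samples.
#' @param sample_prefix prefix used to build sample ids (e.g. `"S"` gives
#'   `"S01"`, `"S02"`, ...).
#' @return Long-format data.frame with columns `sample_id`, `wavelength_nm`,
#'   `mean_reflectance`, `sd_reflectance`.
#' @export
extract_spectra <- function(cube, mask, sample_prefix = "S") {
  stopifnot(inherits(mask, "leaf_mask"))
  if (length(mask$sample_ids) == 0L)
    stop("mask contains no labelled samples")
  width <- nchar(as.character(max(mask$sample_ids)))
  out <- lapply(mask$sample_ids, function(k) {
    sp <- mean_spectrum(cube, mask, k)
    data.frame(sample_id = sprintf("%s%0*d", sample_prefix, width, k),
               sp[, c("wavelength_nm", "mean_reflectance", "sd_reflectance")])
  })
  do.call(rbind, out)
}

#' Write / read long-format spectra tables
#'
#' CSV with columns `sample_id`, `wavelength_nm`, `mean_reflectance` and
#' optionally `sd_reflectance`.
#'
#' @param spectra long-format data.frame as from [extract_spectra()].
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_spectra <- function(spectra, path) {
  need <- c("sample_id", "wavelength_nm", "mean_reflectance")
  if (!all(need %in% names(spectra)))
    stop("spectra table must have columns: ", paste(need, collapse = ", "))
  utils::write.csv(spectra, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "wavelength_nm", "mean_reflectance")
  if (!all(need %in% names(df)))
    stop("spectra CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' Reshape a long spectra table to a samples-by-bands matrix
#'
#' @param spectra long-format spectra data.frame.
#' @return list with `spectra` (matrix, rownames = sample ids) and
#'   `wavelengths` (numeric axis).
#' @export
spectra_matrix <- function(spectra) {
  wl <- sort(unique(spectra$wavelength_nm))
  ids <- unique(spectra$sample_id)
  m <- matrix(NA_real_, length(ids), length(wl),
              dimnames = list(ids, NULL))
  iw <- match(spectra$wavelength_nm, wl)
  is <- match(spectra$sample_id, ids)
  m[cbind(is, iw)] <- spectra$mean_reflectance
  if (anyNA(m))
    stop("spectra table is not a complete sample x wavelength grid")
  list(spectra = m, wavelengths = wl)
}
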