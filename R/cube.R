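#' Construct a hyperspectral data cube
#'
#' A `hypercube` holds a 3-D reflectance array indexed (row, col, band)
#' together with its calibrated band-centre wavelength axis (nm) and a
#' free-form provenance list.
#'
#' @param data 3-D numeric array, dimensions (rows, cols, bands).
#' @param wavelengths_nm spectral axis; length must equal `dim(data)[3]`.
#' @param meta named list of provenance entries.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths_nm, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3-D array (row, col, band)")
  validate_axis(wavelengths_nm)
  if (dim(data)[3L] != length(wavelengths_nm))
    stop(sprintf("band count mismatch: data has %d bands, axis has %d",
                 dim(data)[3L], length(wavelengths_nm)))
  structure(
    list(data = data, wavelengths = as.numeric(wavelengths_nm), meta = meta),
    class = "hypercube"
  )
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1L], d[2L], d[3L], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

# ---- ENVI-style header + binary I/O ----------------------------------------

# ENVI dialect: lowercase keys, required "wavelength" array, interleave one of
# bsq/bil/bip, data type 4 (float32) or 5 (float64), byte order 0 (little).

.envi_header_path <- function(path) paste0(path, ".hdr")

.write_envi_header <- function(cube, path, interleave, data_type) {
  d <- dim(cube$data)
  wl <- paste(format(cube$wavelengths, trim = TRUE, digits = 15),
              collapse = ", ")
  lines <- c(
    "ENVI",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = { %s }", wl)
  )
  writeLines(lines, .envi_header_path(path))
}

.parse_envi_header <- function(hdr_path) {
  if (!file.exists(hdr_path))
    stop("ENVI header not found: ", hdr_path)
  raw_lines <- readLines(hdr_path, warn = FALSE)
  # fold multi-line { ... } blocks onto one line before key=value parsing
  joined <- character(0)
  buf <- ""
  open <- FALSE
  for (ln in raw_lines) {
    if (!open) {
      if (grepl("\\{", ln) && !grepl("\\}", ln)) {
        buf <- ln
        open <- TRUE
      } else joined <- c(joined, ln)
    } else {
      buf <- paste(buf, ln)
      if (grepl("\\}", ln)) {
        joined <- c(joined, buf)
        open <- FALSE
      }
    }
  }
  kv <- list()
  for (ln in joined) {
    if (!grepl("=", ln)) next
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- val
  }
  kv
}

.parse_envi_array <- function(val) {
  val <- gsub("[{}]", "", val)
  as.numeric(trimws(strsplit(val, ",")[[1L]]))
}

#' Write a hyperspectral cube to disk
#'
#' Two formats are supported: `envi` (a flat binary file plus a `<path>.hdr`
#' text header, band interleave selectable) and `rds` (a self-describing
#' compressed R container, convenient for fixtures).
#'
#' @param cube a `hypercube`.
#' @param path output file path (the ENVI header is written to `<path>.hdr`).
#' @param format `"envi"` or `"rds"`.
#' @param interleave ENVI band interleave, one of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type ENVI data type code: 5 = float64 (default, lossless),
#'   4 = float32.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("envi", "rds"),
                       interleave = c("bsq", "bil", "bip"), data_type = 5L) {
  stopifnot(inherits(cube, "hypercube"))
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(list(data = cube$data, wavelengths = cube$wavelengths,
                 meta = cube$meta), path)
    return(invisible(path))
  }
  interleave <- match.arg(interleave)
  if (!data_type %in% c(4L, 5L)) stop("data_type must be 4 or 5")
  a <- cube$data
  # canonical (row, col, band) -> on-disk element order (fastest index first)
  v <- switch(interleave,
    bsq = as.vector(aperm(a, c(2L, 1L, 3L))),  # sample, line, band
    bil = as.vector(aperm(a, c(2L, 3L, 1L))),  # sample, band, line
    bip = as.vector(aperm(a, c(3L, 2L, 1L)))   # band, sample, line
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(v, con, size = if (data_type == 5L) 8L else 4L, endian = "little")
  .write_envi_header(cube, path, interleave, data_type)
  invisible(path)
}

#' Read a hyperspectral cube
#'
#' Resolves any supported band interleave to the canonical (row, col, band)
#' layout. A header without wavelength metadata is a hard error: cubes are
#' never returned with a silent index-only axis.
#'
#' @param path cube file path (for ENVI, `<path>.hdr` must exist).
#' @param format `"auto"` (detect by header presence), `"envi"` or `"rds"`.
#' @return A `hypercube`.
#' @export
read_cube <- function(path, format = c("auto", "envi", "rds")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (file.exists(.envi_header_path(path))) "envi" else "rds"
  if (format == "rds") {
    obj <- readRDS(path)
    if (is.null(obj$wavelengths))
      stop("container has no wavelength metadata: ", path)
    return(hypercube(obj$data, obj$wavelengths,
                     if (is.null(obj$meta)) list() else obj$meta))
  }
  kv <- .parse_envi_header(.envi_header_path(path))
  need <- c("samples", "lines", "bands", "interleave", "data type")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    stop("ENVI header missing required keys: ", paste(miss, collapse = ", "))
  if (is.null(kv[["wavelength"]]))
    stop("ENVI header declares no wavelength array: ", path)
  ns <- as.integer(kv[["samples"]])
  nl <- as.integer(kv[["lines"]])
  nb <- as.integer(kv[["bands"]])
  wl <- .parse_envi_array(kv[["wavelength"]])
  if (length(wl) != nb)
    stop(sprintf("header declares %d bands but %d wavelengths", nb, length(wl)))
  dtype <- as.integer(kv[["data type"]])
  if (!dtype %in% c(4L, 5L))
    stop("unsupported ENVI data type: ", dtype)
  size <- if (dtype == 5L) 8L else 4L
  n_expect <- as.numeric(ns) * nl * nb
  fs <- file.info(path)$size
  if (!isTRUE(fs == n_expect * size))
    stop(sprintf(
      "binary length inconsistent with declared dims: %d bytes on disk, %.0f expected",
      fs, n_expect * size))
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n_expect, size = size, endian = "little")
  il <- tolower(kv[["interleave"]])
  a <- switch(il,
    bsq = aperm(array(v, dim = c(ns, nl, nb)), c(2L, 1L, 3L)),
    bil = aperm(array(v, dim = c(ns, nb, nl)), c(3L, 1L, 2L)),
    bip = aperm(array(v, dim = c(nb, ns, nl)), c(3L, 2L, 1L)),
    stop("unsupported interleave: ", il)
  )
  hypercube(a, wl, meta = list(source = path, interleave = il))
}

# ---- reflectance calibration -----------------------------------------------

#' Calibrate raw counts to reflectance with white and dark references
#'
#' Computes `R = (raw - dark) / (white - dark)` element-wise. Pixels where
#' the white reference does not exceed the dark reference are invalid and set
#' to `NaN`; their count is recorded in `meta$n_invalid`. Negative
#' reflectances are clamped to zero; values above 1 (specular glints) are
#' kept but counted in `meta$n_above_one`.
#'
#' @param raw,white,dark `hypercube`s sharing dimensions and axis.
#' @return A calibrated `hypercube`.
#' @export
reflectance_calibrate <- function(raw, white, dark) {
  stopifnot(inherits(raw, "hypercube"), inherits(white, "hypercube"),
            inherits(dark, "hypercube"))
  if (!identical(dim(raw$data), dim(white$data)) ||
      !identical(dim(raw$data), dim(dark$data)))
    stop("raw, white and dark cubes must share dimensions")
  if (!isTRUE(all.equal(raw$wavelengths, white$wavelengths)) ||
      !isTRUE(all.equal(raw$wavelengths, dark$wavelengths)))
    stop("raw, white and dark cubes must share the wavelength axis")
  denom <- white$data - dark$data
  bad <- denom <= 0
  r <- (raw$data - dark$data) / denom
  r[bad] <- NaN
  n_neg <- sum(r < 0, na.rm = TRUE)
  r[!is.nan(r) & r < 0] <- 0
  n_hi <- sum(r > 1, na.rm = TRUE)
  hypercube(r, raw$wavelengths,
            meta = c(raw$meta,
                     list(calibrated = TRUE, n_invalid = sum(bad),
                          n_clamped_negative = n_neg, n_above_one = n_hi)))
}
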