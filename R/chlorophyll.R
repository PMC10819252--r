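# Spectrophotometric chlorophyll arithmetic for DMF leaf-disc extracts.
# Total chlorophyll per unit leaf area is linear in the extract absorbances
# at 647 nm and 664 nm, scaled by extract volume over sampled disc area.

.CHL_A647_COEF <- 20.27
.CHL_A664_COEF <- 7.04

#' Leaf chlorophyll content from extract absorbances
#'
#' Converts spectrophotometric absorbances of a DMF extract at 647 nm and
#' 664 nm into total leaf chlorophyll content per unit leaf area:
#' `LCC = (20.27 * A647 + 7.04 * A664) * volume / (discs * disc_area)`,
#' in µg per cm². The absorbance coefficients are DMF-specific constants;
#' the extraction geometry (volume, number of leaf discs, disc area) is
#' parameterised with 4 mL / 2 discs / 0.82 cm² defaults.
#'
#' @param a647,a664 absorbances at 647 and 664 nm (non-negative, may be
#'   vectors).
#' @param extract_volume_ml extract volume (mL).
#' @param discs number of leaf discs in the extract.
#' @param disc_area_cm2 area of one disc (cm²).
#' @return LCC in µg·cm⁻² (same length as the absorbance vectors).
#' @export
#' @examples
#' lcc_from_absorbance(0.2, 0.4)  # about 16.76 ug/cm2
lcc_from_absorbance <- function(a647, a664, extract_volume_ml = 4,
                                discs = 2L, disc_area_cm2 = 0.82) {
  if (length(a647) != length(a664))
    stop("a647 and a664 must have equal length")
  if (any(!is.finite(a647)) || any(!is.finite(a664)))
    stop("absorbances must be finite")
  if (any(a647 < 0) || any(a664 < 0))
    stop("absorbances must be non-negative")
  if (extract_volume_ml <= 0 || discs < 1 || disc_area_cm2 <= 0)
    stop("extraction geometry must be positive (volume, discs, disc area)")
  (.CHL_A647_COEF * a647 + .CHL_A664_COEF * a664) *
    extract_volume_ml / (discs * disc_area_cm2)
}

#' Absorbance pair consistent with a target chlorophyll content
#'
#' Inverse of [lcc_from_absorbance()] under a fixed A647:A664 ratio. The
#' forward map is one-dimensional, so the inverse is pinned down by the
#' ratio (a generator knob, not a biological claim).
#'
#' @param lcc target LCC (µg·cm⁻², non-negative, may be a vector).
#' @param ratio_647_to_664 fixed ratio A647 / A664 (default 0.4).
#' @inheritParams lcc_from_absorbance
#' @return data.frame with columns `a647`, `a664`.
#' @export
absorbance_from_lcc <- function(lcc, ratio_647_to_664 = 0.4,
                                extract_volume_ml = 4, discs = 2L,
                                disc_area_cm2 = 0.82) {
  if (any(!is.finite(lcc)) || any(lcc < 0))
    stop("lcc must be finite and non-negative")
  if (ratio_647_to_664 <= 0)
    stop("ratio_647_to_664 must be positive")
  geom <- extract_volume_ml / (discs * disc_area_cm2)
  a664 <- lcc / ((.CHL_A647_COEF * ratio_647_to_664 + .CHL_A664_COEF) * geom)
  data.frame(a647 = ratio_647_to_664 * a664, a664 = a664)
}

#' Read / write sample chlorophyll tables
#'
#' CSV with columns `sample_id`, `a647`, `a664`, `lcc_ug_cm2`. Either the
#' absorbances or the LCC column may be omitted; the missing quantity is
#' derived on read (LCC via [lcc_from_absorbance()] with default geometry,
#' absorbances via [absorbance_from_lcc()]).
#'
#' @param path CSV path.
#' @param df data.frame to write.
#' @return data.frame with all four columns (read), or `path` (write).
#' @export
read_lcc_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("chlorophyll CSV must have a sample_id column")
  has_abs <- all(c("a647", "a664") %in% names(df))
  has_lcc <- "lcc_ug_cm2" %in% names(df)
  if (!has_abs && !has_lcc)
    stop("chlorophyll CSV needs either a647+a664 or lcc_ug_cm2")
  if (!has_lcc)
    df$lcc_ug_cm2 <- lcc_from_absorbance(df$a647, df$a664)
  if (!has_abs) {
    ab <- absorbance_from_lcc(df$lcc_ug_cm2)
    df$a647 <- ab$a647
    df$a664 <- ab$a664
  }
  df[, c("sample_id", "a647", "a664", "lcc_ug_cm2")]
}

#' @rdname read_lcc_table
#' @export
write_lcc_table <- function(df, path) {
  if (!"sample_id" %in% names(df))
    stop("chlorophyll table must have a sample_id column")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
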