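#' Hyperspectral cube container
#'
#' A calibrated or raw hyperspectral cube: a 3-axis numeric array indexed
#' (row, column, band) together with its band-center wavelength grid in
#' nanometres. Calibrated cubes hold unitless transmittance/reflectance in
#' \[0, 1\]; raw cubes hold sensor counts.
#'
#' @param values Numeric 3-axis array, dimensions (rows, columns, bands).
#' @param wavelengths Numeric vector of band-center wavelengths in nm;
#'   must be strictly increasing, finite, positive, and match the band axis.
#' @param calibrated Logical; `TRUE` once white/dark calibration has been
#'   applied (values then clipped to \[0, 1\]).
#' @return An object of class `hsi_cube`.
#' @export
hsi_cube <- function(values, wavelengths, calibrated = FALSE) {
  if (!is.array(values) || length(dim(values)) != 3L)
    hsi_abort("`values` must be a 3-axis array (row, column, band)", "shape_error")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(values)[3L])
    hsi_abort(sprintf("wavelength grid has %d entries but cube has %d bands",
                      length(wavelengths), dim(values)[3L]),
              "consistency_error")
  if (any(!is.finite(wavelengths)) || any(wavelengths <= 0))
    hsi_abort("wavelengths must be finite and positive", "consistency_error")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    hsi_abort("wavelengths must be strictly increasing", "consistency_error")
  structure(list(values = values, wavelengths = wavelengths,
                 calibrated = isTRUE(calibrated)),
            class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hsi_cube> %d x %d px, %d bands (%.1f-%.1f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              if (x$calibrated) "calibrated" else "raw"))
  invisible(x)
}

#' @export
dim.hsi_cube <- function(x) dim(x$values)

#' Radiometric calibration with white/dark reference frames
#'
#' Converts raw sensor counts to transmittance/reflectance with the standard
#' flat-field formula `(raw - dark) / (white - dark)`, clipped to \[0, 1\].
#' References may be full cubes matching the raw data, single frames
#' (rows x bands) reused for every column -- the push-broom per-line
#' convention -- or per-band vectors; anything broadcastable onto the cube.
#'
#' @param raw An [hsi_cube()] with `calibrated = FALSE` (a calibrated cube is
#'   accepted and passed through the same arithmetic).
#' @param white,dark Numeric arrays broadcastable to `dim(raw$values)`:
#'   a 3-axis array of the same shape, a (rows x bands) matrix, or a
#'   length-`bands` vector.
#' @param eps Degeneracy guard: any pixel/band where
#'   `white - dark <= eps * diff(range(white))` raises a degenerate-reference
#'   error instead of dividing.
#' @return A calibrated [hsi_cube()].
#' @export
calibrate_reflectance <- function(raw, white, dark, eps = 1e-8) {
  stopifnot(inherits(raw, "hsi_cube"))
  d <- dim(raw$values)
  wf <- broadcast_ref(white, d, "white")
  df <- broadcast_ref(dark, d, "dark")
  denom <- wf - df
  guard <- eps * max(diff(range(wf)), 1e-300)
  if (any(denom <= guard))
    hsi_abort("white and dark references coincide on some pixels/bands",
              "degenerate_reference_error")
  vals <- (raw$values - df) / denom
  vals[vals < 0] <- 0
  vals[vals > 1] <- 1
  hsi_cube(vals, raw$wavelengths, calibrated = TRUE)
}

# Expand a reference frame to the full cube shape.
broadcast_ref <- function(ref, d, what) {
  if (is.array(ref) && length(dim(ref)) == 3L) {
    if (!all(dim(ref) == d))
      hsi_abort(sprintf("%s reference shape does not match cube", what),
                "shape_error")
    return(ref)
  }
  if (is.matrix(ref)) { # rows x bands, replicated across columns
    if (nrow(ref) != d[1] || ncol(ref) != d[3])
      hsi_abort(sprintf("%s reference frame must be rows x bands", what),
                "shape_error")
    return(aperm(array(ref, c(d[1], d[3], d[2])), c(1, 3, 2)))
  }
  if (is.numeric(ref) && length(ref) %in% c(1L, d[3])) { # per-band scalar(s)
    return(aperm(array(rep(ref, length.out = d[3]), c(d[3], d[1], d[2])),
                 c(2, 3, 1)))
  }
  hsi_abort(sprintf("cannot broadcast %s reference to cube shape", what),
            "shape_error")
}

#' Crop a cube to a wavelength window
#'
#' Keeps exactly the bands whose centers satisfy `lo_nm <= center <= hi_nm`
#' (inclusive endpoints), preserving band order, with the wavelength grid
#' cropped in lockstep. Used to restrict analysis to the 400-800 nm window
#' where the visible/near-infrared signal is reliable.
#'
#' @param cube An [hsi_cube()].
#' @param lo_nm,hi_nm Window edges in nm, `lo_nm < hi_nm`.
#' @return The cropped [hsi_cube()].
#' @export
crop_band_window <- function(cube, lo_nm, hi_nm) {
  stopifnot(inherits(cube, "hsi_cube"))
  if (!(lo_nm < hi_nm))
    hsi_abort("`lo_nm` must be smaller than `hi_nm`", "parameter_error")
  keep <- which(cube$wavelengths >= lo_nm & cube$wavelengths <= hi_nm)
  if (length(keep) == 0L)
    hsi_abort("no band centers fall inside the requested window",
              "empty_selection_error")
  hsi_cube(cube$values[, , keep, drop = FALSE], cube$wavelengths[keep],
           calibrated = cube$calibrated)
}

#' Export a cube as a multi-page TIFF
#'
#' One page per band, values clipped to \[0, 1\]; intended for visual
#' inspection, not for round-tripping (use the ENVI writer for that).
#'
#' @param cube An [hsi_cube()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
cube_to_tiff <- function(cube, path) {
  stopifnot(inherits(cube, "hsi_cube"))
  pages <- lapply(seq_len(dim(cube$values)[3]), function(b) {
    m <- cube$values[, , b]
    m[m < 0] <- 0; m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(pages, path)
  invisible(path)
}
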