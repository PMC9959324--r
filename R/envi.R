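#' Read a hyperspectral cube from an ENVI raster
#'
#' Reads the binary raster plus its ASCII `.hdr` companion (found at
#' `<path>.hdr` or with the raster's extension replaced by `.hdr`). All three
#' interleaves (BSQ, BIL, BIP) are normalized to the package's (row, column,
#' band) axis order. Data types 4 (float32) and 5 (float64) and byte order 0
#' (little-endian) are supported. Wavelengths are taken from the header's
#' `wavelength` block; a `calibrated = {true,false}` annotation written by
#' [write_envi_cube()] is honoured.
#'
#' @param path Path to the binary raster file.
#' @return An [hsi_cube()].
#' @export
read_envi_cube <- function(path) {
  hdr_path <- find_envi_header(path)
  h <- parse_envi_header(hdr_path)
  for (k in c("samples", "lines", "bands", "data type"))
    if (is.null(h[[k]]))
      hsi_abort(sprintf("ENVI header is missing required field '%s'", k),
                "format_error")
  W <- as.integer(h$samples); H <- as.integer(h$lines); B <- as.integer(h$bands)
  dtype <- as.integer(h[["data type"]])
  if (!dtype %in% c(4L, 5L))
    hsi_abort(sprintf("unsupported ENVI data type %d (need 4 or 5)", dtype),
              "format_error")
  byte_order <- as.integer(h[["byte order"]] %||% "0")
  if (byte_order != 0L)
    hsi_abort("only byte order 0 (little-endian) is supported", "format_error")
  interleave <- tolower(h$interleave %||% "bsq")
  wl <- h$wavelength
  if (is.null(wl))
    hsi_abort("ENVI header declares no wavelength block", "format_error")
  wl <- as.numeric(strsplit(gsub("[{}\n]", "", wl), ",")[[1]])
  if (length(wl) != B)
    hsi_abort(sprintf("header lists %d wavelengths for %d bands",
                      length(wl), B), "consistency_error")
  n <- as.double(W) * H * B
  size <- if (dtype == 4L) 4L else 8L
  expected <- n * size + as.numeric(h[["header offset"]] %||% "0")
  if (file.size(path) < expected)
    hsi_abort("raster file is shorter than the header declares",
              "consistency_error")
  con <- file(path, "rb")
  on.exit(close(con))
  off <- as.integer(h[["header offset"]] %||% "0")
  if (off > 0) invisible(readBin(con, "raw", off))
  v <- readBin(con, "double", n = n, size = size, endian = "little")
  vals <- switch(interleave,
    bsq = aperm(array(v, c(W, H, B)), c(2, 1, 3)),
    bil = aperm(array(v, c(W, B, H)), c(3, 1, 2)),
    bip = aperm(array(v, c(B, W, H)), c(3, 2, 1)),
    hsi_abort(sprintf("unknown interleave '%s'", interleave), "format_error"))
  hsi_cube(vals, wl,
           calibrated = identical(tolower(h$calibrated %||% "false"), "true"))
}

#' Write a hyperspectral cube as an ENVI raster
#'
#' Writes a BSQ float64 raster plus `<path>.hdr`, recording the wavelength
#' grid and the calibration flag, so that [read_envi_cube()] round-trips the
#' cube bit-identically.
#'
#' @param cube An [hsi_cube()].
#' @param path Output raster path (`<path>.hdr` is written alongside).
#' @return `path`, invisibly.
#' @export
write_envi_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$values)
  con <- file(path, "wb")
  writeBin(as.vector(aperm(cube$values, c(2, 1, 3))), con,
           size = 8, endian = "little")
  close(con)
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("calibrated = %s", if (cube$calibrated) "true" else "false"),
    sprintf("wavelength = { %s }",
            paste(format(cube$wavelengths, digits = 15, trim = TRUE,
                         scientific = FALSE), collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

find_envi_header <- function(path) {
  cands <- c(paste0(path, ".hdr"), sub("\\.[^.]+$", ".hdr", path))
  for (p in cands) if (file.exists(p)) return(p)
  hsi_abort(sprintf("no ENVI header found for '%s'", path), "format_error")
}

# Minimal ENVI header parser: `key = value` lines, `{ ... }` blocks possibly
# spanning several lines, keys case-insensitive.
parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^ENVI", lines[[1]]))
    hsi_abort("file does not start with the ENVI magic line", "format_error")
  txt <- paste(lines[-1], collapse = "\n")
  out <- list()
  pat <- gregexpr("([A-Za-z ][A-Za-z0-9 ]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)",
                  txt, perl = TRUE)[[1]]
  if (pat[1] == -1) hsi_abort("ENVI header has no fields", "format_error")
  starts <- as.integer(pat)
  lens <- attr(pat, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    eq <- regexpr("=", piece, fixed = TRUE)
    key <- tolower(trimws(substr(piece, 1L, eq - 1L)))
    val <- trimws(substr(piece, eq + 1L, nchar(piece)))
    out[[key]] <- val
  }
  out
}
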