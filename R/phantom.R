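#' Phantom scene configuration
#'
#' Study-condition defaults for the synthetic brightfield H&E liver
#' phantom: a desk-scale grid of 30 bands over 400-800 nm, 64 x 64 px sample
#' images, nucleus disks 12-18 px in diameter (the size a 40x setup at
#' 0.55 um/px measures for liver cell nuclei), a blank-glass strip, additive
#' Gaussian band noise, and the 30-case / 60-sample split design (per split:
#' 1 healthy + 9 unhealthy cases, two sample images each).
#'
#' @param height,width Sample image size in px.
#' @param n_bands Number of spectral bands.
#' @param wl_range Wavelength range in nm (band centers evenly spaced,
#'   endpoints included).
#' @param nucleus_diameter Range (min, max) of nucleus disk diameters in px.
#' @param nucleus_density Expected nuclei per 1000 tissue pixels.
#' @param blank_fraction Fraction of image width covered by the blank glass
#'   strip.
#' @param delta Spectral contrast between tumor and normal endmembers
#'   (peak transmittance difference); 0 gives spectrally identical classes.
#' @param noise_sd Additive Gaussian noise SD per band.
#' @param cases_per_split Named counts `c(healthy = , unhealthy = )` of cases
#'   in each of the three splits.
#' @param samples_per_case Sample images captured per case.
#' @param seed Mandatory RNG seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(height = 64, width = 64, n_bands = 30,
                           wl_range = c(400, 800),
                           nucleus_diameter = c(12, 18),
                           nucleus_density = 1.2,
                           blank_fraction = 0.125,
                           delta = 0.25, noise_sd = 0.02,
                           cases_per_split = c(healthy = 1, unhealthy = 9),
                           samples_per_case = 2,
                           seed = 1L) {
  if (is.null(seed)) hsi_abort("a seed is mandatory", "config_error")
  if (blank_fraction < 0 || blank_fraction > 1)
    hsi_abort("blank_fraction must lie in [0, 1]", "config_error")
  if (max(nucleus_diameter) > min(height, width))
    hsi_abort("nucleus diameter exceeds the image", "config_error")
  if (delta < 0) hsi_abort("delta must be non-negative", "parameter_error")
  structure(list(height = height, width = width, n_bands = n_bands,
                 wl_range = wl_range, nucleus_diameter = nucleus_diameter,
                 nucleus_density = nucleus_density,
                 blank_fraction = blank_fraction,
                 delta = delta, noise_sd = noise_sd,
                 cases_per_split = cases_per_split,
                 samples_per_case = samples_per_case,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

phantom_wavelengths <- function(cfg) {
  seq(cfg$wl_range[1], cfg$wl_range[2], length.out = cfg$n_bands)
}

#' Endmember spectral library for the tissue phantom
#'
#' Builds transmittance spectra for the five scene components: blank glass
#' (near-flat, brighter than any tissue at every band) and cell/background
#' endmembers for the tumor and normal classes. Tissue spectra are a smooth
#' baseline minus Gaussian absorption dips centred at 540 nm (the
#' characteristic eosin dip) and 650 nm. The tumor-vs-normal contrast is a
#' narrow bump pair at 525/555 nm scaled by `delta`, with the row space of
#' the Gaussian RGB synthesis matrix projected out: the two classes are
#' near-metamers under [synthesize_rgb()], so only instruments resolving
#' individual bands can tell them apart. This isolates spectral (as opposed
#' to colour or texture) information in downstream comparisons.
#'
#' @param delta Spectral contrast `> 0` (peak transmittance difference
#'   between tumor and normal variants); use [endmember_library_zero()] for
#'   the degenerate negative control.
#' @param wavelengths Band-center grid in nm, within \[400, 800\].
#' @return A list of class `endmember_library`: one numeric spectrum per
#'   component (`glass`, `normal_cell`, `normal_background`, `tumor_cell`,
#'   `tumor_background`), plus the grid and the contrast vector.
#' @export
endmember_library <- function(delta, wavelengths) {
  if (delta <= 0)
    hsi_abort("delta must be positive (see endmember_library_zero)",
              "parameter_error")
  build_endmembers(delta, wavelengths)
}

#' Degenerate endmember library (negative control)
#'
#' Identical to [endmember_library()] with the class contrast removed:
#' tumor and normal endmembers coincide, so no classifier can separate the
#' classes spectrally.
#'
#' @inheritParams endmember_library
#' @return An `endmember_library` with zero contrast.
#' @export
endmember_library_zero <- function(wavelengths) {
  build_endmembers(0, wavelengths)
}

build_endmembers <- function(delta, wavelengths) {
  wl <- as.numeric(wavelengths)
  if (min(wl) < 400 || max(wl) > 800)
    hsi_abort("band grid must lie within [400, 800] nm", "parameter_error")
  dip <- function(mu, sdv) exp(-(wl - mu)^2 / (2 * sdv^2))
  slope <- (wl - 400) / 400
  glass <- 0.95 - 0.01 * slope
  cell <- 0.48 + 0.05 * slope - 0.17 * dip(540, 18) - 0.10 * dip(650, 16)
  background <- 0.66 + 0.04 * slope - 0.12 * dip(540, 18) - 0.07 * dip(650, 16)
  # Class contrast: a band-alternating component under a smooth envelope
  # that vanishes at both window edges, with the row space of the Gaussian
  # RGB synthesis matrix projected out. Alternation makes the per-band
  # contrast survive constant-stride band sampling in proportion to the
  # number of retained bands, while staying invisible to the smooth RGB
  # windows (near-metamer); the zero-contrast edges mean a single retained
  # band at 400 nm carries no class signal at all.
  env <- sin(pi * (wl - 400) / 400)^2
  u0 <- (-1)^(seq_along(wl) - 1) * env
  Wm <- rgb_weights(wl)
  P <- t(Wm) %*% solve(Wm %*% t(Wm)) %*% Wm
  u <- as.numeric(u0 - P %*% u0)
  u <- u / max(abs(u))
  d <- delta * u
  structure(list(
    glass = glass,
    normal_cell = cell - d / 2,
    normal_background = background - d / 2,
    tumor_cell = cell + d / 2,
    tumor_background = background + d / 2,
    wavelengths = wl, contrast = d),
    class = "endmember_library")
}

# Component codes recorded in phantom masks.
PHANTOM_COMPONENTS <- c(glass = 0L, normal_background = 1L, normal_cell = 2L,
                        tumor_background = 3L, tumor_cell = 4L)

#' Render one synthetic tissue sample image
#'
#' Paints a background-tissue canvas, adds non-overlapping nucleus disks
#' with diameters drawn uniformly from the configured range, reserves a
#' blank glass strip on one side, assigns every pixel its component
#' endmember spectrum plus band-wise Gaussian noise, and clips to (0, 1\].
#'
#' @param cfg A [phantom_config()].
#' @param label `"healthy"` or `"unhealthy"` (selects normal vs tumor
#'   endmembers).
#' @param case_id Case identifier stamped on the output.
#' @param seed Optional seed; when given the render is bit-reproducible.
#' @param endmembers Optional pre-built [endmember_library()] (defaults to
#'   the library implied by `cfg`).
#' @return `list(cube = <hsi_cube>, mask = <H x W integer matrix>,
#'   case_id, label)`; mask codes follow `glass = 0`,
#'   `normal_background = 1`, `normal_cell = 2`, `tumor_background = 3`,
#'   `tumor_cell = 4`.
#' @export
render_tissue_cube <- function(cfg, label = c("unhealthy", "healthy"),
                               case_id = "case", seed = NULL,
                               endmembers = NULL) {
  label <- match.arg(label)
  if (!is.null(seed)) set.seed(seed)
  wl <- phantom_wavelengths(cfg)
  em <- endmembers %||%
    (if (cfg$delta > 0) endmember_library(cfg$delta, wl)
     else endmember_library_zero(wl))
  H <- cfg$height; W <- cfg$width
  tumor <- label == "unhealthy"
  bg_code <- if (tumor) PHANTOM_COMPONENTS[["tumor_background"]] else
    PHANTOM_COMPONENTS[["normal_background"]]
  cell_code <- if (tumor) PHANTOM_COMPONENTS[["tumor_cell"]] else
    PHANTOM_COMPONENTS[["normal_cell"]]

  mask <- matrix(bg_code, H, W)
  strip <- round(cfg$blank_fraction * W)
  if (strip > 0) {
    side <- sample(c("left", "right"), 1L)
    cols <- if (side == "left") seq_len(strip) else (W - strip + 1L):W
    mask[, cols] <- PHANTOM_COMPONENTS[["glass"]]
  } else {
    cols <- integer(0)
  }

  # nucleus disks: non-overlapping, fully inside the tissue area
  tissue_cols <- setdiff(seq_len(W), cols)
  n_tissue <- H * length(tissue_cols)
  n_nuclei <- stats::rpois(1L, cfg$nucleus_density * n_tissue / 1000)
  placed <- matrix(numeric(0), 0, 3) # row, col, radius
  tries <- 0L
  while (nrow(placed) < n_nuclei && tries < 50L * max(n_nuclei, 1L)) {
    tries <- tries + 1L
    r <- runif(1, cfg$nucleus_diameter[1], cfg$nucleus_diameter[2]) / 2
    if (2 * r > H - 2 || length(tissue_cols) < 2 * r + 2) break
    cy <- runif(1, r + 1, H - r)
    cx_lo <- min(tissue_cols) + r
    cx_hi <- max(tissue_cols) - r
    if (cx_hi <= cx_lo) break
    cx <- runif(1, cx_lo, cx_hi)
    if (nrow(placed) > 0 &&
        any((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2 <
            (placed[, 3] + r + 1)^2)) next
    placed <- rbind(placed, c(cy, cx, r))
  }
  if (nrow(placed) > 0) {
    rows <- matrix(seq_len(H), H, W)
    colsm <- matrix(seq_len(W), H, W, byrow = TRUE)
    for (i in seq_len(nrow(placed))) {
      inside <- (rows - placed[i, 1])^2 + (colsm - placed[i, 2])^2 <=
        placed[i, 3]^2
      mask[inside] <- cell_code
    }
  }

  spectra <- rbind(em$glass,
                   em$normal_background, em$normal_cell,
                   em$tumor_background, em$tumor_cell)
  vals <- spectra[as.vector(mask) + 1L, , drop = FALSE]
  vals <- vals + rnorm(length(vals), sd = cfg$noise_sd)
  vals[vals <= 0] <- 1e-6
  vals[vals > 1] <- 1
  cube <- hsi_cube(array(vals, c(H, W, cfg$n_bands)), wl, calibrated = TRUE)
  list(cube = cube, mask = mask, case_id = case_id, label = label)
}

#' Generate a complete phantom dataset
#'
#' Emits the full case/sample layout: for each of the three splits
#' (train, val, test), `cases_per_split` healthy and unhealthy cases with
#' `samples_per_case` images each. The default configuration yields 60
#' sample cubes over 30 cases with 2 healthy + 18 unhealthy samples per
#' split, and split assignment is by case, so no case appears in two
#' splits.
#'
#' @param cfg A [phantom_config()].
#' @return An object of class `phantom_dataset`: `list(samples = <list>,
#'   config = cfg)`, each sample holding `cube`, `mask`, `case_id`, `label`,
#'   and `split`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(cfg$seed)
  wl <- phantom_wavelengths(cfg)
  em <- if (cfg$delta > 0) endmember_library(cfg$delta, wl)
        else endmember_library_zero(wl)
  splits <- c("train", "val", "test")
  samples <- list()
  case_no <- 0L
  for (sp in splits) {
    for (lab in c("healthy", "unhealthy")) {
      n_cases <- cfg$cases_per_split[[lab]]
      for (ci in seq_len(n_cases)) {
        case_no <- case_no + 1L
        case_id <- sprintf("case%02d", case_no)
        for (si in seq_len(cfg$samples_per_case)) {
          seed_i <- sample.int(.Machine$integer.max - 1L, 1L)
          rec <- render_tissue_cube(cfg, label = lab, case_id = case_id,
                                    seed = seed_i, endmembers = em)
          rec$split <- sp
          samples[[length(samples) + 1L]] <- rec
        }
      }
    }
  }
  structure(list(samples = samples, config = cfg),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  labs <- vapply(x$samples, `[[`, "", "label")
  cat(sprintf(
    "<phantom_dataset> %d samples (%d healthy / %d unhealthy), %d cases\n",
    length(x$samples), sum(labs == "healthy"), sum(labs == "unhealthy"),
    length(unique(vapply(x$samples, `[[`, "", "case_id")))))
  invisible(x)
}

#' Write a phantom dataset to disk (ENVI cubes + CSV manifest)
#'
#' @param dataset A `phantom_dataset`.
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dataset$samples), function(i) {
    s <- dataset$samples[[i]]
    stem <- sprintf("%s_s%02d", s$case_id, i)
    cube_path <- file.path(dir, paste0(stem, ".dat"))
    write_envi_cube(s$cube, cube_path)
    mask_cube <- hsi_cube(array(as.numeric(s$mask), c(dim(s$mask), 1L)),
                          dataset$config$wl_range[1], calibrated = FALSE)
    write_envi_cube(mask_cube, file.path(dir, paste0(stem, "_mask.dat")))
    data.frame(case_id = s$case_id, label = s$label, split = s$split,
               path = cube_path)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
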