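#' Tile a cube into non-overlapping S x S patches
#'
#' Tiles the spatial plane with a stride-`S` grid anchored at the top-left
#' corner; trailing remainder rows/columns are discarded, so
#' `floor(H/S) * floor(W/S)` patches are returned in row-major order. Each
#' patch carries its source origin, case identifier, class label, and the
#' wavelength grid of its bands.
#'
#' @param cube An [hsi_cube()].
#' @param S Patch side length in pixels.
#' @param case_id Opaque case (patient) identifier attached to every patch.
#' @param label Class label, `"healthy"` or `"unhealthy"`.
#' @return A list of `hsi_patch` objects.
#' @export
extract_patches <- function(cube, S, case_id = NA_character_,
                            label = NA_character_) {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$values)
  S <- as.integer(S)
  if (S < 1L || S > d[1] || S > d[2])
    hsi_abort(sprintf("patch size %d does not fit a %d x %d image",
                      S, d[1], d[2]), "size_error")
  nr <- d[1] %/% S
  nc <- d[2] %/% S
  patches <- vector("list", nr * nc)
  k <- 1L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      r0 <- (i - 1L) * S
      c0 <- (j - 1L) * S
      patches[[k]] <- structure(
        list(values = cube$values[(r0 + 1L):(r0 + S),
                                  (c0 + 1L):(c0 + S), , drop = FALSE],
             origin = c(row = r0, col = c0),
             case_id = case_id, label = label,
             wavelengths = cube$wavelengths),
        class = "hsi_patch")
      k <- k + 1L
    }
  }
  patches
}

#' @export
print.hsi_patch <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hsi_patch> %dx%d px, %d bands, origin (%d,%d), case %s [%s]\n",
              d[1], d[2], d[3], x$origin[1], x$origin[2],
              x$case_id, x$label))
  invisible(x)
}

#' Blank-glass threshold for an image
#'
#' Unstained glass transmits brightly while stained tissue absorbs, so the
#' band-averaged intensity histogram of a calibrated slide image is bimodal.
#' This computes the two-class (Otsu) threshold separating the glass and
#' tissue modes on the band-averaged image.
#'
#' @param cube A calibrated [hsi_cube()].
#' @return Threshold on band-averaged transmittance; pixels above it count
#'   as blank.
#' @export
blank_threshold <- function(cube) {
  stopifnot(inherits(cube, "hsi_cube"))
  m <- rowMeans(cube$values, dims = 2L)
  EBImage::otsu(m, range = c(0, 1))
}

#' Fraction of blank (glass) pixels in a patch
#'
#' @param patch An `hsi_patch` (or bare 3-axis array) with calibrated values.
#' @param threshold Band-averaged transmittance above which a pixel counts as
#'   blank; typically from [blank_threshold()] on the source image.
#' @return Fraction in \[0, 1\].
#' @export
blank_fraction <- function(patch, threshold) {
  v <- if (inherits(patch, "hsi_patch")) patch$values else patch
  m <- rowMeans(v, dims = 2L)
  mean(m > threshold)
}

#' Remove mostly-blank patches
#'
#' Drops every patch whose blank fraction strictly exceeds `max_blank`
#' (a patch with exactly 50% blank area is kept). Order of kept patches is
#' preserved.
#'
#' @param patches List of `hsi_patch` objects.
#' @param threshold Blank threshold, see [blank_fraction()].
#' @param max_blank Maximum tolerated blank fraction (default 0.5).
#' @return `list(kept = <patches>, removed_count = <int>, kept_idx = <int>)`.
#' @export
filter_blank_patches <- function(patches, threshold, max_blank = 0.5) {
  fr <- vapply(patches, blank_fraction, numeric(1), threshold = threshold)
  keep <- fr <= max_blank
  list(kept = patches[keep], removed_count = sum(!keep),
       kept_idx = which(keep))
}

#' Constant-stride band sampling
#'
#' Reduces the spectral axis by keeping bands at indices
#' `0, s, 2s, ..., (k-1)s` (0-based) with stride `s = floor(B/k)`; the
#' wavelength grid follows in lockstep. With 270 bands and `k = 90` this
#' keeps indices 0, 3, ..., 267.
#'
#' @param x An [hsi_cube()] or `hsi_patch`.
#' @param k Target band count, `1 <= k <= B`.
#' @return Object of the same class with `k` bands.
#' @export
sample_bands <- function(x, k) {
  B <- dim_bands(x)
  k <- as.integer(k)
  if (k < 1L || k > B)
    hsi_abort(sprintf("cannot sample %d bands from %d", k, B),
              "selection_error")
  stride <- B %/% k
  idx <- 1L + (seq_len(k) - 1L) * stride
  select_bands(x, idx)
}

dim_bands <- function(x) {
  v <- if (inherits(x, "hsi_patch") || inherits(x, "hsi_cube")) x$values else x
  dim(v)[3L]
}

select_bands <- function(x, idx) {
  if (inherits(x, "hsi_cube"))
    return(hsi_cube(x$values[, , idx, drop = FALSE], x$wavelengths[idx],
                    calibrated = x$calibrated))
  if (inherits(x, "hsi_patch")) {
    x$values <- x$values[, , idx, drop = FALSE]
    x$wavelengths <- x$wavelengths[idx]
    return(x)
  }
  x[, , idx, drop = FALSE]
}

#' Fit an incremental PCA over pixel spectra
#'
#' Treats every pixel of the supplied training images/patches as one
#' length-B spectral observation, mean-centres, and fits principal
#' components incrementally in fixed-size chunks (default 4096 spectra) via
#' a rank-update SVD, so arbitrarily many training pixels can be digested at
#' a bounded memory cost. Components are retained while their
#' explained-variance ratio stays at or above `variance_threshold`, or
#' exactly `n_components` when that is given. Fit on training-split pixels
#' only: the returned model is applied, never refitted, on validation/test
#' data.
#'
#' @param x A matrix of spectra (rows = observations), an [hsi_cube()], an
#'   `hsi_patch`, or a list of cubes/patches pooled together.
#' @param n_components Exact number of components to keep (overrides the
#'   variance threshold).
#' @param variance_threshold Keep components with explained-variance ratio
#'   `>=` this value (default 0.001, i.e. 0.1%).
#' @param chunk_size Spectra per incremental update.
#' @return An object of class `hsi_pca` with fields `mean`, `components`
#'   (k x B, orthonormal rows), `explained_variance_ratio` (non-increasing),
#'   `n_obs`, and `wavelengths` when available.
#' @export
fit_pca <- function(x, n_components = NULL, variance_threshold = 0.001,
                    chunk_size = 4096L) {
  X <- pool_spectra(x)
  if (nrow(X$mat) < 2L)
    hsi_abort("need at least 2 pixel spectra to fit a PCA", "rank_error")
  B <- ncol(X$mat)
  if (!is.null(n_components) && n_components > min(nrow(X$mat) - 1L, B))
    hsi_abort("fewer observations than requested components", "rank_error")
  if (is.null(n_components) &&
      !(variance_threshold > 0 && variance_threshold < 1))
    hsi_abort("variance_threshold must lie in (0, 1)", "parameter_error")

  st <- list(n = 0, mean = numeric(B), sumsq = numeric(B),
             sv = NULL, V = NULL) # sv: singular values, V: B x k basis
  idx <- seq_len(nrow(X$mat))
  for (start in seq(1L, nrow(X$mat), by = chunk_size)) {
    chunk <- X$mat[idx[start:min(start + chunk_size - 1L, nrow(X$mat))], ,
                   drop = FALSE]
    st <- ipca_update(st, chunk)
  }
  total_var <- sum(st$sumsq) / (st$n - 1)
  ev <- st$sv^2 / (st$n - 1)
  ratio <- ev / total_var
  k <- if (!is.null(n_components)) as.integer(n_components)
       else max(1L, sum(ratio >= variance_threshold))
  structure(list(mean = st$mean,
                 components = t(st$V[, seq_len(k), drop = FALSE]),
                 explained_variance_ratio = ratio[seq_len(k)],
                 all_ratios = ratio,
                 n_obs = st$n,
                 wavelengths = X$wavelengths),
            class = "hsi_pca")
}

# One incremental update: fold a new chunk into the running mean and the
# rank-limited SVD, with the mean-shift correction row.
ipca_update <- function(st, chunk) {
  m <- nrow(chunk)
  cm <- colMeans(chunk)
  n_new <- st$n + m
  mean_new <- (st$n * st$mean + m * cm) / n_new
  st$sumsq <- st$sumsq + colSums(sweep(chunk, 2L, cm)^2) +
    st$n * m / n_new * (st$mean - cm)^2
  Xc <- sweep(chunk, 2L, cm)
  if (st$n == 0) {
    M <- Xc
  } else {
    corr <- sqrt(st$n * m / n_new) * (st$mean - cm)
    M <- rbind(st$sv * t(st$V), Xc, corr)
  }
  sv <- svd(M)
  # deterministic sign: largest-|.| coefficient of each component positive
  for (j in seq_len(ncol(sv$v))) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) sv$v[, j] <- -sv$v[, j]
  }
  keep <- seq_len(min(ncol(chunk), length(sv$d)))
  st$sv <- sv$d[keep]
  st$V <- sv$v[, keep, drop = FALSE]
  st$n <- n_new
  st$mean <- mean_new
  st
}

pool_spectra <- function(x) {
  to_mat <- function(v) {
    d <- dim(v)
    matrix(v, nrow = d[1] * d[2], ncol = d[3])
  }
  if (is.matrix(x)) return(list(mat = x, wavelengths = NULL))
  if (inherits(x, "hsi_cube") || inherits(x, "hsi_patch"))
    return(list(mat = to_mat(x$values), wavelengths = x$wavelengths))
  if (is.list(x)) {
    mats <- lapply(x, function(e) {
      if (inherits(e, "hsi_cube") || inherits(e, "hsi_patch")) to_mat(e$values)
      else if (is.array(e) && length(dim(e)) == 3L) to_mat(e)
      else hsi_abort("cannot pool spectra from this element", "shape_error")
    })
    wl <- NULL
    for (e in x) if (!is.null(e$wavelengths)) { wl <- e$wavelengths; break }
    return(list(mat = do.call(rbind, mats), wavelengths = wl))
  }
  hsi_abort("unsupported input for spectral pooling", "shape_error")
}

#' Component retention by variance threshold
#'
#' The selection rule used by [fit_pca()] when no exact component count is
#' given: keep every component whose explained-variance ratio is `>=` the
#' threshold (at least one).
#'
#' @param ratios Non-increasing explained-variance ratios.
#' @param threshold Retention threshold (0.001 keeps ratios of 0.1% or more).
#' @return Number of components to keep.
#' @export
select_by_variance <- function(ratios, threshold) {
  if (!(threshold > 0 && threshold < 1))
    hsi_abort("threshold must lie in (0, 1)", "parameter_error")
  max(1L, sum(ratios >= threshold))
}

#' Project a patch or cube onto fitted principal components
#'
#' Each pixel spectrum is mean-centred with the model's training mean and
#' projected onto the retained components; the spatial layout is unchanged
#' and the band axis becomes `n_components` pseudo-bands.
#'
#' @param model An `hsi_pca` from [fit_pca()].
#' @param x An [hsi_cube()], `hsi_patch`, or 3-axis array with B bands.
#' @return Same class as `x` with `n_components` pseudo-bands; pseudo-band
#'   "wavelengths" are the component indices (the grid is no longer
#'   physical).
#' @export
apply_pca <- function(model, x) {
  stopifnot(inherits(model, "hsi_pca"))
  v <- if (inherits(x, "hsi_patch") || inherits(x, "hsi_cube")) x$values else x
  d <- dim(v)
  if (d[3] != length(model$mean))
    hsi_abort(sprintf("patch has %d bands but the PCA was fitted on %d",
                      d[3], length(model$mean)), "shape_error")
  scores <- sweep(matrix(v, d[1] * d[2], d[3]), 2L, model$mean) %*%
    t(model$components)
  out <- array(scores, c(d[1], d[2], nrow(model$components)))
  if (inherits(x, "hsi_patch")) {
    x$values <- out
    x$wavelengths <- seq_len(nrow(model$components))
    return(x)
  }
  if (inherits(x, "hsi_cube")) {
    return(structure(list(values = out,
                          wavelengths = seq_len(nrow(model$components)),
                          calibrated = x$calibrated),
                     class = "hsi_cube"))
  }
  out
}

#' Gaussian RGB channel weights on a wavelength grid
#'
#' Channel weights `w_c(lambda) ~ exp(-(lambda - mu_c)^2 / (2 sd^2))` with
#' means 630/540/480 nm (R/G/B) and a 25 nm standard deviation, normalized
#' to unit sum per channel over the available grid so a spectrally flat
#' pixel maps to itself.
#'
#' @param wavelengths Band-center grid in nm.
#' @param means Channel means in nm (R, G, B).
#' @param sd Channel standard deviation in nm.
#' @return A 3 x B matrix with rows summing to 1 (rownames R, G, B).
#' @export
rgb_weights <- function(wavelengths, means = c(630, 540, 480), sd = 25) {
  if (sd <= 0) hsi_abort("rgb sd must be positive", "parameter_error")
  W <- t(vapply(means, function(mu) {
    if (min(abs(wavelengths - mu)) > 3 * sd)
      warning(sprintf(
        "wavelength grid does not reach %g +/- 3 sd; channel computed over available support",
        mu))
    w <- exp(-(wavelengths - mu)^2 / (2 * sd^2))
    w / sum(w)
  }, numeric(length(wavelengths))))
  rownames(W) <- c("R", "G", "B")
  W
}

#' Synthesize an RGB representation from a hyperspectral cube or patch
#'
#' Each channel is the weighted average of the spectrum under a Gaussian
#' window ([rgb_weights()]): the standard three-band rendering of a
#' visible-range cube for display and for the RGB-input baseline model.
#'
#' @param x An [hsi_cube()] or `hsi_patch`.
#' @param means,sd Passed to [rgb_weights()].
#' @return Same class as `x` with 3 bands (nominal centers 630/540/480 nm,
#'   reordered increasing for the cube container).
#' @export
synthesize_rgb <- function(x, means = c(630, 540, 480), sd = 25) {
  v <- if (inherits(x, "hsi_patch") || inherits(x, "hsi_cube")) x$values else x
  d <- dim(v)
  wl <- if (is.null(x$wavelengths)) NULL else x$wavelengths
  if (is.null(wl)) hsi_abort("input carries no wavelength grid", "shape_error")
  Wm <- rgb_weights(wl, means, sd)
  flat <- matrix(v, d[1] * d[2], d[3]) %*% t(Wm)  # columns R, G, B
  # store blue-to-red so the band axis keeps an increasing wavelength grid
  out <- array(flat[, 3:1], c(d[1], d[2], 3L))
  new_wl <- sort(means)
  if (inherits(x, "hsi_patch")) {
    x$values <- out
    x$wavelengths <- new_wl
    return(x)
  }
  if (inherits(x, "hsi_cube"))
    return(hsi_cube(out, new_wl, calibrated = x$calibrated))
  out
}

#' Persist patches as ENVI sub-cubes
#'
#' Writes each patch as its own ENVI raster (named by case, label, and
#' origin) plus a manifest CSV tying the files back to their source
#' coordinates.
#'
#' @param patches List of `hsi_patch` objects.
#' @param dir Output directory (created if needed).
#' @param source Source image identifier recorded in the manifest.
#' @return The manifest data frame, invisibly.
#' @export
write_patches <- function(patches, dir, source = NA_character_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(patches, function(p) {
    stem <- sprintf("%s_%s_r%04d_c%04d", p$case_id, p$label,
                    p$origin[[1]], p$origin[[2]])
    path <- file.path(dir, paste0(stem, ".dat"))
    write_envi_cube(hsi_cube(p$values, p$wavelengths, calibrated = TRUE),
                    path)
    data.frame(case_id = as.character(p$case_id),
               label = as.character(p$label), source = source,
               origin_row = p$origin[[1]], origin_col = p$origin[[2]],
               S = dim(p$values)[1], path = path)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "patches.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Write a patch manifest as CSV
#'
#' Records one row per patch: case, label, source file, origin, patch size,
#' and whether the blank filter kept it.
#'
#' @param patches List of `hsi_patch` objects.
#' @param kept_idx Indices of patches kept by [filter_blank_patches()].
#' @param source Source image identifier/path recorded for every patch.
#' @param path Output CSV path.
#' @return The manifest data frame, invisibly.
#' @export
write_patch_manifest <- function(patches, kept_idx, source, path) {
  df <- data.frame(
    case_id = vapply(patches, function(p) as.character(p$case_id), ""),
    label = vapply(patches, function(p) as.character(p$label), ""),
    source = source,
    origin_row = vapply(patches, function(p) p$origin[[1]], 0),
    origin_col = vapply(patches, function(p) p$origin[[2]], 0),
    S = vapply(patches, function(p) dim(p$values)[1], 0),
    kept = seq_along(patches) %in% kept_idx)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
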