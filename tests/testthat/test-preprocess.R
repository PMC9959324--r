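test_that("tiling yields floor(H/S)*floor(W/S) patches in row-major order", {
  big <- hsi_cube(array(0.3, c(1000, 2000, 2)), wl_grid(2))
  ps <- extract_patches(big, 100, "caseA", "unhealthy")
  expect_length(ps, 200)
  expect_equal(ps[[1]]$origin, c(row = 0, col = 0))
  expect_equal(ps[[2]]$origin, c(row = 0, col = 100)) # row-major
  expect_equal(ps[[21]]$origin, c(row = 100, col = 0))

  sq <- hsi_cube(array(0.3, c(250, 250, 2)), wl_grid(2))
  ps2 <- extract_patches(sq, 100)
  # brute-force tiling enumeration: remainder discarded
  expected <- expand.grid(row = c(0, 100), col = c(0, 100))
  expect_length(ps2, 4)
  origins <- do.call(rbind, lapply(ps2, function(p) p$origin))
  expect_setequal(paste(origins[, 1], origins[, 2]),
                  paste(expected$row, expected$col))
})

test_that("tiling is a partition of disjoint in-bounds footprints", {
  cube <- toy_cube(13, 11, 2)
  ps <- extract_patches(cube, 4)
  cover <- matrix(0L, 13, 11)
  for (p in ps) {
    rows <- (p$origin[1] + 1):(p$origin[1] + 4)
    cols <- (p$origin[2] + 1):(p$origin[2] + 4)
    cover[rows, cols] <- cover[rows, cols] + 1L
  }
  expect_true(all(cover <= 1L)) # disjoint
  expect_equal(sum(cover), length(ps) * 16)
})

test_that("patch size equal to the image gives one patch, larger errors", {
  cube <- toy_cube(8, 8, 2)
  ps <- extract_patches(cube, 8)
  expect_length(ps, 1)
  expect_equal(ps[[1]]$origin, c(row = 0, col = 0))
  expect_error(extract_patches(cube, 9), class = "hsicnn_size_error")
})

test_that("blank fraction separates glass from tissue endmembers", {
  thr <- 0.75
  glass <- flat_patch(8, 0.95)
  tissue <- flat_patch(8, 0.4)
  expect_equal(blank_fraction(glass, thr), 1)
  expect_equal(blank_fraction(tissue, thr), 0)
  half <- glass
  half$values[, 1:4, ] <- 0.4
  expect_equal(blank_fraction(half, thr), 0.5)
})

test_that("the blank filter removes strictly-more-than-half-blank patches", {
  thr <- 0.75
  mostly_blank <- flat_patch(8, 0.95)
  mostly_blank$values[, 1:3, ] <- 0.4 # 5/8 blank
  exactly_half <- flat_patch(8, 0.95)
  exactly_half$values[, 1:4, ] <- 0.4
  clean <- flat_patch(8, 0.4)
  res <- filter_blank_patches(list(mostly_blank, exactly_half, clean), thr)
  expect_equal(res$removed_count, 1)
  expect_equal(res$kept_idx, c(2L, 3L)) # exactly 50% kept, order preserved
})

test_that("a stricter blank limit removes a superset of patches", {
  set.seed(3)
  thr <- 0.75
  patches <- lapply(runif(30), function(f) {
    p <- flat_patch(10, 0.4)
    plane <- matrix(0.4, 10, 10)
    plane[seq_len(round(f * 100))] <- 0.95
    p$values <- array(rep(plane, 4), c(10, 10, 4))
    p
  })
  kept_loose <- filter_blank_patches(patches, thr, max_blank = 0.6)$kept_idx
  kept_strict <- filter_blank_patches(patches, thr, max_blank = 0.3)$kept_idx
  expect_true(all(kept_strict %in% kept_loose))
})

test_that("Otsu blank threshold lands between tissue and glass modes", {
  set.seed(4)
  v <- array(c(runif(3000, 0.3, 0.5), runif(1000, 0.9, 1)), c(40, 100, 1))
  cube <- hsi_cube(v, 500, calibrated = TRUE)
  thr <- blank_threshold(cube)
  expect_gt(thr, 0.5)
  expect_lt(thr, 0.9)
})

test_that("constant-stride band sampling picks the enumerated indices", {
  cube <- toy_cube(2, 2, 270, wl = wl_grid(270))
  s90 <- sample_bands(cube, 90)
  # stride 3, 0-based indices 0, 3, ..., 267
  expect_equal(s90$wavelengths, cube$wavelengths[1 + 3 * (0:89)])
  s10 <- sample_bands(cube, 10)
  expect_equal(s10$wavelengths, cube$wavelengths[1 + 27 * (0:9)])
  expect_equal(length(s10$wavelengths), 10)
  ident <- sample_bands(cube, 270)
  expect_identical(ident$values, cube$values)
  expect_error(sample_bands(cube, 271), class = "hsicnn_selection_error")
})

test_that("sampling preserves values in lockstep with wavelengths", {
  cube <- toy_cube(3, 3, 12)
  s4 <- sample_bands(cube, 4)
  expect_identical(s4$values, cube$values[, , c(1, 4, 7, 10)])
})

test_that("PCA on collinear spectra concentrates all variance on axis one", {
  set.seed(5)
  t_ <- runif(300)
  X <- outer(t_, c(1, 2, 3, 4)) + matrix(0.5, 300, 4)
  m <- fit_pca(X, n_components = 2, chunk_size = 64)
  expect_gt(m$explained_variance_ratio[1], 1 - 1e-6)
})

test_that("variance-threshold retention applies the >= rule", {
  expect_equal(select_by_variance(c(0.9, 0.09, 0.009, 0.0009), 0.001), 3)
  expect_equal(select_by_variance(c(0.99, 0.01), 0.5), 1)
  expect_error(select_by_variance(c(0.9, 0.1), 0),
               class = "hsicnn_parameter_error")
})

test_that("incremental PCA agrees with one-shot SVD on pooled spectra", {
  set.seed(6)
  n <- 500; B <- 20
  X <- matrix(rnorm(n * B), n, B) %*% matrix(rnorm(B * B, sd = 0.5), B, B)
  m <- fit_pca(X, n_components = 5, chunk_size = 128)
  # independent oracle: full-matrix SVD of the centred data
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  V_full <- sv$v[, 1:5]
  # principal angles between the two 5-dim subspaces
  ang <- acos(pmin(1, svd(t(m$components %*% V_full))$d))
  expect_lt(max(ang), 1e-3)
  # explained-variance ratios match the oracle's
  expect_equal(m$explained_variance_ratio,
               (sv$d[1:5]^2 / (n - 1)) / sum(apply(X, 2, var)),
               tolerance = 1e-6)
  # orthonormal, non-increasing, summing below 1
  expect_equal(m$components %*% t(m$components), diag(5), tolerance = 1e-8)
  expect_true(all(diff(m$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(m$explained_variance_ratio), 1 + 1e-12)
})

test_that("projection centres the mean and a complete basis reconstructs", {
  set.seed(7)
  X <- matrix(runif(200 * 6), 200, 6)
  m <- fit_pca(X, n_components = 6, chunk_size = 64)
  mean_patch <- structure(list(values = array(m$mean, c(1, 1, 6)),
                               origin = c(row = 0, col = 0), case_id = "c",
                               label = "healthy", wavelengths = wl_grid(6)),
                          class = "hsi_patch")
  expect_equal(as.numeric(apply_pca(m, mean_patch)$values), rep(0, 6),
               tolerance = 1e-9)
  p <- structure(list(values = array(runif(4 * 4 * 6), c(4, 4, 6)),
                      origin = c(row = 0, col = 0), case_id = "c",
                      label = "healthy", wavelengths = wl_grid(6)),
                 class = "hsi_patch")
  scores <- apply_pca(m, p)
  recon <- sweep(matrix(scores$values, 16, 6) %*% m$components, 2L,
                 -m$mean)
  expect_lt(max(abs(recon - matrix(p$values, 16, 6))), 1e-6)
})

test_that("a rank-3 endmember mixture concentrates variance in 3 components", {
  set.seed(8)
  B <- 15
  E <- matrix(runif(3 * B), 3, B)
  A <- matrix(runif(600 * 3), 600, 3)
  X <- A %*% E + matrix(rnorm(600 * B, sd = 1e-4), 600, B)
  m <- fit_pca(X, n_components = 5, chunk_size = 200)
  expect_gt(sum(m$explained_variance_ratio[1:3]), 0.99)
})

test_that("reconstruction error is monotone non-increasing in components", {
  set.seed(9)
  X <- matrix(rnorm(300 * 8), 300, 8) %*% matrix(rnorm(64, sd = 0.6), 8, 8)
  errs <- vapply(1:6, function(k) {
    m <- fit_pca(X, n_components = k, chunk_size = 100)
    Xc <- sweep(X, 2L, m$mean)
    sum((Xc - Xc %*% t(m$components) %*% m$components)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("PCA refuses degenerate inputs", {
  expect_error(fit_pca(matrix(1, 1, 5)), class = "hsicnn_rank_error")
  expect_error(fit_pca(matrix(rnorm(20), 4, 5), n_components = 5),
               class = "hsicnn_rank_error")
})

test_that("RGB weights are normalized Gaussians peaking at their means", {
  wl <- wl_grid(30)
  W <- rgb_weights(wl)
  expect_equal(rowSums(W), c(R = 1, G = 1, B = 1))
  expect_equal(which.max(W["R", ]), which.min(abs(wl - 630)))
  expect_equal(which.max(W["G", ]), which.min(abs(wl - 540)))
  expect_equal(which.max(W["B", ]), which.min(abs(wl - 480)))
})

test_that("a spectrally flat cube synthesizes to its own constant in RGB", {
  cube <- hsi_cube(array(0.37, c(4, 4, 30)), wl_grid(30), calibrated = TRUE)
  rgb <- synthesize_rgb(cube)
  expect_equal(dim(rgb$values)[3], 3)
  expect_equal(as.numeric(rgb$values), rep(0.37, 48))
})

test_that("a delta spectrum at 540 nm lights the green channel most", {
  wl <- wl_grid(30)
  v <- array(0, c(2, 2, 30))
  v[, , which.min(abs(wl - 540))] <- 1
  rgb <- synthesize_rgb(hsi_cube(v, wl, calibrated = TRUE))
  # bands stored blue-to-red: 480, 540, 630
  g <- rgb$values[1, 1, 2]
  expect_gt(g, rgb$values[1, 1, 1])
  expect_gt(g, rgb$values[1, 1, 3])
})

test_that("a grid missing a channel's support warns but still computes", {
  wl <- seq(470, 550, length.out = 10) # no red coverage within 3 sd
  expect_warning(rgb_weights(wl), "available support")
})

test_that("a scene with 4% blank-heavy patches loses exactly those", {
  # 320x320 image tiled at S=32: 100 patches, 4 of them 75% glass
  plane <- matrix(0.4, 320, 320)
  blank_cells <- list(c(0, 0), c(3, 5), c(7, 2), c(9, 9))
  for (cell in blank_cells) {
    rows <- cell[1] * 32 + 1:32
    cols <- cell[2] * 32 + 1:24 # 75% of the patch width
    plane[rows, cols] <- 0.95
  }
  cube <- hsi_cube(array(rep(plane, 2), c(320, 320, 2)), wl_grid(2),
                   calibrated = TRUE)
  thr <- blank_threshold(cube)
  patches <- extract_patches(cube, 32, "c1", "unhealthy")
  res <- filter_blank_patches(patches, thr)
  expect_equal(res$removed_count, 4)
  removed <- setdiff(seq_along(patches), res$kept_idx)
  removed_origins <- lapply(patches[removed], function(p)
    unname(p$origin) / 32)
  expect_setequal(lapply(blank_cells, as.numeric), removed_origins)
})

test_that("patches persist as ENVI sub-cubes with a manifest", {
  cube <- toy_cube(8, 8, 3, calibrated = TRUE)
  patches <- extract_patches(cube, 4, "caseX", "healthy")
  dir <- withr::local_tempdir()
  manifest <- write_patches(patches, dir, source = "img1")
  expect_equal(nrow(manifest), 4)
  back <- read_envi_cube(manifest$path[2])
  expect_identical(back$values, patches[[2]]$values)
})
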