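test_that("tissue endmembers dip near 540 and 650 nm; glass stays brighter", {
  wl <- wl_grid(30)
  em <- endmember_library(0.15, wl)
  tissues <- c("normal_cell", "normal_background",
               "tumor_cell", "tumor_background")
  for (n in tissues) {
    expect_true(has_dip_near(em[[n]], wl, 540), info = n)
    expect_true(has_dip_near(em[[n]], wl, 650), info = n)
    # the eosin dip: darker at 540 than at 580 (on the smoothed baseline;
    # the metameric class contrast is a deliberate band-alternating overlay)
    sm <- smooth_spectrum(em[[n]])
    expect_lt(sm[which.min(abs(wl - 540))], sm[which.min(abs(wl - 580))])
    # glass brighter than tissue at every band (checked by enumeration)
    expect_true(all(em$glass - em[[n]] > 0), info = n)
  }
  expect_true(all(vapply(tissues, function(n)
    all(em[[n]] > 0 & em[[n]] <= 1), logical(1))))
})

test_that("zero contrast collapses tumor and normal endmembers", {
  wl <- wl_grid(30)
  em0 <- endmember_library_zero(wl)
  expect_identical(em0$tumor_cell, em0$normal_cell)
  expect_identical(em0$tumor_background, em0$normal_background)
  expect_error(endmember_library(0, wl), class = "hsicnn_parameter_error")
  expect_error(endmember_library(-1, wl), class = "hsicnn_parameter_error")
})

test_that("the class contrast is invisible to RGB synthesis (metamer)", {
  wl <- wl_grid(30)
  em <- endmember_library(0.15, wl)
  Wm <- rgb_weights(wl)
  # tumor and normal map to identical RGB triples, per component
  expect_equal(as.numeric(Wm %*% em$tumor_cell),
               as.numeric(Wm %*% em$normal_cell), tolerance = 1e-10)
  expect_equal(as.numeric(Wm %*% em$tumor_background),
               as.numeric(Wm %*% em$normal_background), tolerance = 1e-10)
  # but the spectra themselves differ by delta at the peak band
  expect_equal(max(abs(em$tumor_cell - em$normal_cell)), 0.15,
               tolerance = 1e-12)
})

test_that("rendering is bit-reproducible under a fixed seed", {
  cfg <- phantom_config(seed = 1)
  a <- render_tissue_cube(cfg, "unhealthy", "c1", seed = 42)
  b <- render_tissue_cube(cfg, "unhealthy", "c1", seed = 42)
  expect_identical(a$cube$values, b$cube$values)
  expect_identical(a$mask, b$mask)
})

test_that("blank fraction 1 renders an all-glass scene", {
  cfg <- phantom_config(seed = 2, blank_fraction = 1)
  rec <- render_tissue_cube(cfg, "healthy", "c1", seed = 3)
  expect_true(all(rec$mask == 0L))
  # glass is near-flat and bright
  expect_gt(mean(rec$cube$values), 0.9)
})

test_that("nucleus disks measure 12-18 px in equivalent diameter", {
  cfg <- phantom_config(seed = 3, height = 96, width = 96,
                        blank_fraction = 0)
  rec <- render_tissue_cube(cfg, "unhealthy", "c1", seed = 7)
  cells <- rec$mask == 4L
  expect_gt(sum(cells), 0)
  # geometric oracle: connected components, equivalent-disk diameter
  lbl <- EBImage::bwlabel(cells)
  areas <- tabulate(lbl[lbl > 0])
  diam <- 2 * sqrt(areas / pi)
  expect_true(all(diam > 12 - 2 & diam < 18 + 2))
  expect_gte(mean(diam), 12)
  expect_lte(mean(diam), 18)
})

test_that("mask and components partition every pixel", {
  rec <- render_tissue_cube(phantom_config(seed = 4), "healthy", "c1",
                            seed = 9)
  expect_true(all(rec$mask %in% c(0L, 1L, 2L)))
  rec2 <- render_tissue_cube(phantom_config(seed = 4), "unhealthy", "c2",
                             seed = 9)
  expect_true(all(rec2$mask %in% c(0L, 3L, 4L)))
})

test_that("the default dataset reproduces the 60-sample/30-case design", {
  ds <- generate_dataset(phantom_config(seed = 10))
  expect_length(ds$samples, 60)
  cases <- vapply(ds$samples, `[[`, "", "case_id")
  labels <- vapply(ds$samples, `[[`, "", "label")
  splits <- vapply(ds$samples, `[[`, "", "split")
  expect_length(unique(cases), 30)
  expect_equal(sum(labels == "healthy"), 6)
  expect_equal(sum(labels == "unhealthy"), 54)
  for (sp in c("train", "val", "test")) {
    expect_equal(sum(splits == sp & labels == "healthy"), 2)
    expect_equal(sum(splits == sp & labels == "unhealthy"), 18)
    expect_length(unique(cases[splits == sp]), 10)
  }
  # split assignment is by case: no case id in two splits
  expect_equal(nrow(unique(data.frame(cases, splits))), 30)
  # two samples per case
  expect_true(all(table(cases) == 2))
})

test_that("a nearest-endmember pixel classifier separates the classes", {
  cfg <- phantom_config(seed = 20, blank_fraction = 0)
  wl <- wl_grid(cfg$n_bands)
  em <- endmember_library(cfg$delta, wl)
  M <- rbind(em$normal_cell, em$normal_background,
             em$tumor_cell, em$tumor_background)
  cls <- c("healthy", "healthy", "unhealthy", "unhealthy")
  acc <- vapply(c(healthy = "healthy", unhealthy = "unhealthy"),
                function(lab) {
    rec <- render_tissue_cube(cfg, lab, "c", seed = match(lab, cls))
    X <- matrix(rec$cube$values, ncol = cfg$n_bands)
    d2 <- outer(rowSums(X^2), rowSums(M^2), "+") - 2 * X %*% t(M)
    mean(cls[max.col(-d2)] == lab)
  }, numeric(1))
  expect_gt(min(acc), 0.95)
})

test_that("mean cell spectra of rendered scenes keep the H&E dips", {
  cfg <- phantom_config(seed = 21)
  wl <- wl_grid(cfg$n_bands)
  for (lab in c("healthy", "unhealthy")) {
    rec <- render_tissue_cube(cfg, lab, "c", seed = 31)
    cells <- rec$mask %in% c(2L, 4L)
    spec <- colMeans(matrix(rec$cube$values, ncol = cfg$n_bands)[cells, ])
    expect_true(has_dip_near(spec, wl, 540), info = lab)
    expect_true(has_dip_near(spec, wl, 650), info = lab)
  }
})
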