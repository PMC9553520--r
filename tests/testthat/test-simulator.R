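test_that("region model and config invariants are enforced", {
  expect_error(region_speckle_model("air", base_scale = 0), "base_scale")
  expect_error(region_speckle_model("air", 1, rayleigh_purity = 1.2))
  expect_error(region_speckle_model("air", 1, decorrelation = -0.1))
  expect_error(region_speckle_model("lipid", 1), "arg")

  expect_error(phantom_config(tube = list(center_depth = 600,
                                          center_fast = 500,
                                          inner_diameter = 800,
                                          outer_diameter = 762)),
               "inner diameter")
  # tube poking out of the volume is a configuration error
  expect_error(phantom_config(tube = list(center_depth = 100,
                                          center_fast = 500,
                                          inner_diameter = 305,
                                          outer_diameter = 762)),
               "does not fit")
  models <- default_region_models()
  models$air <- NULL
  expect_error(phantom_config(region_models = models), "missing")
})

test_that("generation is deterministic given the config seed", {
  cfg <- small_phantom_config(seed = 11)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$volume$intensity, b$volume$intensity)
  expect_identical(a$labels$labels, b$labels$labels)
  c <- generate_phantom(small_phantom_config(seed = 12))
  expect_false(identical(a$volume$intensity, c$volume$intensity))
})

test_that("single-region pure-Rayleigh output passes a KS test against the closed form", {
  # statistical contract: shifted-Rayleigh marginal at purity 1, no floor
  model <- region_speckle_model("intralipid", base_scale = 2, shift = -0.2,
                                rayleigh_purity = 1, noise_floor_scale = 0,
                                decorrelation = 1)
  pass <- vapply(1:100, function(seed) {
    vol <- generate_region_volume(model, shape = c(6L, 6L, 10L, 24L),
                                  seed = seed)
    s <- pool_roi(vol, c(0, 0, 0), c(6, 6, 10))
    ks <- suppressWarnings(
      stats::ks.test(s, function(q) p_shifted_rayleigh(q, b = 2, c = -0.2))
    )
    ks$p.value > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("the Rayleigh marginal survives partial decorrelation", {
  # field-space interpolation keeps the single-frame amplitude distribution
  model <- region_speckle_model("dyed_water", base_scale = 1.5, shift = 0,
                                decorrelation = 0.2)
  vol <- generate_region_volume(model, shape = c(12L, 12L, 10L, 8L),
                                seed = 5)
  s <- as.vector(vol$intensity[, , , 3])  # one frame: iid across voxels
  ks <- suppressWarnings(
    stats::ks.test(s, function(q) p_shifted_rayleigh(q, b = 1.5, c = 0))
  )
  expect_gt(ks$p.value, 0.01)
  # and repeats really are correlated at low decorrelation
  # (field correlation rho = 0.8 gives amplitude correlation near rho^2)
  r1 <- as.vector(vol$intensity[, , , 1])
  r2 <- as.vector(vol$intensity[, , , 2])
  expect_gt(stats::cor(r1, r2), 0.25)
})

test_that("a vanishing scale collapses intensities onto the shift", {
  model <- region_speckle_model("air", base_scale = 1e-9, shift = 5,
                                noise_floor_scale = 0)
  vol <- generate_region_volume(model, shape = c(4L, 4L, 4L, 2L), seed = 1)
  expect_true(all(abs(vol$intensity - 5) < 1e-6))
})

test_that("label geometry matches the analytic cylinders", {
  cfg <- phantom_config()
  ph <- generate_phantom(cfg)
  lab <- ph$labels$labels
  expect_setequal(sort(unique(as.vector(lab))), 1:6)

  dims <- dim(lab)
  z <- (seq_len(dims[1]) - 0.5) * cfg$voxel_pitch[1]
  x <- (seq_len(dims[2]) - 0.5) * cfg$voxel_pitch[2]
  zz <- matrix(z, dims[1], dims[2])
  xx <- matrix(x, dims[1], dims[2], byrow = TRUE)

  # every voxel centre strictly inside the lumen is dyed water
  r_tube <- sqrt((zz - cfg$tube$center_depth)^2 + (xx - cfg$tube$center_fast)^2)
  lumen <- r_tube < cfg$tube$inner_diameter / 2
  k_dw <- match("dyed_water", region_labels())
  for (slice in c(1L, dims[3])) {
    expect_true(all(lab[, , slice][lumen] == k_dw))
  }

  # voxel-counting oracle: label counts match analytic cylinder cross-section
  # areas to within a one-voxel boundary shell
  count_dw <- sum(lab[, , 1] == k_dw)
  area_vox <- pi * (cfg$tube$inner_diameter / 2)^2 /
    (cfg$voxel_pitch[1] * cfg$voxel_pitch[2])
  perimeter_vox <- pi * cfg$tube$inner_diameter / cfg$voxel_pitch[1]
  expect_lt(abs(count_dw - area_vox), perimeter_vox)

  k_rod <- match("transparent_solid", region_labels())
  count_rod <- sum(lab[, , 1] == k_rod)
  rod_area <- pi * (cfg$rod$diameter / 2)^2 /
    (cfg$voxel_pitch[1] * cfg$voxel_pitch[2])
  rod_perim <- pi * cfg$rod$diameter / cfg$voxel_pitch[1]
  expect_lt(abs(count_rod - rod_area), rod_perim)

  # air occupies exactly the rows above the surface
  k_air <- match("air", region_labels())
  n_air_rows <- sum(z < cfg$surface_depth)
  expect_true(all(lab[seq_len(n_air_rows), , ] == k_air))
  expect_true(all(lab[n_air_rows + 1L, , ] != k_air))
})

test_that("lowering rayleigh_purity never raises expected fit R^2", {
  purities <- c(1, 0.9, 0.75, 0.6)
  means <- vapply(purities, function(p) {
    r2 <- vapply(1:20, function(seed) {
      m <- region_speckle_model("intralipid", base_scale = 3, shift = -0.3,
                                noise_floor_scale = 0.15,
                                rayleigh_purity = p, decorrelation = 1)
      vol <- generate_region_volume(m, shape = c(6L, 6L, 10L, 24L),
                                    seed = seed)
      fit_rayleigh(pool_roi(vol, c(0, 0, 0), c(6, 6, 10)))$r_squared
    }, numeric(1))
    mean(r2)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("volumes round-trip through the raw format bit-identically", {
  ph <- generate_phantom(small_phantom_config(seed = 3))
  dir <- withr::local_tempdir()
  write_volume(ph$volume, dir, labels = ph$labels)
  back <- read_volume(dir)
  expect_identical(back$volume$intensity, ph$volume$intensity)
  expect_identical(back$volume$voxel_pitch, ph$volume$voxel_pitch)
  expect_identical(back$labels$labels, ph$labels$labels)
})

test_that("a 1x1x1x1 volume round-trips", {
  v <- oct_volume(array(3.14, dim = c(1, 1, 1, 1)), c(7.5, 7.5, 3.75))
  dir <- withr::local_tempdir()
  write_volume(v, dir)
  back <- read_volume(dir)
  expect_identical(back$volume$intensity, v$intensity)
})

test_that("tiff layout round-trips to single precision", {
  ph <- generate_phantom(small_phantom_config(seed = 4))
  dir <- withr::local_tempdir()
  write_volume(ph$volume, dir, labels = ph$labels, format = "tiff")
  back <- read_volume(dir)
  expect_equal(back$volume$intensity, ph$volume$intensity, tolerance = 1e-5)
  expect_identical(back$labels$labels, ph$labels$labels)
})

test_that("reading without sidecar metadata is an explicit error", {
  dir <- withr::local_tempdir()
  expect_error(read_volume(dir), "sidecar")
})

test_that("the packaged default config parses and matches the in-code default", {
  path <- system.file("extdata", "phantom_default.yaml", package = "octspeckle")
  cfg <- read_phantom_config(path)
  ref <- phantom_config()
  expect_equal(cfg$volume_shape, ref$volume_shape)
  expect_equal(cfg$voxel_pitch, ref$voxel_pitch)
  expect_equal(cfg$tube, ref$tube)
  expect_equal(cfg$rod, ref$rod)
  for (lab in region_labels()) {
    expect_equal(cfg$region_models[[lab]], ref$region_models[[lab]],
                 info = lab)
  }
})
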