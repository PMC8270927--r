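test_that("phantom construction honours its configured composition levels", {
  ph <- shared_phantom()
  m <- ph$plaque_mask_true$data > 0
  ff <- phantom_ff(ph)
  expect_gte(max(ff[m]), 0.4)                       # lipid core present
  expect_gte(max(ph$r2star_map$data[m]), 90)        # hemorrhage present
  expect_true(all(ff[!is.na(ff)] >= 0 & ff[!is.na(ff)] <= 1))
  expect_true(all(ph$water_map$data >= 0))
  expect_true(all(ph$fat_map$data >= 0))
  expect_true(all(ph$r2star_map$data >= 0))
  expect_true(all(ph$activity_map$data >= 0))
  expect_equal(ph$injected_dose, 3 * ph$body_weight)
})

test_that("phantom generation is deterministic for a fixed seed", {
  a <- make_phantom(phantom_config(), seed = 42)
  b <- make_phantom(phantom_config(), seed = 42)
  expect_identical(a$water_map$data, b$water_map$data)
  expect_identical(a$t1w_map$data, b$t1w_map$data)
  expect_identical(a$plaque_mask_true$data, b$plaque_mask_true$data)
  c <- make_phantom(phantom_config(), seed = 43)
  expect_false(identical(a$t1w_map$data, c$t1w_map$data))
})

test_that("degenerate and unbuildable geometries are handled", {
  ph0 <- make_phantom(phantom_config(plaque_angle_extent = 0), seed = 1)
  expect_equal(sum(ph0$plaque_mask_true$data), 0)
  expect_true(attr(ph0$plaque_mask_true, "degenerate"))
  expect_error(make_phantom(phantom_config(lumen_radius = 20), seed = 1),
               "does not fit")
  expect_error(
    make_phantom(phantom_config(wall_thickness = 0.4,
                                plaque_protrusion = 0.5), seed = 1),
    "1.5 mm")
})

test_that("plaque mask sits in wall voxels at least 1.5 mm thick", {
  ph <- shared_phantom()
  cfg <- ph$config
  # every mask voxel must be wall tissue (not lumen, not background)
  m <- which(ph$plaque_mask_true$data > 0, arr.ind = TRUE)
  w <- grid_to_world(ph$grid, m)
  r <- sqrt((w[, 1] - cfg$vessel_center[1])^2 + (w[, 2] - cfg$vessel_center[2])^2)
  expect_true(all(r >= cfg$lumen_radius))
  expect_true(all(r < cfg$lumen_radius + cfg$wall_thickness +
                    cfg$plaque_protrusion))
  expect_gte(cfg$wall_thickness + cfg$plaque_protrusion, 1.5)
})

test_that("Dixon rendering matches the forward model exactly at zero noise", {
  ph <- shared_phantom()
  ser <- render_dixon(ph, noise_sd = 0, seed = 1)
  expect_s3_class(ser, "pf_dixon_series")
  expect_equal(ser$tes, default_tes)
  i <- which(ph$plaque_mask_true$data > 0)[1]
  w <- ph$water_map$data[i]; f <- ph$fat_map$data[i]
  r2 <- ph$r2star_map$data[i]
  for (k in seq_along(ser$tes))
    expect_equal(ser$volumes[[k]]$data[i],
                 forward_signal(w, f, r2, ser$tes[k]), tolerance = 1e-12)
  # determinism of the noisy render
  a <- render_dixon(ph, 0.05, seed = 9)
  b <- render_dixon(ph, 0.05, seed = 9)
  expect_identical(a$volumes[[1]]$data, b$volumes[[1]]$data)
  expect_error(render_dixon(ph, noise_sd = -1), "non-negative")
})

test_that("in-phase signal at the zero-echo-time limit equals water + fat", {
  ph <- shared_phantom()
  te_small <- 1e-6
  s <- forward_signal(ph$water_map$data, ph$fat_map$data,
                      ph$r2star_map$data, te_small)
  # cos(2 pi te / 2.4) -> 1 and exp(-r2 te) -> 1 as te -> 0
  expect_equal(as.numeric(s),
               as.numeric(ph$water_map$data + ph$fat_map$data),
               tolerance = 1e-4)
})

test_that("T1W rendering targets the session grids and encodes misalignment", {
  ph <- shared_phantom()
  t1s <- render_t1w(ph, "standalone")
  expect_equal(t1s$grid$voxel_size, c(0.50, 0.50, 1.75))
  t1p <- render_t1w(ph, "petmr")
  expect_equal(t1p$grid$voxel_size, c(0.31, 0.31, 2.5))
  expect_error(render_t1w(ph, "unknown"))
  # custom grid is honoured
  g <- grid_geometry(c(20, 20, 8), c(1, 1, 2), c(-10, -10, -8))
  expect_equal(render_t1w(ph, "standalone", grid = g)$grid$shape, g$shape)

  # identity session transform: standalone and petmr differ only by grid
  cfg_id <- phantom_config(session_transform = identity_transform())
  ph_id <- make_phantom(cfg_id, seed = 1)
  a <- render_t1w(ph_id, "standalone", grid = g)
  b <- render_t1w(ph_id, "petmr", grid = g)
  expect_equal(a$data, b$data, tolerance = 1e-12)
})

test_that("a pure translation shows up as a cross-correlation peak offset", {
  cfg <- phantom_config(session_transform = similarity_transform(
    translation = c(2, 0, 0)))
  ph <- make_phantom(cfg, seed = 1)
  g <- grid_geometry(c(56, 56, 10), c(0.5, 0.5, 1.75),
                     -(c(56, 56, 10) - 1) / 2 * c(0.5, 0.5, 1.75))
  fixed <- render_t1w(ph, "standalone", grid = g)
  moved <- render_t1w(ph, "petmr", grid = g)
  # brute-force shift search along x (2 mm = 4 voxels of 0.5 mm)
  shifts <- -8:8
  score <- vapply(shifts, function(s) {
    a <- fixed$data[pmax(1, 1 - s):pmin(56, 56 - s), , ]
    b <- moved$data[pmax(1, 1 + s):pmin(56, 56 + s), , ]
    stats::cor(as.numeric(a), as.numeric(b))
  }, numeric(1))
  expect_equal(shifts[which.max(score)], 4)
})

test_that("PET rendering preserves uniform fields and conserves activity", {
  ph <- shared_phantom()
  uni <- ph
  uni$activity_map$data[] <- 5
  pet <- render_pet(uni, psf_fwhm_mm = 3, noise_sd = 0, seed = 1,
                    apply_session_transform = FALSE)
  inner <- pet$activity$data[5:20, 5:20, 3:5]   # away from grid edges
  expect_equal(range(inner), c(5, 5), tolerance = 1e-6)

  # convolution conserves total activity for a kernel supported in-grid
  blob <- array(0, ph$grid$shape)
  blob[20:28, 20:28, 10:14] <- 7
  sm <- plaquefusion:::gaussian_blur_array(blob, sigma_vox = c(2, 2, 1.7))
  expect_lt(abs(sum(sm) - sum(blob)) / sum(blob), 0.005)

  expect_error(render_pet(ph, psf_fwhm_mm = 0), "positive")
  expect_error(render_pet(ph, noise_sd = -0.1), "non-negative")
  a <- render_pet(ph, 3, 0.1, seed = 3)
  b <- render_pet(ph, 3, 0.1, seed = 3)
  expect_identical(a$activity$data, b$activity$data)
})

test_that("a rendered point source has the requested point-spread FWHM", {
  cfg <- phantom_config(background_activity = 0, wall_activity = 0,
                        blood_activity = 0, plaque_activity = 0)
  ph <- make_phantom(cfg, seed = 1)
  ph$activity_map$data[] <- 0
  ph$activity_map$data[24, 24, 12] <- 1000
  pet <- render_pet(ph, psf_fwhm_mm = 3, noise_sd = 0, seed = 1,
                    apply_session_transform = FALSE)
  # profile through the maximum along x, in mm
  mx <- which(pet$activity$data == max(pet$activity$data), arr.ind = TRUE)[1, ]
  prof <- pet$activity$data[, mx[2], mx[3]]
  x_mm <- (seq_along(prof) - mx[1]) * pet$grid$voxel_size[1]
  fit <- stats::nls(prof ~ a * exp(-x_mm^2 / (2 * s^2)),
                    start = list(a = max(prof), s = 1.5))
  fwhm <- 2 * sqrt(2 * log(2)) * abs(coef(fit)[["s"]])
  expect_lt(abs(fwhm - 3), pet$grid$voxel_size[1])  # within one voxel
})

test_that("Dixon round trip is the identity on the full phantom at zero noise", {
  ph <- shared_phantom()
  ser <- render_dixon(ph, 0, 1)
  comp <- fit_volume(ser)
  ok <- comp$valid_mask$data > 0
  ff <- phantom_ff(ph)
  sel <- ok & !is.na(ff) & ph$water_map$data > ph$fat_map$data
  expect_gt(sum(sel), 1000)
  expect_lt(max(abs(comp$fat_fraction$data[sel] - ff[sel]) /
                  pmax(ff[sel], 1e-9)), 1e-6)
  rel_r2 <- abs(comp$r2star$data[sel] - ph$r2star_map$data[sel]) /
    pmax(ph$r2star_map$data[sel], 1e-9)
  expect_lt(max(rel_r2), 1e-6)
})
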