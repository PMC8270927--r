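# deterministic test image whose values land exactly on histogram bin
# centres, so self-MI equals the binned marginal entropy exactly
bin_exact_image <- function(seed = 5, bins = 32) {
  g <- grid_geometry(c(16, 16, 8), c(1, 1, 1))
  set.seed(seed)
  as_volume(array(sample(0:(bins - 1), prod(g$shape), replace = TRUE),
                  g$shape), g)
}

test_that("mutual information behaves as an alignment metric", {
  img <- bin_exact_image()
  mi_self <- mattes_mi(img, img)
  # marginal entropy of the same binning
  p <- tabulate(as.numeric(img$data) + 1, nbins = 32) / length(img$data)
  entropy <- -sum(p[p > 0] * log(p[p > 0]))
  expect_equal(mi_self, entropy, tolerance = 1e-10)

  shifted <- similarity_transform(translation = c(5, 0, 0))
  expect_lt(mattes_mi(img, img, shifted), mi_self)

  const <- as_volume(array(1, img$grid$shape), img$grid)
  expect_equal(mattes_mi(img, const), 0)
  expect_error(mattes_mi(img, img, bins = 4), "at least 8")
  # empty overlap gives the defined worst score, not an error
  far <- similarity_transform(translation = c(1000, 0, 0))
  expect_equal(mattes_mi(img, img, far), 0)
})

test_that("the MI optimum is preserved under monotone intensity rescaling", {
  t1 <- shared_t1w()
  pos <- as_volume(t1$data - min(t1$data), t1$grid)
  quad <- as_volume(pos$data^2, t1$grid)
  shifts <- seq(-2, 2, 0.5)
  mi_orig <- vapply(shifts, function(s)
    mattes_mi(pos, pos, similarity_transform(translation = c(s, 0, 0))),
    numeric(1))
  mi_quad <- vapply(shifts, function(s)
    mattes_mi(quad, pos, similarity_transform(translation = c(s, 0, 0))),
    numeric(1))
  expect_equal(shifts[which.max(mi_orig)], 0)
  expect_equal(shifts[which.max(mi_quad)], 0)
  # equal-width binning redistributes mass under a nonlinear rescale, so the
  # MI value moves boundedly while the optimum stays put
  expect_lt(abs(mi_quad[shifts == 0] - mi_orig[shifts == 0]) /
              mi_orig[shifts == 0], 0.25)
})

test_that("registering an image to itself returns (near) identity", {
  t1 <- shared_t1w()
  reg <- register_similarity(t1, t1, seed = 1)
  expect_lt(max(abs(reg$translation)), 0.1)
  expect_lt(max(abs(reg$rotation)), 0.1)
  expect_lt(abs(reg$scale - 1), 0.001)
})

test_that("known translations and scalings are recovered", {
  t1 <- shared_t1w()
  tt <- similarity_transform(translation = c(2, -1, 0))
  mov <- resample_volume(t1, t1$grid, transform = tt, fill = NA)
  reg <- register_similarity(t1, mov, seed = 3)
  truth <- invert_transform(tt)
  expect_lt(max(abs(reg$translation - truth$translation) /
                  t1$grid$voxel_size), 0.5)

  # pure scaling between the two sessions, each rendered from the phantom
  # with a single interpolation (as two acquisitions of one object)
  cfg <- phantom_config(session_transform = similarity_transform(scale = 1.05))
  ph <- make_phantom(cfg, seed = 1)
  fixed <- render_t1w(ph, "standalone")
  moving <- render_t1w(ph, "petmr")
  regs <- register_similarity(fixed, moving, seed = 4)
  expect_lt(abs(regs$scale - 1.05), 0.01)
})

test_that("random similarity perturbations are recovered to sub-voxel error", {
  t1 <- shared_t1w()
  for (i in 1:3) {
    tt <- random_similarity(300 + i, 5, 5, c(0.95, 1.05))
    mov <- resample_volume(t1, t1$grid, transform = tt, fill = NA)
    reg <- register_similarity(t1, mov, seed = i)
    truth <- invert_transform(tt)
    expect_lt(max(abs(reg$translation - truth$translation) /
                    t1$grid$voxel_size), 1)
    expect_lt(max(abs(reg$rotation - truth$rotation)), 1)
  }
})

test_that("degenerate constant images yield a flagged identity transform", {
  g <- grid_geometry(c(10, 10, 5), c(1, 1, 2))
  const <- as_volume(array(2, g$shape), g)
  expect_warning(reg <- register_similarity(const, const, seed = 1),
                 "degenerate")
  expect_true(attr(reg, "degenerate"))
  expect_equal(reg$translation, c(0, 0, 0))
  expect_equal(reg$scale, 1)
})

test_that("mask transfer is exact for identity and whole-slice shifts", {
  ph <- shared_phantom()
  mask <- ph$plaque_mask_true
  same <- apply_to_mask(mask, NULL, mask$grid)
  expect_identical(same$data, mask$data)

  shift <- similarity_transform(translation = c(0, 0, -mask$grid$voxel_size[3]))
  shifted <- apply_to_mask(mask, shift, mask$grid)
  expect_equal(mask_slice_ids(shifted), mask_slice_ids(mask) + 1)

  empty <- apply_to_mask(mask, similarity_transform(translation = c(100, 0, 0)),
                         mask$grid)
  expect_true(attr(empty, "degenerate"))
})

test_that("mask voxel count is conserved up to voxel-volume ratio", {
  ph <- shared_phantom()
  mask <- ph$plaque_mask_true
  tf <- invert_transform(ph$session_transform_true)
  pet_grid <- grid_geometry(c(24, 24, 7), c(1.2, 1.2, 2.78),
                            -(c(24, 24, 7) - 1) / 2 * c(1.2, 1.2, 2.78))
  moved <- apply_to_mask(mask, tf, pet_grid)
  vol_ratio <- prod(mask$grid$voxel_size) / prod(pet_grid$voxel_size)
  expected <- sum(mask$data) * vol_ratio * ph$session_transform_true$scale^3
  expect_gt(sum(moved$data), expected * 0.8)
  expect_lt(sum(moved$data), expected * 1.2)
})

test_that("slice correspondence follows landmark-relative nearest centres", {
  g175 <- grid_geometry(c(4, 4, 12), c(1, 1, 1.75))
  g250 <- grid_geometry(c(4, 4, 9), c(1, 1, 2.5))
  a <- as_volume(array(0, g175$shape), g175)
  b <- as_volume(array(0, g250$shape), g250)

  # equal thickness, same landmark: identity mapping
  same <- align_slices(a, as_volume(array(0, g175$shape), g175), 6, 6)
  expect_equal(same$target_slice, same$source_slice)

  # 1.75 vs 2.5 mm: source at +3.50 mm maps to target at +2.5 mm
  m <- align_slices(a, b, 5, 4)
  row <- m[m$source_slice == 7, ]           # (7 - 5) * 1.75 = +3.5 mm
  expect_equal(row$target_slice, 5)         # (5 - 4) * 2.5 = +2.5 mm
  expect_true(all(diff(m$target_slice) >= 0))  # monotone

  # landmark offset by k slices shifts the mapping by k
  m2 <- align_slices(a, a, 6, 6)
  m3 <- align_slices(a, a, 6, 8)
  shared <- intersect(m2$source_slice, m3$source_slice)
  expect_equal(m3$target_slice[match(shared, m3$source_slice)],
               m2$target_slice[match(shared, m2$source_slice)] + 2)

  expect_error(align_slices(a, b, 0, 1), "landmark")
})

test_that("transform algebra round-trips through inversion and composition", {
  tf <- similarity_transform(translation = c(2, -3, 1),
                             rotation = c(4, -2, 7), scale = 1.04,
                             center = c(1, 2, 0))
  id <- compose_transforms(tf, invert_transform(tf))
  expect_lt(max(abs(id$translation)), 1e-8)
  expect_lt(max(abs(id$rotation)), 1e-8)
  expect_lt(abs(id$scale - 1), 1e-10)
  # point mapping agrees with matrix composition
  p <- c(3.3, -1.2, 5.0)
  tf2 <- similarity_transform(translation = c(-1, 0.5, 2),
                              rotation = c(-3, 1, 5), scale = 0.97)
  expect_equal(as.numeric(apply_transform(compose_transforms(tf2, tf), p)),
               as.numeric(apply_transform(tf2, apply_transform(tf, p))),
               tolerance = 1e-10)
  expect_error(similarity_transform(scale = -1), "positive")
})
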