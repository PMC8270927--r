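#' Configuration for the digital carotid-plaque phantom
#'
#' The phantom is a straight vessel (lumen + wall) along the slice axis with
#' an eccentric wall thickening (the plaque) over a configurable angular
#' sector and slice range. Inside the plaque sit a lipid-rich region with
#' elevated fat fraction and a hemorrhagic region with elevated R2*. A second
#' smaller vessel stands in for the jugular vein and provides the venous
#' blood pool; a smooth intensity texture in the background keeps the
#' registration problem well-posed. The carotid bifurcation is modelled as a
#' marked slice index used as the landmark for slice alignment.
#'
#' Default levels: plaque is defined as a luminal protrusion of the wall of
#' at least 1.5 mm radial thickness, so the default wall (1.0 mm) plus
#' protrusion (1.3 mm) gives 2.3 mm in the plaque sector. Blood activity
#' defaults to 3.9 kBq/mL so that with 3 MBq/kg dosing the blood SUV is 1.3,
#' in the range observed for venous blood in carotid FDG studies; body weight
#' defaults to 75 kg.
#'
#' @param shape,voxel_size phantom grid (defaults: 48 x 48 x 24 voxels at
#'   0.60 x 0.60 x 0.7 mm, the Dixon acquisition grid).
#' @param vessel_center in-plane centre of the carotid lumen, mm.
#' @param lumen_radius,wall_thickness mm.
#' @param plaque_angle_center,plaque_angle_extent angular sector of the
#'   plaque, degrees; zero extent gives a degenerate (empty) plaque.
#' @param plaque_slices integer range (first, last) of plaque slices.
#' @param plaque_protrusion extra radial wall thickness in the plaque, mm.
#' @param lipid_ff fat fraction of the lipid-rich core.
#' @param lipid_angle_extent,lipid_slices sub-extent of the lipid core.
#' @param hemorrhage_r2star R2* of the hemorrhagic region, s^-1.
#' @param hemorrhage_angles,hemorrhage_slices sub-extent of the hemorrhage.
#' @param wall_ff,wall_r2star,plaque_ff,plaque_r2star baseline composition.
#' @param background_ff,background_r2star,blood_ff,blood_r2star as above.
#' @param blood_activity,plaque_activity,wall_activity,background_activity
#'   tracer concentrations, kBq/mL.
#' @param body_weight kg; `dose_per_kg` MBq/kg (injected dose = product).
#' @param vein_center,vein_radius geometry of the venous blood pool, mm.
#' @param bifurcation_slice landmark slice index.
#' @param session_transform [similarity_transform()] mapping the phantom
#'   frame to the PET-session frame (unknown to the pipeline; ground truth
#'   for registration).
#' @param texture_amp amplitude of the smooth background texture.
#' @return A `pf_phantom_config` list.
#' @export
phantom_config <- function(shape = c(48, 48, 24),
                           voxel_size = c(0.6, 0.6, 0.7),
                           vessel_center = c(-3, 0),
                           lumen_radius = 3.0,
                           wall_thickness = 1.0,
                           plaque_angle_center = 0,
                           plaque_angle_extent = 140,
                           plaque_slices = c(7, 20),
                           plaque_protrusion = 1.3,
                           lipid_ff = 0.40,
                           lipid_angle_extent = 60,
                           lipid_slices = c(9, 16),
                           hemorrhage_r2star = 90,
                           hemorrhage_angles = c(15, 65),
                           hemorrhage_slices = c(12, 19),
                           wall_ff = 0.05, wall_r2star = 40,
                           plaque_ff = 0.10, plaque_r2star = 45,
                           background_ff = 0.10, background_r2star = 30,
                           blood_ff = 0.0, blood_r2star = 15,
                           blood_activity = 3.9,
                           plaque_activity = 6.0,
                           wall_activity = 3.0,
                           background_activity = 1.5,
                           body_weight = 75,
                           dose_per_kg = 3,
                           vein_center = c(6, 5),
                           vein_radius = 2.0,
                           bifurcation_slice = 12,
                           session_transform = similarity_transform(
                             translation = c(1.5, -1.0, 1.0),
                             rotation = c(0, 0, 2), scale = 1.0),
                           texture_amp = 0.08) {
  cfg <- as.list(environment())
  class(cfg) <- "pf_phantom_config"
  cfg
}

phantom_grid <- function(cfg) {
  shape <- as.integer(cfg$shape)
  vox <- as.numeric(cfg$voxel_size)
  # world origin so the grid centre sits at (0, 0, 0)
  origin <- -(shape - 1) / 2 * vox
  grid_geometry(shape, vox, origin)
}

# run expr with a private RNG stream, restoring the caller's state
with_phantom_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

angle_in_sector <- function(theta, center, extent) {
  if (extent <= 0) return(rep(FALSE, length(theta)))
  d <- (theta - center + 180) %% 360 - 180
  abs(d) <= extent / 2
}

#' Build a ground-truth carotid-plaque phantom
#'
#' Generates voxel-wise water, fat, R2* and tracer-activity maps with a known
#' binary plaque mask, a marked bifurcation slice, and a known
#' phantom-to-PET-session similarity transform. All downstream inputs (Dixon
#' echoes, T1-weighted volumes, PET) are rendered from this object, so every
#' pipeline stage can be tested against exact truth.
#'
#' @param config a [phantom_config()].
#' @param seed integer; the phantom is deterministic given the seed.
#' @return Object of class `pf_phantom` with fields `water_map`, `fat_map`,
#'   `r2star_map`, `activity_map`, `t1w_map` (all `pf_volume`),
#'   `plaque_mask_true` (`pf_mask`), `session_transform_true`, `grid`,
#'   `blood_activity`, `body_weight`, `injected_dose`, `bifurcation_slice`,
#'   and `blood_points` (6 venous sample points, phantom-frame mm).
#' @examples
#' ph <- make_phantom(phantom_config(), seed = 1)
#' sum(ph$plaque_mask_true$data)
#' @export
make_phantom <- function(config = phantom_config(), seed = 1) {
  cfg <- config
  grid <- phantom_grid(cfg)
  fov <- grid$shape * grid$voxel_size

  r_out_max <- cfg$lumen_radius + cfg$wall_thickness + cfg$plaque_protrusion
  if (any(abs(cfg$vessel_center) + r_out_max > fov[1:2] / 2) ||
      any(abs(cfg$vein_center) + cfg$vein_radius > fov[1:2] / 2))
    stop("phantom geometry does not fit inside the grid; enlarge the grid ",
         "or shrink the vessel")
  if (cfg$plaque_angle_extent > 0 &&
      cfg$wall_thickness + cfg$plaque_protrusion < 1.5)
    stop("plaque wall thickness must be at least 1.5 mm ",
         "(definition of a plaque as a luminal protrusion >= 1.5 mm)")

  shp <- grid$shape
  ix <- seq_len(shp[1]); iy <- seq_len(shp[2]); iz <- seq_len(shp[3])
  wx <- grid$origin[1] + (ix - 1) * grid$voxel_size[1]
  wy <- grid$origin[2] + (iy - 1) * grid$voxel_size[2]
  X <- array(rep(wx, times = shp[2] * shp[3]), shp)
  Y <- array(rep(rep(wy, each = shp[1]), times = shp[3]), shp)
  Z <- array(rep(iz, each = shp[1] * shp[2]), shp)  # slice index

  dx <- X - cfg$vessel_center[1]; dy <- Y - cfg$vessel_center[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx) * 180 / pi

  in_plaque_sector <- angle_in_sector(theta, cfg$plaque_angle_center,
                                      cfg$plaque_angle_extent) &
    Z >= cfg$plaque_slices[1] & Z <= cfg$plaque_slices[2]
  thickness <- cfg$wall_thickness + cfg$plaque_protrusion * in_plaque_sector

  lumen <- r < cfg$lumen_radius
  wall <- r >= cfg$lumen_radius & r < cfg$lumen_radius + thickness
  plaque <- wall & in_plaque_sector & (thickness >= 1.5)

  lipid <- plaque &
    angle_in_sector(theta, cfg$plaque_angle_center, cfg$lipid_angle_extent) &
    Z >= cfg$lipid_slices[1] & Z <= cfg$lipid_slices[2]
  hem <- plaque &
    theta >= cfg$hemorrhage_angles[1] & theta <= cfg$hemorrhage_angles[2] &
    Z >= cfg$hemorrhage_slices[1] & Z <= cfg$hemorrhage_slices[2]

  dvx <- X - cfg$vein_center[1]; dvy <- Y - cfg$vein_center[2]
  vein <- sqrt(dvx^2 + dvy^2) < cfg$vein_radius

  background <- !(lumen | wall | vein)

  # smooth deterministic + seeded texture (background proton density);
  # the through-slice components anchor out-of-plane rotations during
  # registration
  wz <- grid$origin[3] + (iz - 1) * grid$voxel_size[3]
  Zw <- array(rep(wz, each = shp[1] * shp[2]), shp)
  fov_mm <- shp * grid$voxel_size
  # deterministic component uses wavelengths near or above the field of
  # view (no repeats inside the volume, so no false registration optima);
  # the seeded smooth random field has a unique autocorrelation peak and
  # anchors fine alignment
  tex_det <- 0.45 * sin(2 * pi * X / 25) * cos(2 * pi * Y / 29) +
    0.4 * sin(2 * pi * Zw / 23) * cos(2 * pi * X / 31) +
    0.3 * Zw / fov_mm[3] + 0.25 * X / fov_mm[1]
  tex_rand <- with_phantom_seed(seed, {
    n <- array(stats::rnorm(prod(shp)), shp)
    gaussian_blur_array(n, sigma_vox = c(2.5, 2.5, 1.5))
  })
  tex_rand <- tex_rand / max(stats::sd(tex_rand), 1e-12)
  texture <- 1 + cfg$texture_amp * (tex_det + tex_rand)

  # total proton signal per compartment (a.u.)
  total <- 0.6 * texture
  total[vein] <- 0.35
  total[lumen] <- 0.30
  total[wall] <- 1.0
  ff <- array(cfg$background_ff, shp)
  ff[lumen | vein] <- cfg$blood_ff
  ff[wall] <- cfg$wall_ff
  ff[plaque] <- cfg$plaque_ff
  ff[lipid] <- cfg$lipid_ff
  r2 <- array(cfg$background_r2star, shp)
  r2[lumen | vein] <- cfg$blood_r2star
  r2[wall] <- cfg$wall_r2star
  r2[plaque] <- cfg$plaque_r2star
  r2[hem] <- cfg$hemorrhage_r2star

  water <- (1 - ff) * total
  fat <- ff * total

  act <- array(cfg$background_activity, shp)
  act[wall] <- cfg$wall_activity
  act[plaque] <- cfg$plaque_activity
  act[lumen | vein] <- cfg$blood_activity

  # anatomical (T1W-like) contrast
  t1w <- 0.55 * texture
  t1w[vein] <- 0.35
  t1w[lumen] <- 0.20
  t1w[wall] <- 1.0
  t1w[plaque] <- 1.2
  t1w[lipid] <- 1.45

  # six venous blood-pool sample points along the vein (phantom frame, mm)
  bp_slices <- round(seq(4, shp[3] - 3, length.out = 6))
  blood_points <- cbind(cfg$vein_center[1], cfg$vein_center[2],
                        grid$origin[3] + (bp_slices - 1) * grid$voxel_size[3])

  mask <- as_mask(plaque, grid)
  if (cfg$plaque_angle_extent <= 0 || sum(plaque) == 0)
    attr(mask, "degenerate") <- TRUE

  structure(list(
    water_map = as_volume(water, grid),
    fat_map = as_volume(fat, grid),
    r2star_map = as_volume(r2, grid),
    activity_map = as_volume(act, grid),
    t1w_map = as_volume(t1w, grid),
    plaque_mask_true = mask,
    session_transform_true = cfg$session_transform,
    grid = grid,
    blood_activity = cfg$blood_activity,
    body_weight = cfg$body_weight,
    injected_dose = cfg$dose_per_kg * cfg$body_weight,
    bifurcation_slice = cfg$bifurcation_slice,
    blood_points = blood_points,
    seed = seed,
    config = cfg
  ), class = "pf_phantom")
}

#' @export
print.pf_phantom <- function(x, ...) {
  cat(sprintf(paste0("<pf_phantom> %s, plaque %d voxels%s, weight %.0f kg, ",
                     "dose %.0f MBq\n"),
              format(x$grid), sum(x$plaque_mask_true$data),
              if (isTRUE(attr(x$plaque_mask_true, "degenerate")))
                " (degenerate)" else "",
              x$body_weight, x$injected_dose))
  invisible(x)
}

#' Render the 4-echo Dixon acquisition of a phantom
#'
#' Evaluates the forward signal model per voxel and echo and adds Rician
#' noise: independent Gaussian noise on two quadrature channels followed by
#' the magnitude, the noise model appropriate for magnitude MRI data.
#' `noise_sd = 0` returns the exact forward model.
#'
#' @param truth a [make_phantom()] object.
#' @param noise_sd channel noise standard deviation (a.u.), >= 0.
#' @param seed integer seed for the noise stream.
#' @param tes echo times in ms.
#' @return A [dixon_series()].
#' @export
render_dixon <- function(truth, noise_sd = 0, seed = 1,
                         tes = c(3.6, 7.2, 10.8, 14.4)) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  grid <- truth$grid
  w <- as.numeric(truth$water_map$data)
  f <- as.numeric(truth$fat_map$data)
  r2 <- as.numeric(truth$r2star_map$data)
  vols <- with_phantom_seed(seed, {
    lapply(tes, function(te) {
      s <- abs((w + f * fat_phase(te)) * exp(-r2 * te / 1000))
      s <- add_rician(s, noise_sd)
      as_volume(array(s, grid$shape), grid)
    })
  })
  dixon_series(vols, tes)
}

default_t1w_grid <- function(truth, session) {
  vox <- switch(session,
                standalone = c(0.50, 0.50, 1.75),
                petmr = c(0.31, 0.31, 2.5))
  fov <- truth$grid$shape * truth$grid$voxel_size
  shape <- pmax(ceiling(fov / vox), 1)
  grid_geometry(shape, vox, -(shape - 1) / 2 * vox)
}

#' Render a T1-weighted volume of the phantom
#'
#' The stand-alone MRI session samples the phantom frame directly on a
#' 0.50 x 0.50 x 1.75 mm grid; the PET/MRI session samples on a
#' 0.31 x 0.31 x 2.5 mm grid and is misaligned from the phantom frame by
#' exactly the phantom's session transform, emulating the unknown patient
#' repositioning between scanners.
#'
#' @param truth a [make_phantom()] object.
#' @param session `"standalone"` or `"petmr"`.
#' @param grid optional target [grid_geometry()]; defaults to the session's
#'   acquisition grid covering the phantom field of view.
#' @return `pf_volume` on the requested grid, with attributes `session` and
#'   `landmark_slice` (the bifurcation landmark mapped to this grid).
#' @export
render_t1w <- function(truth, session = c("standalone", "petmr"), grid = NULL) {
  session <- match.arg(session)
  if (is.null(grid)) grid <- default_t1w_grid(truth, session)
  tf <- if (session == "petmr") invert_transform(truth$session_transform_true)
        else NULL
  out <- resample_volume(truth$t1w_map, grid, transform = tf,
                         interpolation = "linear", fill = 0)
  # bifurcation landmark slice in the output grid
  zb_phantom <- truth$grid$origin[3] +
    (truth$bifurcation_slice - 1) * truth$grid$voxel_size[3]
  zb <- if (session == "petmr") {
    apply_transform(truth$session_transform_true,
                    c(0, 0, zb_phantom))[3]
  } else zb_phantom
  attr(out, "session") <- session
  attr(out, "landmark_slice") <-
    round((zb - grid$origin[3]) / grid$voxel_size[3]) + 1
  out
}

#' Render the PET acquisition of a phantom
#'
#' Convolves the true activity map with an isotropic Gaussian point-spread
#' function of the given FWHM (default 3 mm, the effective neck resolution),
#' resamples onto the PET grid (1.2 mm in-plane, 2.78 mm slices) in the
#' PET-session frame, and adds Gaussian noise. Metadata carries the injected
#' dose (3 MBq/kg by default) and body weight.
#'
#' @param truth a [make_phantom()] object.
#' @param psf_fwhm_mm point-spread FWHM in mm, > 0.
#' @param noise_sd Gaussian noise SD in kBq/mL.
#' @param seed integer seed for the noise stream.
#' @param apply_session_transform sample in the PET-session frame (default);
#'   set FALSE to render in the phantom frame.
#' @return A [pet_study()].
#' @export
render_pet <- function(truth, psf_fwhm_mm = 3.0, noise_sd = 0, seed = 1,
                       apply_session_transform = TRUE) {
  if (psf_fwhm_mm <= 0) stop("psf_fwhm_mm must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  sigma_mm <- psf_fwhm_mm / (2 * sqrt(2 * log(2)))
  sigma_vox <- sigma_mm / truth$grid$voxel_size
  blurred <- gaussian_blur_array(truth$activity_map$data, sigma_vox)
  bvol <- as_volume(blurred, truth$grid)

  fov <- truth$grid$shape * truth$grid$voxel_size
  vox <- c(1.2, 1.2, 2.78)
  shape <- pmax(ceiling(fov / vox), 1)
  pet_grid <- grid_geometry(shape, vox, -(shape - 1) / 2 * vox)
  tf <- if (apply_session_transform)
    invert_transform(truth$session_transform_true) else NULL
  act <- resample_volume(bvol, pet_grid, transform = tf,
                         interpolation = "linear", fill = 0)
  act$data <- with_phantom_seed(seed, {
    act$data + array(stats::rnorm(prod(pet_grid$shape), 0, noise_sd),
                     pet_grid$shape)
  })
  act$data[act$data < 0] <- 0
  pet_study(act, injected_dose = truth$injected_dose,
            body_weight = truth$body_weight, uptake_time = 90)
}

# separable Gaussian blur of a 3D array; sigma in voxels per axis,
# zero-padded edges, kernel normalized to unit sum
gaussian_blur_array <- function(a, sigma_vox) {
  shp <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    rad <- max(1L, ceiling(3 * s))
    x <- (-rad):rad
    k <- exp(-x^2 / (2 * s^2))
    k <- k / sum(k)
    n <- shp[ax]
    K <- matrix(0, n, n)
    for (j in seq_along(x)) {
      idx <- seq_len(n) + x[j]
      ok <- idx >= 1 & idx <= n
      K[cbind(which(ok), idx[ok])] <- K[cbind(which(ok), idx[ok])] + k[j]
    }
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- K %*% matrix(ap, nrow = dp[1])
    a <- aperm(array(m, dp), order(perm))
  }
  a
}
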