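#' Draw a random similarity transform
#'
#' Uniform translation, rotation and scale perturbations, used to emulate
#' patient repositioning between sessions and to probe registration
#' recovery.
#'
#' @param seed integer seed.
#' @param max_translation mm, per axis.
#' @param max_rotation degrees, per axis.
#' @param scale_range range of the isotropic scale factor.
#' @param center rotation centre (world mm).
#' @return A [similarity_transform()].
#' @export
random_similarity <- function(seed, max_translation = 5, max_rotation = 5,
                              scale_range = c(0.95, 1.05),
                              center = c(0, 0, 0)) {
  with_phantom_seed(seed, {
    similarity_transform(
      translation = stats::runif(3, -max_translation, max_translation),
      rotation = stats::runif(3, -max_rotation, max_rotation),
      scale = stats::runif(1, scale_range[1], scale_range[2]),
      center = center)
  })
}

subject_seed <- function(seed, i, salt = 0L) {
  as.integer((as.numeric(seed) * 1009 + i * 97 + salt) %% 2147483647)
}

#' Draw a per-subject phantom configuration
#'
#' Emulates the heterogeneity of real plaques: lipid-core fat fraction,
#' hemorrhage R2*, plaque length and position, body weight and the
#' between-session transform all vary between subjects. Tracer uptake is
#' drawn independently of composition, so a simulated cohort carries no
#' built-in composition-inflammation correlation.
#'
#' @param seed integer seed.
#' @return A [phantom_config()].
#' @export
random_phantom_config <- function(seed) {
  with_phantom_seed(seed, {
    start <- sample(5:8, 1)
    len <- sample(10:15, 1)
    lipid_lo <- start + 2
    lipid_hi <- min(start + len - 2, lipid_lo + 7)
    hem_lo <- start + 4
    hem_hi <- min(start + len - 1, hem_lo + 7)
    phantom_config(
      lipid_ff = stats::runif(1, 0.15, 0.45),
      hemorrhage_r2star = stats::runif(1, 70, 110),
      plaque_slices = c(start, start + len - 1),
      lipid_slices = c(lipid_lo, lipid_hi),
      hemorrhage_slices = c(hem_lo, hem_hi),
      plaque_activity = stats::runif(1, 3.5, 8.0),
      body_weight = stats::runif(1, 65, 95),
      plaque_angle_extent = stats::runif(1, 110, 170),
      session_transform = similarity_transform(
        translation = c(stats::runif(2, -2, 2), stats::runif(1, -1, 1)),
        rotation = c(stats::runif(2, -1, 1), stats::runif(1, -3, 3)),
        scale = stats::runif(1, 0.98, 1.02)))
  })
}

#' Run the full composition-versus-uptake analysis for one phantom subject
#'
#' Renders the Dixon series and the PET study from a phantom, inverts the
#' Dixon model under the plaque mask, applies masked neighbour averaging and
#' slice sampling, transfers the mask onto the PET grid, computes SUV and
#' blood-pool values and the TBR, and joins composition to uptake slice by
#' slice via the bifurcation landmark.
#'
#' @param truth a [make_phantom()] object.
#' @param subject subject label.
#' @param dixon_noise_sd Rician channel noise for the Dixon rendering
#'   (default 0.02, i.e. 2% of the unit wall signal).
#' @param pet_noise_sd Gaussian noise for the PET rendering, kBq/mL.
#' @param seed integer seed for the noise streams.
#' @param session_transform transform used to move between the phantom and
#'   PET-session frames; defaults to the ground truth (pass an estimate from
#'   [register_similarity()] to exercise the registration path).
#' @return list with `roi` (per-slice tibble: subject, slice_id, n_voxels,
#'   ff_mean, r2star_mean, pet_slice, suv_mean, suv_max, tbr) and `summary`
#'   (one-row tibble with whole-plaque ff/r2star means, plaque SUV mean/max,
#'   blood SUV and TBR).
#' @export
analyze_subject <- function(truth, subject = "S1", dixon_noise_sd = 0.02,
                            pet_noise_sd = 0.1, seed = 1,
                            session_transform = NULL) {
  if (is.null(session_transform)) session_transform <- truth$session_transform_true
  mask <- truth$plaque_mask_true

  series <- render_dixon(truth, noise_sd = dixon_noise_sd, seed = seed)
  comp <- fit_volume(series, mask = mask)
  rtab <- roi_table(comp, mask, subject = subject)

  pet <- render_pet(truth, psf_fwhm_mm = 3.0, noise_sd = pet_noise_sd,
                    seed = subject_seed(seed, 1, salt = 13L))
  suv <- suv_map(pet)
  mask_pet <- apply_to_mask(mask, invert_transform(session_transform),
                            suv$grid)
  ps <- plaque_suv(suv, mask_pet)
  blood_pts <- apply_transform(session_transform, truth$blood_points)
  suv_blood <- blood_pool_suv(suv, blood_pts)
  tbr_val <- tbr(attr(ps, "suv_mean_plaque"), suv_blood)

  # slice correspondence Dixon -> PET via the bifurcation landmark
  zb <- apply_transform(session_transform,
                        c(0, 0, truth$grid$origin[3] +
                            (truth$bifurcation_slice - 1) *
                            truth$grid$voxel_size[3]))[3]
  lm_pet <- round((zb - suv$grid$origin[3]) / suv$grid$voxel_size[3]) + 1
  lm_pet <- min(max(lm_pet, 1), suv$grid$shape[3])
  corr <- align_slices(truth$water_map, suv, truth$bifurcation_slice, lm_pet)

  roi <- dplyr::left_join(rtab,
                          dplyr::select(corr, "source_slice", "target_slice"),
                          by = c(slice_id = "source_slice"))
  roi <- dplyr::rename(roi, pet_slice = "target_slice")
  roi <- dplyr::left_join(roi,
                          dplyr::select(ps, "slice_id", "suv_mean", "suv_max"),
                          by = c(pet_slice = "slice_id"))
  roi <- dplyr::mutate(roi, tbr = .data$suv_mean / suv_blood)

  summary <- tibble::tibble(
    subject = subject,
    n_slices = nrow(rtab),
    ff_mean = attr(rtab, "ff_mean_whole"),
    r2star_mean = attr(rtab, "r2star_mean_whole"),
    suv_mean_plaque = attr(ps, "suv_mean_plaque"),
    suv_max_plaque = attr(ps, "suv_max_plaque"),
    suv_mean_blood = suv_blood,
    tbr = tbr_val)
  list(roi = roi, summary = summary)
}

#' Simulate and analyse a synthetic patient cohort
#'
#' Builds `n_subjects` heterogeneous plaque phantoms (see
#' [random_phantom_config()]), runs the full pipeline on each, and stacks
#' the per-slice and per-subject results. Uptake is generated independently
#' of composition, so the cohort is a null model for the
#' composition-inflammation correlation.
#'
#' @param n_subjects number of subjects (default 12, the pilot-study size).
#' @param seed integer master seed; all per-subject randomness derives from
#'   it.
#' @param ... passed on to [analyze_subject()].
#' @return list with `roi` (slice-level tibble) and `summary`
#'   (subject-level tibble).
#' @export
simulate_cohort <- function(n_subjects = 12, seed = 1, ...) {
  res <- purrr::map(seq_len(n_subjects), function(i) {
    cfg <- random_phantom_config(subject_seed(seed, i))
    truth <- make_phantom(cfg, seed = subject_seed(seed, i, salt = 1L))
    analyze_subject(truth, subject = sprintf("S%02d", i),
                    seed = subject_seed(seed, i, salt = 2L), ...)
  })
  list(roi = dplyr::bind_rows(purrr::map(res, "roi")),
       summary = dplyr::bind_rows(purrr::map(res, "summary")))
}

#' Group-level correlations between uptake and plaque composition
#'
#' Pearson correlation (with t-based two-sided p-values and regression
#' lines) of per-subject TBR against whole-plaque mean fat fraction and
#' mean R2*.
#'
#' @param summary subject-level tibble from [simulate_cohort()] (columns
#'   `tbr`, `ff_mean`, `r2star_mean`).
#' @return tibble with one row per composition measure.
#' @export
correlate_group <- function(summary) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(pearson(x = summary$ff_mean, y = summary$tbr)),
                  measure = "ff_mean", .before = 1),
    dplyr::mutate(tidy(pearson(x = summary$r2star_mean, y = summary$tbr)),
                  measure = "r2star_mean", .before = 1))
}
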