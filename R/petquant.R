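#' PET study: activity volume plus dosing metadata
#'
#' @param activity `pf_volume` of activity concentration, kBq/mL, >= 0.
#' @param injected_dose MBq, > 0.
#' @param body_weight kg, > 0.
#' @param uptake_time minutes between injection and acquisition (metadata
#'   only; SUVs are assumed decay-corrected by the scanner).
#' @return Object of class `pf_pet_study`.
#' @export
pet_study <- function(activity, injected_dose, body_weight, uptake_time = 90) {
  if (missing(injected_dose) || is.null(injected_dose) || !is.finite(injected_dose) ||
      injected_dose <= 0)
    stop("injected_dose (MBq) is required and must be positive")
  if (missing(body_weight) || is.null(body_weight) || !is.finite(body_weight) ||
      body_weight <= 0)
    stop("body_weight (kg) is required and must be positive")
  if (any(activity$data < 0, na.rm = TRUE))
    stop("activity must be non-negative")
  structure(list(activity = activity, grid = activity$grid,
                 injected_dose = injected_dose, body_weight = body_weight,
                 uptake_time = uptake_time),
            class = "pf_pet_study")
}

#' @export
print.pf_pet_study <- function(x, ...) {
  cat(sprintf("<pf_pet_study> %s, dose %.1f MBq, weight %.1f kg, uptake %g min\n",
              format(x$grid), x$injected_dose, x$body_weight, x$uptake_time))
  invisible(x)
}

#' Standardized uptake value map
#'
#' SUV = activity concentration / (injected dose / body weight). With
#' activity in kBq/mL, dose in MBq and weight in kg the units cancel under
#' the 1 g/mL tissue-density convention: MBq/kg equals kBq/g equals kBq/mL.
#'
#' @param study a [pet_study()].
#' @return dimensionless `pf_volume`.
#' @examples
#' # activity 2.0 kBq/mL, 225 MBq in a 75 kg subject -> SUV 0.667
#' @export
suv_map <- function(study) {
  scale <- study$injected_dose / study$body_weight  # kBq/mL at uniform dilution
  as_volume(study$activity$data / scale, study$grid)
}

#' Plaque SUV summaries per slice and whole plaque
#'
#' Per slice, the mean and maximum SUV over in-mask voxels. The whole-plaque
#' SUV mean is the unweighted mean of the per-slice means — slice ROI means
#' are computed first, then averaged — and the whole-plaque maximum is the
#' maximum over slices. A voxel-weighted whole-plaque mean is available via
#' `slice_then_average = FALSE`.
#'
#' @param suv dimensionless `pf_volume` from [suv_map()].
#' @param mask a `pf_mask` already resampled onto the PET grid.
#' @param slice_then_average average the slice means (default) rather than
#'   the voxels.
#' @return tibble of per-slice rows (`slice_id`, `n_voxels`, `suv_mean`,
#'   `suv_max`) with attributes `suv_mean_plaque` and `suv_max_plaque`.
#' @export
plaque_suv <- function(suv, mask, slice_then_average = TRUE) {
  if (!grids_equal(suv$grid, mask$grid))
    stop("mask must be on the PET grid; resample it first")
  if (sum(mask$data) == 0) stop("empty mask on the PET grid")
  ids <- mask_slice_ids(mask)
  out <- dplyr::bind_rows(purrr::map(ids, function(k) {
    v <- suv$data[, , k][mask$data[, , k] > 0]
    tibble::tibble(slice_id = k, n_voxels = length(v),
                   suv_mean = mean(v), suv_max = max(v))
  }))
  attr(out, "suv_mean_plaque") <- if (slice_then_average) mean(out$suv_mean)
    else mean(suv$data[mask$data > 0])
  attr(out, "suv_max_plaque") <- max(out$suv_max)
  out
}

#' Venous blood-pool SUV from six sample points
#'
#' The blood-pool SUV is the mean of the SUV at exactly six points in the
#' venous blood pool, each read from the nearest voxel.
#'
#' @param suv dimensionless `pf_volume`.
#' @param points 6 x 3 matrix of world coordinates (mm).
#' @return scalar blood-pool SUV mean.
#' @export
blood_pool_suv <- function(suv, points) {
  points <- rbind_coords(points)
  if (nrow(points) != 6) stop("exactly 6 blood-pool sample points are required")
  idx <- round(world_to_grid(suv$grid, points))
  if (any(idx < 1) || any(sweep(idx, 2, suv$grid$shape, `>`)))
    stop("blood-pool point outside the PET volume")
  mean(suv$data[idx])
}

#' Target-to-blood-pool ratio
#'
#' TBR = plaque SUV mean / venous blood-pool SUV mean.
#'
#' @param suv_mean_plaque whole-plaque SUV mean.
#' @param suv_mean_blood venous blood-pool SUV mean, > 0.
#' @return scalar TBR (vectorized over inputs).
#' @examples
#' tbr(2.13, 1.33)  # 1.60
#' @export
tbr <- function(suv_mean_plaque, suv_mean_blood) {
  if (any(!is.finite(suv_mean_blood)) || any(suv_mean_blood <= 0))
    stop("blood-pool SUV mean must be positive")
  suv_mean_plaque / suv_mean_blood
}

#' Reference FDG-uptake cohort
#'
#' Published intraplaque FDG uptake measurements from a 12-patient carotid
#' pilot cohort: per patient, the plaque SUV max and SUV mean, the printed
#' TBR, and the inferior vena cava (venous blood pool) SUV max and SUV mean.
#' Shipped as plain CSV in `extdata`; useful for desk-checking the TBR
#' arithmetic and the group summary statistics.
#'
#' @return tibble with columns `patient`, `suv_max_plaque`,
#'   `suv_mean_plaque`, `tbr_printed`, `suv_max_blood`, `suv_mean_blood`.
#' @export
fdg_uptake_cohort <- function() {
  path <- system.file("extdata", "fdg_uptake_cohort.csv",
                      package = "plaquefusion", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
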