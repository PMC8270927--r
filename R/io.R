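grid_affine <- function(grid) {
  aff <- diag(4)
  aff[1, 1] <- grid$voxel_size[1]
  aff[2, 2] <- grid$voxel_size[2]
  aff[3, 3] <- grid$voxel_size[3]
  aff[1:3, 4] <- grid$origin
  aff
}

#' Read and write volumes as NIfTI-1
#'
#' Volumes are written with an axis-aligned affine carrying the voxel size
#' and origin; `read_volume` expects such an affine (rotated NIfTI data
#' should be resampled outside the package first).
#'
#' @param volume a `pf_volume`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   `pf_volume`.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$grid$voxel_size
  RNifti::qform(img) <- structure(grid_affine(volume$grid), code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-4 * max(abs(diag(rot))))
    stop("only axis-aligned NIfTI affines are supported")
  d <- dim(img)
  grid <- grid_geometry(d, abs(diag(rot)), aff[1:3, 4])
  as_volume(array(as.numeric(img), dim = d), grid)
}

#' Read and write a Dixon series as NIfTI volumes plus a JSON sidecar
#'
#' One NIfTI file per echo (`echo_1.nii.gz`, ...) plus `echo_times.json`
#' listing the echo times in ms.
#'
#' @param series a [dixon_series()].
#' @param dir output directory (created if needed).
#' @return `write_dixon_series` returns `dir` invisibly; `read_dixon_series`
#'   returns a [dixon_series()].
#' @export
write_dixon_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(series$tes))
    write_volume(series$volumes[[i]],
                 file.path(dir, sprintf("echo_%d.nii.gz", i)))
  jsonlite::write_json(list(echo_times_ms = series$tes),
                       file.path(dir, "echo_times.json"), digits = NA)
  invisible(dir)
}

#' @rdname write_dixon_series
#' @export
read_dixon_series <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "echo_times.json"),
                              simplifyVector = TRUE)
  tes <- meta$echo_times_ms
  vols <- lapply(seq_along(tes), function(i)
    read_volume(file.path(dir, sprintf("echo_%d.nii.gz", i))))
  dixon_series(vols, tes)
}

#' Read and write a PET study as NIfTI plus a JSON sidecar
#'
#' The sidecar carries injected dose (MBq), body weight (kg) and uptake
#' time (min).
#'
#' @param study a [pet_study()].
#' @param dir output directory.
#' @return `write_pet_study` returns `dir` invisibly; `read_pet_study`
#'   returns a [pet_study()].
#' @export
write_pet_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(study$activity, file.path(dir, "pet.nii.gz"))
  jsonlite::write_json(list(injected_dose_MBq = study$injected_dose,
                            body_weight_kg = study$body_weight,
                            uptake_time_min = study$uptake_time),
                       file.path(dir, "pet_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_pet_study
#' @export
read_pet_study <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "pet_meta.json"),
                              simplifyVector = TRUE)
  pet_study(read_volume(file.path(dir, "pet.nii.gz")),
            injected_dose = meta$injected_dose_MBq,
            body_weight = meta$body_weight_kg,
            uptake_time = meta$uptake_time_min)
}
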