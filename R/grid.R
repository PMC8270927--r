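#' Grid geometry for a volumetric image
#'
#' Describes the sampling lattice of a 3D volume: voxels per axis, voxel size
#' in millimetres and the world position of the first voxel centre. Axis order
#' is fixed as (x, y, slice); the slice axis is the vessel axis.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param voxel_size numeric vector of length 3, mm per axis (all > 0).
#' @param origin numeric vector of length 3, world mm of the centre of voxel
#'   (1, 1, 1). Defaults to zero.
#' @return An object of class `pf_grid`.
#' @examples
#' grid_geometry(c(48, 48, 24), c(0.6, 0.6, 0.7))
#' @export
grid_geometry <- function(shape, voxel_size, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3L, length(voxel_size) == 3L, length(origin) == 3L)
  if (any(shape < 1L)) stop("grid shape must be at least 1 voxel per axis")
  if (any(voxel_size <= 0)) stop("voxel_size must be positive on all axes")
  structure(list(shape = shape, voxel_size = voxel_size, origin = origin),
            class = "pf_grid")
}

#' @export
print.pf_grid <- function(x, ...) {
  cat(sprintf("<pf_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' @export
format.pf_grid <- function(x, ...) {
  sprintf("%dx%dx%d @ %.3g/%.3g/%.3g mm",
          x$shape[1], x$shape[2], x$shape[3],
          x$voxel_size[1], x$voxel_size[2], x$voxel_size[3])
}

grids_equal <- function(a, b, tol = 1e-8) {
  all(a$shape == b$shape) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' World coordinates of voxel centres
#'
#' Converts 1-based voxel indices to world millimetres (`grid_to_world`) and
#' back (`world_to_grid`, returning continuous indices).
#'
#' @param grid a [grid_geometry()] object.
#' @param idx,xyz numeric matrix (n x 3) or length-3 vector.
#' @return n x 3 numeric matrix.
#' @export
grid_to_world <- function(grid, idx) {
  idx <- rbind_coords(idx)
  sweep(sweep(idx - 1, 2, grid$voxel_size, `*`), 2, grid$origin, `+`)
}

#' @rdname grid_to_world
#' @export
world_to_grid <- function(grid, xyz) {
  xyz <- rbind_coords(xyz)
  sweep(sweep(xyz, 2, grid$origin, `-`), 2, grid$voxel_size, `/`) + 1
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3) else
    matrix(as.numeric(x), ncol = 3, dimnames = NULL)
}

grid_center_world <- function(grid) {
  grid$origin + (grid$shape - 1) / 2 * grid$voxel_size
}

#' Volumetric image on a grid
#'
#' A minimal container pairing a 3D numeric array with its [grid_geometry()].
#'
#' @param data 3D numeric array matching `grid$shape`.
#' @param grid a [grid_geometry()].
#' @return Object of class `pf_volume`.
#' @export
as_volume <- function(data, grid) {
  data <- as.array(data)
  if (!identical(dim(data), NULL) && length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  if (!all(dim(data) == grid$shape))
    stop("array dimensions do not match grid shape")
  structure(list(data = data, grid = grid), class = "pf_volume")
}

#' @export
print.pf_volume <- function(x, ...) {
  rng <- range(x$data, finite = TRUE)
  cat(sprintf("<pf_volume> %s, range [%.4g, %.4g]\n", format(x$grid), rng[1], rng[2]))
  invisible(x)
}

#' Binary plaque mask on a grid
#'
#' @param data logical/0-1 3D array.
#' @param grid a [grid_geometry()].
#' @return Object of class `pf_mask` (also a `pf_volume`); attribute
#'   `degenerate` is TRUE when the mask is empty.
#' @export
as_mask <- function(data, grid) {
  v <- as_volume(array(as.numeric(data != 0), dim = grid$shape), grid)
  class(v) <- c("pf_mask", class(v))
  attr(v, "degenerate") <- sum(v$data) == 0
  v
}

#' @export
print.pf_mask <- function(x, ...) {
  cat(sprintf("<pf_mask> %s, %d voxels%s\n", format(x$grid), sum(x$data),
              if (isTRUE(attr(x, "degenerate"))) " (degenerate: empty)" else ""))
  invisible(x)
}

#' Slice indices of a mask that contain at least one voxel
#' @param mask a [as_mask()] object.
#' @return integer vector of slice indices along the vessel axis.
#' @export
mask_slice_ids <- function(mask) {
  counts <- apply(mask$data, 3, sum)
  which(counts > 0)
}

#' Resample a volume onto a target grid
#'
#' Pulls values from `volume` at the target voxel centres mapped through
#' `transform` (a [similarity_transform()], interpreted as target-world to
#' source-world; identity when `NULL`).
#'
#' @param volume a `pf_volume`.
#' @param target a [grid_geometry()].
#' @param transform optional [similarity_transform()].
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill value for points falling outside `volume` (default `NA`).
#' @return `pf_volume` on `target`.
#' @export
resample_volume <- function(volume, target, transform = NULL,
                            interpolation = c("linear", "nearest"), fill = NA_real_) {
  interpolation <- match.arg(interpolation)
  if (is.null(transform)) transform <- identity_transform()
  mt <- transform_matrix(transform)
  out <- affine_resample_cpp(
    as.numeric(volume$data), volume$grid$shape, volume$grid$voxel_size,
    volume$grid$origin, target$shape, target$voxel_size, target$origin,
    mt$M, mt$offset, as.integer(interpolation == "nearest"), fill)
  as_volume(array(out, dim = target$shape), target)
}
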