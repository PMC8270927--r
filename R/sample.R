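neighbour_offsets <- function(connectivity = 26, include_self = TRUE) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  l1 <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = l1 <= 1,
                 "18" = l1 <= 2,
                 "26" = rep(TRUE, nrow(g)),
                 stop("connectivity must be 6, 18 or 26"))
  g <- g[keep, , drop = FALSE]
  if (!include_self) g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), , drop = FALSE]
  as.matrix(g)
}

#' Masked neighbourhood averaging of a map
#'
#' Replaces each in-mask voxel by the mean of the map over its immediate
#' neighbours that are themselves inside the mask. "Immediate neighbours" is
#' read as the 26-connected neighbourhood including the voxel itself
#' (configurable: 6/18/26-connectivity, with or without self). An isolated
#' in-mask voxel keeps its own value when self-inclusion is on; with
#' self-inclusion off it also falls back to its own value, there being no
#' neighbours to average. Out-of-mask voxels are undefined (NA) in the output.
#'
#' @param map a `pf_volume`.
#' @param mask a `pf_mask` on the same grid.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param include_self include the centre voxel in its own average (default
#'   TRUE).
#' @return `pf_volume` with values only inside the mask.
#' @export
neighborhood_average <- function(map, mask, connectivity = 26,
                                 include_self = TRUE) {
  if (!grids_equal(map$grid, mask$grid))
    stop("map and mask must share a grid")
  offs <- neighbour_offsets(connectivity, include_self)
  shp <- map$grid$shape
  m <- (mask$data > 0) & is.finite(map$data)  # usable neighbours
  vals <- map$data
  vals[!m] <- 0
  acc <- array(0, shp)
  cnt <- array(0, shp)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    sx <- seq_len(shp[1]); sy <- seq_len(shp[2]); sz <- seq_len(shp[3])
    dx <- sx + o[1]; dy <- sy + o[2]; dz <- sz + o[3]
    okx <- dx >= 1 & dx <= shp[1]
    oky <- dy >= 1 & dy <= shp[2]
    okz <- dz >= 1 & dz <= shp[3]
    contrib <- vals[dx[okx], dy[oky], dz[okz], drop = FALSE] *
      m[dx[okx], dy[oky], dz[okz], drop = FALSE]
    acc[sx[okx], sy[oky], sz[okz]] <- acc[sx[okx], sy[oky], sz[okz]] + contrib
    cnt[sx[okx], sy[oky], sz[okz]] <- cnt[sx[okx], sy[oky], sz[okz]] +
      m[dx[okx], dy[oky], dz[okz], drop = FALSE]
  }
  out <- array(NA_real_, shp)
  inm <- which(m)
  out[inm] <- ifelse(cnt[inm] > 0, acc[inm] / cnt[inm], vals[inm])
  as_volume(out, map$grid)
}

#' Per-slice means of a map under a mask
#'
#' Unweighted mean over in-mask voxels of each slice along the vessel axis;
#' slices without mask voxels are absent from the output. NA map values
#' (e.g. out-of-mask voxels of a neighbourhood-averaged map) are ignored.
#'
#' @param map a `pf_volume`.
#' @param mask a `pf_mask` on the same grid.
#' @return tibble with columns `slice_id`, `n_voxels`, `mean`; attribute
#'   `empty` flags an empty mask.
#' @export
slice_means <- function(map, mask) {
  if (!grids_equal(map$grid, mask$grid)) stop("map and mask must share a grid")
  ids <- mask_slice_ids(mask)
  rows <- purrr::map(ids, function(k) {
    sel <- mask$data[, , k] > 0
    v <- map$data[, , k][sel]
    tibble::tibble(slice_id = k, n_voxels = sum(sel),
                   mean = mean(v, na.rm = TRUE))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "empty") <- nrow(out) == 0
  out
}

#' Whole-mask mean of a map
#'
#' Unweighted (voxel-weighted) mean over all in-mask voxels. This is the
#' natural reading of a whole-mask average; the alternative — the mean of the
#' per-slice means, which weights slices equally — is available with
#' `slice_weighted = TRUE`. The two agree when every slice holds the same
#' number of mask voxels.
#'
#' @param map a `pf_volume`.
#' @param mask a `pf_mask` on the same grid.
#' @param slice_weighted average slice means instead of voxels.
#' @return scalar; `NA` (flagged by a warning) for an empty mask.
#' @export
whole_mask_mean <- function(map, mask, slice_weighted = FALSE) {
  if (!grids_equal(map$grid, mask$grid)) stop("map and mask must share a grid")
  if (sum(mask$data) == 0) {
    warning("empty mask: whole-mask mean undefined")
    return(NA_real_)
  }
  if (slice_weighted) {
    mean(slice_means(map, mask)$mean)
  } else {
    mean(map$data[mask$data > 0], na.rm = TRUE)
  }
}

#' Slice-wise composition table of a plaque
#'
#' Applies the masked neighbour-averaging rule to the fat-fraction and R2*
#' maps and tabulates per-slice and whole-plaque means — the unit of the
#' downstream statistical analysis.
#'
#' @param composition a `pf_composition` from [fit_volume()].
#' @param mask a `pf_mask` on the composition grid.
#' @param subject subject identifier for the table.
#' @param neighbor_average apply [neighborhood_average()] first (default
#'   TRUE, the pipeline order).
#' @param connectivity,include_self passed to [neighborhood_average()].
#' @return tibble with columns `subject`, `slice_id`, `n_voxels`, `ff_mean`,
#'   `r2star_mean`; attributes `ff_mean_whole` and `r2star_mean_whole` carry
#'   the whole-mask averages.
#' @export
roi_table <- function(composition, mask, subject = "S1",
                      neighbor_average = TRUE, connectivity = 26,
                      include_self = TRUE) {
  ff <- composition$fat_fraction
  r2 <- composition$r2star
  if (neighbor_average) {
    ff <- neighborhood_average(ff, mask, connectivity, include_self)
    r2 <- neighborhood_average(r2, mask, connectivity, include_self)
  }
  sf <- slice_means(ff, mask)
  sr <- slice_means(r2, mask)
  out <- dplyr::left_join(
    dplyr::rename(sf, ff_mean = "mean"),
    dplyr::select(dplyr::rename(sr, r2star_mean = "mean"),
                  "slice_id", "r2star_mean"),
    by = "slice_id")
  out <- dplyr::mutate(out, subject = subject, .before = 1)
  attr(out, "ff_mean_whole") <- whole_mask_mean(ff, mask)
  attr(out, "r2star_mean_whole") <- whole_mask_mean(r2, mask)
  out
}
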