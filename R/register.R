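#' Mutual information between a fixed and a transformed moving image
#'
#' Resamples `moving` onto the grid of `fixed` through `transform` (linear
#' interpolation), bins the overlapping intensities into a `bins` x `bins`
#' joint histogram, and returns the mutual information in nats. Higher values
#' indicate better alignment. An empty overlap returns 0, the metric's worst
#' value, rather than an error.
#'
#' @param fixed,moving `pf_volume` images.
#' @param transform a [similarity_transform()] mapping fixed-world to
#'   moving-world coordinates (identity when `NULL`).
#' @param bins histogram bins per image, >= 8 (default 32).
#' @return scalar mutual information (nats).
#' @export
mattes_mi <- function(fixed, moving, transform = NULL, bins = 32) {
  if (bins < 8) stop("bins must be at least 8")
  mv <- resample_volume(moving, fixed$grid, transform = transform,
                        interpolation = "linear", fill = NA_real_)
  a <- as.numeric(fixed$data); b <- as.numeric(mv$data)
  ok <- is.finite(a) & is.finite(b)
  if (!any(ok)) return(0)
  a <- a[ok]; b <- b[ok]
  H <- joint_histogram_cpp(a, b, as.integer(bins),
                           min(a), max(a), min(b), max(b))
  mi_from_histogram(H)
}

# Overlap-penalized MI used inside the optimizer: mutual information over a
# shrinking overlap is spuriously high, so configurations keeping less than
# half of the fixed image covered are down-weighted proportionally.
mi_score <- function(fixed, moving, transform, bins) {
  mv <- resample_volume(moving, fixed$grid, transform = transform,
                        interpolation = "linear", fill = NA_real_)
  a <- as.numeric(fixed$data); b <- as.numeric(mv$data)
  ok <- is.finite(a) & is.finite(b)
  frac <- mean(ok)
  if (frac == 0) return(0)
  a <- a[ok]; b <- b[ok]
  H <- joint_histogram_cpp(a, b, as.integer(bins),
                           min(a), max(a), min(b), max(b))
  mi_from_histogram(H) * min(1, frac / 0.5)
}

mi_from_histogram <- function(H) {
  n <- sum(H)
  if (n == 0) return(0)
  p <- H / n
  px <- rowSums(p); py <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  sum(p[nz] * log(p[nz] / (px[nz[, 1]] * py[nz[, 2]])))
}

#' Default configuration for similarity registration
#'
#' @param max_iter iteration budget of the (1+1) evolutionary search.
#' @param bins mutual-information histogram bins.
#' @param init optional initial [similarity_transform()].
#' @param radius_init,grow,shrink,radius_min mutation-radius schedule in
#'   normalized parameter units: the radius grows by `grow` after an accepted
#'   mutation, shrinks by `shrink` after a rejected one, and the search stops
#'   when it falls below `radius_min`.
#' @param levels 1 (single resolution) or 2 (coarse-to-fine, the default).
#' @param restarts number of coarse-level starts; the first is the supplied
#'   (or identity) initial transform, the rest are jittered over the
#'   expected misalignment range (about 5 mm / 5 degrees).
#' @param param_scales mm / degrees / scale step corresponding to one
#'   normalized unit for the 7 parameters (3 translations, 3 rotations,
#'   1 scale).
#' @return list of settings for [register_similarity()].
#' @export
register_config <- function(max_iter = 2500, bins = 32, init = NULL,
                            radius_init = 1.0, grow = 1.05, shrink = 0.98,
                            radius_min = 1e-4, levels = 2, restarts = 20,
                            param_scales = c(0.5, 0.5, 1, 3, 3, 3, 0.01)) {
  stopifnot(levels %in% c(1, 2), restarts >= 1)
  list(max_iter = max_iter, bins = bins, init = init,
       radius_init = radius_init, grow = grow, shrink = shrink,
       radius_min = radius_min, levels = levels, restarts = restarts,
       param_scales = param_scales)
}

params_to_transform <- function(p, center) {
  similarity_transform(translation = p[1:3], rotation = p[4:6],
                       scale = exp(p[7]), center = center)
}
transform_to_params <- function(tf) {
  c(tf$translation, tf$rotation, log(tf$scale))
}

#' Similarity registration by (1+1) evolutionary search on mutual information
#'
#' Finds the nonreflective similarity transform (translation, rotation,
#' isotropic scale) maximizing the Mattes-style mutual information between
#' `fixed` and the transformed `moving`. At each iteration the current
#' 7-parameter vector is perturbed with Gaussian mutations; an improving
#' mutation is accepted and the mutation radius grows by 1.05, otherwise it
#' shrinks by 0.98. The search stops at the iteration budget or when the
#' radius falls below its floor. Deterministic given `seed`.
#'
#' With the default two-level schedule the search first runs on smoothed,
#' in-plane-downsampled copies of both images (widening the capture range),
#' then refines at full resolution from the coarse solution.
#'
#' @param fixed,moving `pf_volume` images.
#' @param seed integer seed for the mutation stream.
#' @param config a [register_config()].
#' @return A [similarity_transform()] with attributes `mi` (final metric),
#'   `iterations`, and `degenerate` (TRUE when either image is constant, in
#'   which case the identity is returned with a warning).
#' @export
register_similarity <- function(fixed, moving, seed = 1,
                                config = register_config()) {
  center <- grid_center_world(fixed$grid)
  if (stats::sd(fixed$data) == 0 || stats::sd(moving$data, na.rm = TRUE) == 0) {
    warning("degenerate (constant) image; returning identity transform")
    out <- identity_transform(center)
    attr(out, "degenerate") <- TRUE
    attr(out, "mi") <- 0
    return(out)
  }
  init <- if (is.null(config$init)) identity_transform(center) else config$init
  total_iter <- 0L

  if (config$levels == 2) {
    coarse <- function(v) {
      sm <- gaussian_blur_array(v$data, sigma_vox = c(2, 2, 0.75))
      g <- v$grid
      cg <- grid_geometry(pmax(ceiling(g$shape / c(2, 2, 1)), 1),
                          g$voxel_size * c(2, 2, 1), g$origin)
      resample_volume(as_volume(sm, g), cg)
    }
    cf <- coarse(fixed); cm <- coarse(moving)
    # multiple coarse starts guard against capture failures: the first run
    # starts from the supplied (or identity) transform, later runs from
    # randomly jittered starting points spanning the expected misalignment
    # range
    starts <- c(list(init), lapply(seq_len(max(config$restarts - 1, 0)),
                                   function(r) {
      jit <- with_phantom_seed(seed + 1000L * r, {
        list(t = stats::runif(3, -5, 5), r = stats::runif(3, -5, 5))
      })
      similarity_transform(init$translation + jit$t, init$rotation + jit$r,
                           init$scale, center)
    }))
    runs <- lapply(seq_along(starts), function(r) {
      es_search(cf, cm, starts[[r]], center, seed = seed + 31L * (r - 1L),
                config = config,
                max_iter = ceiling(config$max_iter * 0.32),
                radius_init = config$radius_init)
    })
    total_iter <- sum(vapply(runs, `[[`, integer(1), "iterations"))
    # thin slabs admit a mirror basin with the out-of-plane rotations
    # sign-flipped; pool every coarse solution with its four sign variants,
    # rank by full-resolution score, briefly refine the leaders and restart
    # the fine level from the best
    cands <- list()
    for (run in runs) {
      tf <- run$transform
      for (sg in list(c(1, 1), c(-1, 1), c(1, -1), c(-1, -1))) {
        cands[[length(cands) + 1L]] <-
          similarity_transform(tf$translation, tf$rotation * c(sg, 1),
                               tf$scale, tf$center)
      }
    }
    scores <- vapply(cands, function(tf) mi_score(fixed, moving, tf,
                                                  config$bins), numeric(1))
    top <- order(scores, decreasing = TRUE)[seq_len(min(3L, length(cands)))]
    probes <- lapply(seq_along(top), function(i) {
      es_search(fixed, moving, cands[[top[i]]], center,
                seed = seed + 100L + i, config = config,
                max_iter = 150L, radius_init = 0.25)
    })
    init <- probes[[which.max(vapply(probes, `[[`, numeric(1), "mi"))]]$transform
    total_iter <- total_iter + sum(vapply(probes, `[[`, integer(1),
                                          "iterations"))
  }

  lvl2 <- es_search(fixed, moving, init, center, seed = seed + 1L,
                    config = config,
                    max_iter = if (config$levels == 2)
                      ceiling(config$max_iter * 0.5) else config$max_iter,
                    radius_init = if (config$levels == 2)
                      config$radius_init / 2 else config$radius_init)
  out <- lvl2$transform
  attr(out, "mi") <- mattes_mi(fixed, moving, out, config$bins)
  attr(out, "iterations") <- total_iter + lvl2$iterations
  attr(out, "degenerate") <- FALSE
  out
}

# one (1+1)-ES run at a single resolution level
es_search <- function(fixed, moving, init, center, seed, config,
                      max_iter, radius_init) {
  p <- transform_to_params(init)
  scales <- config$param_scales
  best_mi <- mi_score(fixed, moving, params_to_transform(p, center),
                      config$bins)
  radius <- radius_init
  iter <- 0L
  with_phantom_seed(seed, {
    while (iter < max_iter && radius >= config$radius_min) {
      iter <- iter + 1L
      cand <- p + radius * scales * stats::rnorm(7)
      mi <- mi_score(fixed, moving, params_to_transform(cand, center),
                     config$bins)
      if (mi > best_mi) {
        best_mi <- mi
        p <- cand
        radius <- radius * config$grow
      } else {
        radius <- radius * config$shrink
      }
    }
  })
  list(transform = params_to_transform(p, center), mi = best_mi,
       iterations = iter)
}

#' Transfer a binary mask through a similarity transform
#'
#' Resamples the mask onto `target` with nearest-neighbour interpolation
#' (masks stay strictly binary). `transform` maps target-world to mask-world
#' coordinates, i.e. the transform returned by registering the target frame
#' (fixed) to the mask frame (moving). An empty result is allowed but
#' flagged degenerate.
#'
#' @param mask a `pf_mask`.
#' @param transform a [similarity_transform()] (identity when `NULL`).
#' @param target target [grid_geometry()].
#' @return `pf_mask` on `target`.
#' @export
apply_to_mask <- function(mask, transform, target) {
  v <- resample_volume(mask, target, transform = transform,
                       interpolation = "nearest", fill = 0)
  as_mask(v$data > 0.5, target)
}

#' Dice overlap coefficient of two binary masks on a common grid
#' @param a,b `pf_mask` objects on the same grid.
#' @return scalar in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  if (!grids_equal(a$grid, b$grid)) stop("masks must share a grid")
  inter <- sum(a$data > 0 & b$data > 0)
  denom <- sum(a$data > 0) + sum(b$data > 0)
  if (denom == 0) return(NA_real_)
  2 * inter / denom
}

#' Landmark-based slice correspondence between two volumes
#'
#' Maps each slice of `a` to the nearest slice of `b` by physical distance
#' from the bifurcation landmark: slice `i` of `a` sits at
#' `(i - landmark_a) * thickness_a` mm from the landmark and maps to the
#' slice of `b` whose centre is nearest in those landmark-relative
#' coordinates, ties broken toward the landmark. Source slices falling
#' outside `b`'s extent (beyond half a slice from its outermost centre) are
#' dropped; a fully non-overlapping pair yields an empty, flagged mapping.
#'
#' @param a,b `pf_volume` images (only grids are used).
#' @param landmark_a,landmark_b bifurcation slice indices in each volume.
#' @return tibble with columns `source_slice`, `target_slice`,
#'   `source_offset_mm`, `target_offset_mm`; attribute `empty` flags a
#'   non-overlapping pair.
#' @export
align_slices <- function(a, b, landmark_a, landmark_b) {
  na <- a$grid$shape[3]; nb <- b$grid$shape[3]
  if (landmark_a < 1 || landmark_a > na || landmark_b < 1 || landmark_b > nb)
    stop("landmark slice index outside the volume")
  tha <- a$grid$voxel_size[3]; thb <- b$grid$voxel_size[3]
  off_a <- (seq_len(na) - landmark_a) * tha
  off_b <- (seq_len(nb) - landmark_b) * thb

  rows <- purrr::map(seq_len(na), function(i) {
    d <- abs(off_a[i] - off_b)
    j <- which(d == min(d))
    if (length(j) > 1) j <- j[which.min(abs(j - landmark_b))]  # toward landmark
    if (min(d) > thb / 2 + 1e-9) return(NULL)  # outside target extent
    tibble::tibble(source_slice = i, target_slice = j,
                   source_offset_mm = off_a[i], target_offset_mm = off_b[j])
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "empty") <- nrow(out) == 0
  out
}
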