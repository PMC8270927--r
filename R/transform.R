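#' Nonreflective similarity transform
#'
#' A rigid transform plus isotropic scaling: a point `x` (world mm) maps to
#' `s * R %*% (x - center) + center + translation`, where `R` is the rotation
#' built from the three Euler angles (degrees, applied x, then y, then z) and
#' `s > 0` is the isotropic scale. `scale > 0` makes the transform
#' nonreflective by construction.
#'
#' @param translation numeric length 3, mm per axis.
#' @param rotation numeric length 3, degrees about the x, y and slice axes.
#' @param scale isotropic scale factor, must be > 0.
#' @param center rotation/scaling centre in world mm (default origin).
#' @return Object of class `pf_transform`.
#' @examples
#' t1 <- similarity_transform(translation = c(2, -1, 0))
#' compose_transforms(t1, invert_transform(t1))  # identity
#' @export
similarity_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                                 scale = 1, center = c(0, 0, 0)) {
  stopifnot(length(translation) == 3L, length(rotation) == 3L,
            length(scale) == 1L, length(center) == 3L)
  if (!is.finite(scale) || scale <= 0)
    stop("scale must be a positive finite number (nonreflective transform)")
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation),
                 scale = as.numeric(scale),
                 center = as.numeric(center)),
            class = "pf_transform")
}

#' @rdname similarity_transform
#' @export
identity_transform <- function(center = c(0, 0, 0)) {
  similarity_transform(center = center)
}

#' @export
print.pf_transform <- function(x, ...) {
  cat(sprintf("<pf_transform> t = (%.3f, %.3f, %.3f) mm, r = (%.3f, %.3f, %.3f) deg, s = %.5f\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$rotation[1], x$rotation[2], x$rotation[3], x$scale))
  invisible(x)
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Linear form y = M x + offset of a pf_transform.
transform_matrix <- function(tf) {
  M <- tf$scale * rotation_matrix(tf$rotation)
  offset <- tf$center + tf$translation - as.numeric(M %*% tf$center)
  list(M = M, offset = offset)
}

#' Apply a similarity transform to world points
#' @param tf a [similarity_transform()].
#' @param xyz n x 3 matrix or length-3 vector of world mm.
#' @return n x 3 matrix of mapped points.
#' @export
apply_transform <- function(tf, xyz) {
  xyz <- rbind_coords(xyz)
  mt <- transform_matrix(tf)
  sweep(xyz %*% t(mt$M), 2, mt$offset, `+`)
}

# Recover (translation, rotation, scale) about `center` from y = M x + offset.
transform_from_matrix <- function(M, offset, center = c(0, 0, 0)) {
  s <- det(M)^(1 / 3)
  if (!is.finite(s) || s <= 0) stop("matrix is not a nonreflective similarity")
  R <- M / s
  # Euler angles for R = Rz Ry Rx
  ry <- asin(pmin(1, pmax(-1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-10) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  rot <- c(rx, ry, rz) * 180 / pi
  trans <- offset + as.numeric(M %*% center) - center
  similarity_transform(translation = trans, rotation = rot, scale = s,
                       center = center)
}

#' Invert or compose similarity transforms
#'
#' `invert_transform(tf)` returns the transform mapping `tf`'s outputs back to
#' its inputs; `compose_transforms(a, b)` returns the transform applying `b`
#' first, then `a`. Both preserve the similarity structure exactly.
#'
#' @param tf,a,b [similarity_transform()] objects.
#' @return A [similarity_transform()].
#' @export
invert_transform <- function(tf) {
  mt <- transform_matrix(tf)
  Minv <- solve(mt$M)
  transform_from_matrix(Minv, -as.numeric(Minv %*% mt$offset), tf$center)
}

#' @rdname invert_transform
#' @export
compose_transforms <- function(a, b) {
  ma <- transform_matrix(a); mb <- transform_matrix(b)
  M <- ma$M %*% mb$M
  offset <- as.numeric(ma$M %*% mb$offset) + ma$offset
  transform_from_matrix(M, offset, a$center)
}

#' Read / write a similarity transform as JSON
#'
#' Serialized fields: translation (mm), rotation (deg), scale, center (mm).
#'
#' @param tf a [similarity_transform()].
#' @param path file path.
#' @return `write_transform` returns `path` invisibly; `read_transform`
#'   returns the transform.
#' @export
write_transform <- function(tf, path) {
  jsonlite::write_json(unclass(tf), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  similarity_transform(x$translation, x$rotation, x$scale, x$center)
}
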