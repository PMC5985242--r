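#' Rigid transform (rotation + translation, no scaling)
#'
#' CBCT volumes image dentofacial structures at a 1:1 ratio, so every
#' alignment in the pipeline is strictly rigid: an orthonormal rotation with
#' determinant +1 plus a translation in mm. Scaling is never estimated.
#'
#' @param rotation 3x3 orthonormal matrix with det = +1 (checked to 1e-9).
#' @param translation length-3 numeric vector (mm).
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3x3")
  if (length(translation) != 3L) stop("translation must have length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal (tolerance 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation determinant is not +1 (reflections are not rigid)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("rigid_transform: rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
              ang * 180 / pi, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Identity transform
#' @return the identity `rigid_transform`.
#' @export
transform_identity <- function() rigid_transform()

#' Rotation about an axis
#'
#' @param axis length-3 axis direction (normalized internally).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @param center optional point the axis passes through; when given the
#'   result rotates about the line through `center`, not the origin.
#' @return a `rigid_transform`.
#' @export
rotation_about_axis <- function(axis, angle_deg, center = c(0, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  R <- orthonormalize(R)
  rigid_transform(R, as.numeric(center - R %*% center))
}

#' Magnitude of a rotation
#' @param rotation 3x3 rotation matrix.
#' @return rotation angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(rotation) {
  acos(max(-1, min(1, (sum(diag(rotation)) - 1) / 2)))
}

# nearest orthonormal matrix with det +1 (polar projection via SVD);
# applied after accumulating compositions to stop round-off drift
orthonormalize <- function(R) {
  s <- svd(R)
  Q <- s$u %*% t(s$v)
  if (det(Q) < 0) Q <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  Q
}

#' Compose and invert rigid transforms
#'
#' `compose_transform(a, b)` applies `b` first, then `a` (matrix order
#' `a %*% b`). `invert_transform(t)` satisfies
#' `compose_transform(invert_transform(t), t) == identity` to 1e-12.
#' @param a,b,t `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(orthonormalize(a$rotation %*% b$rotation),
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_transform
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  Rt <- t(t$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% t$translation))
}

#' Apply a rigid transform
#'
#' Maps every vertex v to `rotation %*% v + translation`; connectivity and
#' colors are unchanged.
#' @param mesh a `triangle_mesh` (or, for `transform_points`, an n x 3
#'   coordinate matrix).
#' @param t a `rigid_transform`.
#' @param points n x 3 coordinate matrix.
#' @return transformed mesh / matrix.
#' @export
apply_transform <- function(mesh, t) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(t, "rigid_transform"))
  out <- mesh
  out$vertices <- transform_points(mesh$vertices, t)
  out
}

#' @rdname apply_transform
#' @export
transform_points <- function(points, t) {
  stopifnot(inherits(t, "rigid_transform"))
  points <- as.matrix(points)
  sweep(points %*% t(t$rotation), 2L, -t$translation)
}

#' Convert to/from a 4x4 homogeneous matrix
#' @param t a `rigid_transform`; `m` a 4x4 homogeneous matrix.
#' @return `transform_to_matrix`: 4x4 matrix; `transform_from_matrix`: a
#'   `rigid_transform` (validates the rotation block).
#' @export
transform_to_matrix <- function(t) {
  m <- diag(4)
  m[1:3, 1:3] <- t$rotation
  m[1:3, 4L] <- t$translation
  m
}

#' @rdname transform_to_matrix
#' @export
transform_from_matrix <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4L, 4L))) stop("expected a 4x4 matrix")
  if (max(abs(m[4L, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last row of a rigid homogeneous matrix must be (0,0,0,1)")
  rigid_transform(m[1:3, 1:3], m[1:3, 4L])
}
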