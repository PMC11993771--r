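#' Rigid (or mirrored) spatial transform
#'
#' A rotation plus translation. `proper = TRUE` denotes a rotation
#' (determinant +1); `proper = FALSE` a mirroring (determinant -1).
#'
#' @param rotation 3x3 orthogonal matrix.
#' @param translation 3-vector (mm).
#' @param tol orthogonality tolerance.
#' @return object of class `rigid_transform` with fields `rotation`,
#'   `translation`, `proper`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-9) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (!is.finite(err) || err > sqrt(tol))
    stop("rotation matrix is not orthogonal (max |R'R - I| = ",
         format(err), ")")
  d <- det(rotation)
  structure(list(rotation = rotation, translation = translation,
                 proper = d > 0), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform (", if (x$proper) "proper" else "improper/mirroring",
      ")\n", sep = "")
  print(cbind(x$rotation, x$translation))
  invisible(x)
}

#' Apply a transform to points or a mesh
#'
#' For a mesh transformed by an improper (mirroring) map, face winding is
#' flipped so outward normals are preserved.
#'
#' @param tf a `rigid_transform`.
#' @param x an n x 3 point matrix, a 3-vector, or a `triangle_mesh`.
#' @return same shape as `x`.
#' @export
apply_transform <- function(tf, x) {
  if (inherits(x, "triangle_mesh")) {
    v <- transform_points(tf, x$vertices)
    f <- x$faces
    if (!tf$proper) f <- f[, c(1, 3, 2), drop = FALSE]
    return(triangle_mesh(v, f, validate = FALSE))
  }
  transform_points(tf, x)
}

#' @rdname apply_transform
#' @param pts n x 3 matrix or 3-vector.
#' @export
transform_points <- function(tf, pts) {
  vec <- is.null(dim(pts))
  pts <- to_points(pts)
  out <- pts %*% t(tf$rotation) +
    matrix(tf$translation, nrow(pts), 3, byrow = TRUE)
  if (vec && nrow(out) == 1) drop(out) else out
}

#' Compose two transforms: `compose_transforms(a, b)` applies `b` first,
#' then `a` (matrix convention `a %*% b`).
#' @param a,b `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Invert a transform
#' @param tf a `rigid_transform`.
#' @return a `rigid_transform` with `compose_transforms(tf, invert_transform(tf))`
#'   equal to the identity to 1e-9.
#' @export
invert_transform <- function(tf) {
  rt <- t(tf$rotation)
  rigid_transform(rt, drop(-rt %*% tf$translation))
}

#' Reflection across a plane, as an improper transform
#' @param plane a `plane3`.
#' @return an improper `rigid_transform` (Householder reflection).
#' @export
reflection_transform <- function(plane) {
  n <- plane$normal
  r <- diag(3) - 2 * tcrossprod(n)
  rigid_transform(r, drop(2 * sum(plane$point * n) * n))
}

#' Mirror a mesh across a plane
#'
#' Reflects every vertex and re-flips face winding so that outward normals
#' are preserved. Mirroring twice restores the input.
#' @param mesh a `triangle_mesh`. @param plane a `plane3`.
#' @return a `triangle_mesh`.
#' @export
mirror_mesh <- function(mesh, plane) {
  apply_transform(reflection_transform(plane), mesh)
}

#' Rotation matrix about a coordinate axis
#' @param axis "x", "y" or "z". @param angle_deg angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
         y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
         z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

#' Rotation angle (degrees) of the rotation part of a transform
#' @param tf a proper `rigid_transform`.
#' @return angle in `[0, 180]` degrees.
#' @export
rotation_angle_deg <- function(tf) {
  tr <- sum(diag(tf$rotation))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

#' Transform JSON serialisation (4x4 row-major homogeneous matrix)
#' @param tf a `rigid_transform`. @param path file path.
#' @return `read_transform_json()` returns a `rigid_transform`.
#' @export
write_transform_json <- function(tf, path) {
  m <- rbind(cbind(tf$rotation, tf$translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = as.vector(t(m)), proper = tf$proper),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(x$matrix, 4, 4, byrow = TRUE)
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

# internal: unit-normalise a 3-vector
unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

# internal: cross product
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
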