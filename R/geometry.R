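#' Triangle surface mesh
#'
#' Construct and validate a triangle surface mesh. Coordinates are in
#' millimetres throughout the package.
#'
#' @param vertices numeric matrix, one row per vertex, 3 columns (mm).
#' @param faces integer matrix, one row per triangle, 3 columns of 1-based
#'   vertex indices.
#' @param validate check invariants (finite coordinates, valid indices,
#'   nondegenerate triangles).
#' @return An object of class `triangle_mesh` with elements `vertices` and
#'   `faces`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = NULL)
  faces <- matrix(as.integer(faces), ncol = 3, dimnames = NULL)
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "triangle_mesh")
  if (validate) validate_mesh(m)
  m
}

#' @rdname triangle_mesh
#' @param mesh a `triangle_mesh`.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  if (!all(is.finite(v))) stop("mesh vertices contain non-finite coordinates")
  if (nrow(f) > 0) {
    if (min(f) < 1L || max(f) > nrow(v))
      stop("face indices out of range [1, ", nrow(v), "]")
    if (any(f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]))
      stop("degenerate triangle: repeated vertex index within a face")
  }
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces\n")
  invisible(x)
}

#' Per-face and total surface area
#' @param mesh a `triangle_mesh`.
#' @return `face_areas()`: numeric vector (mm^2); `mesh_area()`: total (mm^2).
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0) return(numeric(0))
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @rdname face_areas
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Area-weighted outward vertex normals
#'
#' Face normals follow the right-hand winding rule; each vertex normal is the
#' normalised sum of incident face normals weighted by face area.
#' @param mesh a `triangle_mesh`.
#' @return numeric matrix of unit normals, one row per vertex.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) # area-weighted already
  vn <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    for (c in 1:3) {
      acc <- rowsum(fn[, c], group = f[, k], reorder = FALSE)
      vn[as.integer(rownames(acc)), c] <- vn[as.integer(rownames(acc)), c] +
        acc[, 1]
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

#' Merge two meshes into one (disjoint union of surfaces)
#' @param a,b `triangle_mesh` objects.
#' @return a `triangle_mesh`.
#' @export
merge_meshes <- function(a, b) {
  triangle_mesh(rbind(a$vertices, b$vertices),
                rbind(a$faces, b$faces + nrow(a$vertices)),
                validate = FALSE)
}

#' Oriented plane
#'
#' @param point a 3-vector on the plane (mm).
#' @param normal a 3-vector; normalised to unit length (must be nonzero).
#' @return object of class `plane3` with fields `point`, `normal`.
#' @export
plane3 <- function(point, normal) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  stopifnot(length(point) == 3, length(normal) == 3, all(is.finite(point)))
  n <- sqrt(sum(normal^2))
  if (!is.finite(n) || n < 1e-12) stop("plane normal must be nonzero")
  structure(list(point = point, normal = normal / n), class = "plane3")
}

#' Signed distance of points to a plane
#' @param pts matrix of points (rows) or a 3-vector.
#' @param plane a `plane3`.
#' @return numeric vector; positive on the side the normal points to.
#' @export
signed_distance <- function(pts, plane) {
  pts <- to_points(pts)
  drop((pts - matrix(plane$point, nrow(pts), 3, byrow = TRUE)) %*%
         plane$normal)
}

# internal: coerce 3-vector or n x 3 matrix to n x 3 matrix
to_points <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3) else
    matrix(as.numeric(x), ncol = 3)
}

#' Plane JSON serialisation
#' @param plane a `plane3`. @param path file path.
#' @return `read_plane_json()` returns a `plane3`.
#' @export
write_plane_json <- function(plane, path) {
  jsonlite::write_json(list(point = plane$point, normal = plane$normal),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_plane_json
#' @export
read_plane_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  plane3(x$point, x$normal)
}
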