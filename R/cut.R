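#' Cut a mesh with a plane
#'
#' Splits the surface into the part on the positive side of the plane (the
#' side the normal points to) and the part on the negative side. Triangles
#' straddling the plane are clipped exactly at the plane; the cut leaves open
#' boundaries (no cap surface is created), because only the outer bone
#' surface is used downstream.
#'
#' @param mesh a `triangle_mesh`.
#' @param plane a `plane3`.
#' @param tol vertices within `tol` (mm) of the plane count as on-plane and
#'   are kept by both parts.
#' @return list with `positive` and `negative` `triangle_mesh` parts (either
#'   may be empty; a warning is emitted if the plane misses the mesh).
#' @export
cut_with_plane <- function(mesh, plane, tol = 1e-9) {
  s <- signed_distance(mesh$vertices, plane)
  cls <- integer(length(s))
  cls[s > tol] <- 1L
  cls[s < -tol] <- -1L
  f <- mesh$faces
  c1 <- cls[f[, 1]]; c2 <- cls[f[, 2]]; c3 <- cls[f[, 3]]
  pos_ok <- c1 >= 0L & c2 >= 0L & c3 >= 0L
  neg_ok <- c1 <= 0L & c2 <= 0L & c3 <= 0L
  straddle <- which(!(pos_ok | neg_ok))

  pos_tris <- list(cbind(mesh$vertices[f[pos_ok, 1], , drop = FALSE],
                         mesh$vertices[f[pos_ok, 2], , drop = FALSE],
                         mesh$vertices[f[pos_ok, 3], , drop = FALSE]))
  neg_tris <- list(cbind(mesh$vertices[f[neg_ok, 1], , drop = FALSE],
                         mesh$vertices[f[neg_ok, 2], , drop = FALSE],
                         mesh$vertices[f[neg_ok, 3], , drop = FALSE]))
  for (i in straddle) {
    vs <- mesh$vertices[f[i, ], , drop = FALSE]
    ss <- s[f[i, ]]
    pos_tris[[length(pos_tris) + 1L]] <- clip_triangle(vs, ss)
    neg_tris[[length(neg_tris) + 1L]] <- clip_triangle(vs, -ss)
  }
  pos <- soup_to_mesh(do.call(rbind, pos_tris))
  neg <- soup_to_mesh(do.call(rbind, neg_tris))
  if (nrow(pos$faces) == 0 || nrow(neg$faces) == 0)
    warning("cut plane does not intersect the mesh: one part is empty")
  list(positive = pos, negative = neg)
}

# internal: clip one triangle against the halfspace s >= 0
# (Sutherland-Hodgman), returning fan-triangulated rows of 9 coordinates.
clip_triangle <- function(vs, ss) {
  poly <- list()
  for (k in 1:3) {
    j <- if (k == 3) 1 else k + 1
    vi <- vs[k, ]; vj <- vs[j, ]
    si <- ss[k]; sj <- ss[j]
    if (si >= 0) poly[[length(poly) + 1L]] <- vi
    if ((si > 0 && sj < 0) || (si < 0 && sj > 0)) {
      t <- si / (si - sj)
      poly[[length(poly) + 1L]] <- vi + t * (vj - vi)
    }
  }
  np <- length(poly)
  if (np < 3) return(matrix(numeric(0), ncol = 9))
  p <- do.call(rbind, poly)
  out <- matrix(numeric(0), ncol = 9)
  for (k in 2:(np - 1)) {
    tri <- c(p[1, ], p[k, ], p[k + 1, ])
    # drop slivers of zero area produced by on-plane vertices
    e1 <- tri[4:6] - tri[1:3]; e2 <- tri[7:9] - tri[1:3]
    cr <- cross3(e1, e2)
    if (sum(cr^2) > 1e-24) out <- rbind(out, tri)
  }
  out
}

# internal: rows of 9 coordinates -> welded triangle_mesh
soup_to_mesh <- function(tri9) {
  if (is.null(tri9) || nrow(tri9) == 0)
    return(triangle_mesh(matrix(numeric(0), ncol = 3),
                         matrix(integer(0), ncol = 3), validate = FALSE))
  v <- rbind(tri9[, 1:3, drop = FALSE], tri9[, 4:6, drop = FALSE],
             tri9[, 7:9, drop = FALSE])
  # interleave so faces are (1,2,3),(4,5,6),...
  n <- nrow(tri9)
  ord <- as.vector(t(matrix(seq_len(3 * n), ncol = 3)))
  weld_triangle_soup(v[ord, , drop = FALSE])
}
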