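#' ICP parameter block
#'
#' @param max_iterations maximum ICP iterations (>= 1).
#' @param convergence_tol convergence tolerance on the change in mean
#'   residual (mm, > 0). The default 1e-4 mm is well below the 0.05 mm
#'   single-shot error of the optical scanner the pipeline emulates.
#' @param sample_count number of points sampled from the moving surface
#'   (>= 3).
#' @param trim_mode `"none"` or `"auto_threshold"`. Auto-threshold excludes,
#'   at each iteration, correspondences farther than mean + 2 SD of the
#'   current correspondence distances from the transform estimate (a standard
#'   robust stand-in for the unspecified commercial "automatic distance
#'   threshold").
#' @param seed integer seed for the deterministic area-weighted surface
#'   sampling.
#' @return list of class `icp_params`.
#' @export
icp_params <- function(max_iterations = 100L, convergence_tol = 1e-4,
                       sample_count = 600L,
                       trim_mode = c("none", "auto_threshold"), seed = 1L) {
  trim_mode <- match.arg(trim_mode)
  stopifnot(max_iterations >= 1, convergence_tol > 0, sample_count >= 3)
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 sample_count = as.integer(sample_count),
                 trim_mode = trim_mode, seed = as.integer(seed)),
            class = "icp_params")
}

#' Closed-form rigid alignment of paired points (Kabsch / orthogonal
#' Procrustes)
#'
#' Returns the proper rigid transform minimising the sum of squared
#' distances between `transform_points(tf, moving)` and `fixed`; the SVD
#' solution is the global optimum.
#'
#' @param moving,fixed n x 3 matrices of paired points, n >= 3, not
#'   collinear.
#' @return a proper `rigid_transform`.
#' @export
kabsch <- function(moving, fixed) {
  moving <- to_points(moving); fixed <- to_points(fixed)
  stopifnot(nrow(moving) == nrow(fixed))
  if (nrow(moving) < 3) stop("kabsch needs at least 3 point pairs")
  mc <- colMeans(moving); fc <- colMeans(fixed)
  p0 <- sweep(moving, 2, mc); q0 <- sweep(fixed, 2, fc)
  sv_m <- svd(p0)$d
  if (sv_m[2] < 1e-9 * max(sv_m[1], 1e-30))
    stop("degenerate (collinear) point configuration: rank < 2")
  h <- crossprod(p0, q0)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(r, fc - drop(r %*% mc))
}

#' Deterministic area-weighted sampling of points on a mesh surface
#'
#' Faces are drawn with probability proportional to area and points placed
#' uniformly inside each drawn face, under a fixed seed, so repeated calls
#' are identical.
#'
#' @param mesh a `triangle_mesh`. @param n number of points. @param seed
#'   integer seed.
#' @return n x 3 matrix of points.
#' @export
sample_mesh_points <- function(mesh, n, seed = 1L) {
  areas <- face_areas(mesh)
  if (length(areas) == 0) stop("cannot sample an empty mesh")
  with_seed(seed, {
    fi <- sample.int(length(areas), n, replace = TRUE, prob = areas)
    r1 <- sqrt(runif(n)); r2 <- runif(n)
    a <- mesh$vertices[mesh$faces[fi, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[fi, 2], , drop = FALSE]
    cc <- mesh$vertices[mesh$faces[fi, 3], , drop = FALSE]
    (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * cc
  })
}

#' Closest points on a mesh surface
#'
#' Exact point-to-triangle closest-point queries (not vertex-to-vertex),
#' so correspondences are meaningful between unrelated tessellations.
#'
#' @param mesh a `triangle_mesh`. @param query n x 3 matrix of points.
#' @return list with `points` (n x 3 closest surface points), `distance`
#'   (unsigned, mm) and `face` (1-based face index).
#' @export
closest_points <- function(mesh, query) {
  cpp_closest_on_mesh(mesh$vertices, mesh$faces, to_points(query))
}

#' Iterative Closest Point rigid registration
#'
#' Aligns a moving surface (mesh or point set) onto a fixed mesh. Each
#' iteration matches sample points, under the current transform, to their
#' closest points on the fixed surface and re-solves the full transform with
#' [kabsch()]. With `trim_mode = "auto_threshold"` correspondences beyond
#' mean + 2 SD of the current distances are excluded from the estimate.
#'
#' @param moving a `triangle_mesh` (sampled with `params$sample_count`
#'   points) or an n x 3 point matrix (used as-is, subsampled to
#'   `params$sample_count` if larger).
#' @param fixed a `triangle_mesh`.
#' @param init initial `rigid_transform` (identity by default; the clinical
#'   workflow provides a roughly correct initial pose).
#' @param params an [icp_params()] block.
#' @return list of class `registration_result`: `transform`,
#'   `mean_residual` (mm), `iterations_run`, `converged`,
#'   `retained_fraction`, `residual_trace`.
#' @export
icp <- function(moving, fixed, init = rigid_transform(),
                params = icp_params()) {
  if (inherits(moving, "triangle_mesh")) {
    if (nrow(moving$faces) == 0) stop("moving mesh is empty")
    pts <- sample_mesh_points(moving, params$sample_count, params$seed)
  } else {
    pts <- to_points(moving)
    if (nrow(pts) > params$sample_count) {
      keep <- with_seed(params$seed,
                        sample.int(nrow(pts), params$sample_count))
      pts <- pts[keep, , drop = FALSE]
    }
  }
  if (nrow(pts) < 3) stop("fewer than 3 moving points")
  if (nrow(fixed$faces) == 0) stop("fixed mesh is empty")

  tf <- init
  prev <- Inf
  trace <- numeric(0)
  converged <- FALSE
  retained <- 1
  iters <- 0L
  for (it in seq_len(params$max_iterations)) {
    iters <- it
    cur <- transform_points(tf, pts)
    cp <- closest_points(fixed, cur)
    d <- cp$distance
    keep <- rep(TRUE, length(d))
    if (params$trim_mode == "auto_threshold") {
      thr <- mean(d) + 2 * sd(d)
      keep <- d <= thr
      if (sum(keep) < 3)
        stop("trimming collapse: fewer than 3 retained correspondences")
    }
    retained <- mean(keep)
    res <- mean(d[keep])
    trace <- c(trace, res)
    tf <- kabsch(pts[keep, , drop = FALSE], cp$points[keep, , drop = FALSE])
    if (is.finite(prev) && abs(prev - res) < params$convergence_tol) {
      converged <- TRUE
      break
    }
    prev <- res
  }
  # final residual under the final transform
  cur <- transform_points(tf, pts)
  d <- closest_points(fixed, cur)$distance
  keep <- rep(TRUE, length(d))
  if (params$trim_mode == "auto_threshold") {
    thr <- mean(d) + 2 * sd(d)
    keep <- d <= thr & is.finite(d)
    if (sum(keep) < 3) keep <- rep(TRUE, length(d))
  }
  structure(list(transform = tf, mean_residual = mean(d[keep]),
                 iterations_run = iters, converged = converged,
                 retained_fraction = mean(keep), residual_trace = trace),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "registration_result: residual %.5f mm after %d iteration(s)%s, %.0f%% retained\n",
    x$mean_residual, x$iterations_run,
    if (x$converged) " (converged)" else "", 100 * x$retained_fraction))
  invisible(x)
}

#' Select mesh vertices on one side of a plane
#'
#' Returns the vertices lying on the requested side of the plane, excluding
#' a dead zone of `margin` mm around the plane (the osteotomy junction is
#' geometrically unreliable there).
#'
#' @param mesh a `triangle_mesh`. @param plane a `plane3`.
#' @param side `"positive"` (the side the normal points to) or
#'   `"negative"`.
#' @param margin dead-zone half-width in mm (default 2).
#' @return n x 3 matrix of vertices.
#' @export
restrict_to_region <- function(mesh, plane, side = c("positive", "negative"),
                               margin = 2) {
  side <- match.arg(side)
  s <- signed_distance(mesh$vertices, plane)
  keep <- if (side == "positive") s > margin else s < -margin
  if (!any(keep)) stop("region selection is empty (side = ", side,
                       ", margin = ", margin, " mm)")
  mesh$vertices[keep, , drop = FALSE]
}

#' Default ICP parameters for the measurement pipeline
#'
#' Untrimmed ICP with a tight convergence tolerance (1e-6 mm change in mean
#' residual): ICP converges linearly, and the measurement stages need the
#' transform, not just the residual, to have converged. Trimming is left
#' off because the measurement stages already exclude the unreliable
#' junction zone by region margins, and an automatic threshold can lock in
#' a slid pose by discarding exactly the feature points that would correct
#' it.
#'
#' @param seed sampling seed.
#' @return an [icp_params()] block.
#' @export
measurement_icp_params <- function(seed = 1L) {
  icp_params(max_iterations = 400L, convergence_tol = 1e-6,
             sample_count = 1200L, trim_mode = "none", seed = seed)
}
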