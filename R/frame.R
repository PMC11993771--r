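#' Landmark set for the distal radius
#'
#' @param crp Central Reference Point: centre of the rim between the lunate
#'   fossa and the sigmoid notch; the frame origin.
#' @param styloid_tip tip of the radial styloid.
#' @param volar_ref optional point on the volar cortex, used to orient the
#'   y axis.
#' @param side `"left"` or `"right"`.
#' @return list of class `landmark_set`.
#' @export
landmark_set <- function(crp, styloid_tip, volar_ref = NULL,
                         side = c("right", "left")) {
  side <- match.arg(side)
  crp <- as.numeric(crp); styloid_tip <- as.numeric(styloid_tip)
  stopifnot(length(crp) == 3, length(styloid_tip) == 3)
  if (sqrt(sum((crp - styloid_tip)^2)) < 1e-9)
    stop("crp and styloid_tip must be distinct points")
  if (!is.null(volar_ref)) {
    volar_ref <- as.numeric(volar_ref)
    stopifnot(length(volar_ref) == 3)
  }
  structure(list(crp = crp, styloid_tip = styloid_tip,
                 volar_ref = volar_ref, side = side),
            class = "landmark_set")
}

#' Landmark JSON serialisation
#' @param lm a `landmark_set`. @param path file path.
#' @return `read_landmarks_json()` returns a `landmark_set`.
#' @export
write_landmarks_json <- function(lm, path) {
  jsonlite::write_json(
    list(crp = lm$crp, styloid_tip = lm$styloid_tip,
         volar_ref = lm$volar_ref, side = lm$side),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_set(x$crp, x$styloid_tip, x$volar_ref, x$side)
}

#' Central shaft axis of the radius
#'
#' Fits the central axis of the shaft as a least-squares 3D line through
#' cross-section centroids sampled every `step` mm on the segment 30-50 mm
#' proximal to the CRP (a deterministic surrogate for the manual
#' two-plane construction: the intersection of two fitted planes is exactly
#' a fitted 3D line). Centroids use overlapping Gaussian windows (SD =
#' `step`) so that partial tessellation rings cannot bias individual
#' cross-sections. The fit is iterated with its own result as the
#' provisional axis until the direction is stable.
#'
#' @param mesh a `triangle_mesh`.
#' @param crp the Central Reference Point (3-vector).
#' @param segment `c(min_mm, max_mm)` distances proximal of the CRP
#'   (default `c(30, 50)`).
#' @param provisional optional unit 3-vector giving a provisional proximal
#'   direction; defaults to the direction from the CRP towards the vertex
#'   centroid.
#' @param step cross-section spacing in mm.
#' @return list of class `axis_line` with `point` (on the axis) and
#'   `direction` (unit vector pointing distally).
#' @export
central_axis <- function(mesh, crp, segment = c(30, 50), provisional = NULL,
                         step = 1) {
  crp <- as.numeric(crp)
  v <- mesh$vertices
  prox <- if (is.null(provisional)) unit3(colMeans(v) - crp)
          else unit3(as.numeric(provisional))
  if (max(drop((v - matrix(crp, nrow(v), 3, byrow = TRUE)) %*% prox)) <
      segment[2])
    stop("insufficient shaft: mesh does not cover the ", segment[1], "-",
         segment[2], " mm segment proximal to the CRP")
  dir_prev <- NULL
  for (iter in 1:8) {
    t <- drop((v - matrix(crp, nrow(v), 3, byrow = TRUE)) %*% prox)
    mids <- seq(segment[1], segment[2], by = step)
    cents <- t(vapply(mids, function(m) {
      w <- exp(-0.5 * ((t - m) / step)^2)
      w[abs(t - m) > 3 * step] <- 0
      if (sum(w) < 1e-6) return(rep(NA_real_, 3))
      colSums(v * w) / sum(w)
    }, numeric(3)))
    cents <- cents[stats::complete.cases(cents), , drop = FALSE]
    if (nrow(cents) < 3)
      stop("insufficient shaft: mesh does not cover the ", segment[1], "-",
           segment[2], " mm segment proximal to the CRP")
    ctr <- colMeans(cents)
    pc <- prcomp(cents, center = TRUE)
    dir <- pc$rotation[, 1]
    # orient distally: towards the CRP
    if (sum(dir * (crp - ctr)) < 0) dir <- -dir
    if (!is.null(dir_prev) &&
        acos(min(1, sum(dir * dir_prev))) < 0.01 * pi / 180) break
    dir_prev <- dir
    prox <- -dir
  }
  structure(list(point = ctr, direction = dir), class = "axis_line")
}

#' Anatomical coordinate frame of the distal radius
#'
#' Builds the CRP-origin frame: z along the central shaft axis pointing
#' distally; x perpendicular to z, from the origin towards the projection of
#' the styloid tip (the radial direction); y perpendicular to the xz plane.
#' With a `volar_ref` landmark, y is flipped if needed so it points volarly
#' (a mirrored anatomy then yields a mirrored, left-handed frame). Without
#' one, `y = z x x` for a right radius and its negative for a left radius.
#'
#' @param mesh a `triangle_mesh`.
#' @param landmarks a `landmark_set`.
#' @param segment passed to [central_axis()].
#' @return list of class `anatomical_frame`: `origin`, `x_axis`, `y_axis`,
#'   `z_axis`, `handedness`.
#' @export
build_frame <- function(mesh, landmarks, segment = c(30, 50)) {
  ax <- central_axis(mesh, landmarks$crp, segment = segment)
  z <- ax$direction
  origin <- landmarks$crp
  v <- landmarks$styloid_tip - origin
  xproj <- v - sum(v * z) * z
  if (sqrt(sum(xproj^2)) < 5)
    stop("ill-conditioned frame: styloid projection is < 5 mm from the axis")
  x <- unit3(xproj)
  y <- cross3(z, x)
  handedness <- "right"
  flip <- FALSE
  if (!is.null(landmarks$volar_ref)) {
    flip <- sum(y * (landmarks$volar_ref - origin)) < 0
  } else {
    flip <- landmarks$side == "left"
  }
  if (flip) {
    y <- -y
    handedness <- "left"
  }
  structure(list(origin = origin, x_axis = x, y_axis = y, z_axis = z,
                 handedness = handedness),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("anatomical_frame (", x$handedness, "-handed)\n", sep = "")
  m <- rbind(origin = x$origin, x = x$x_axis, y = x$y_axis, z = x$z_axis)
  colnames(m) <- c("X", "Y", "Z")
  print(round(m, 4))
  invisible(x)
}

#' World alignment of an anatomical frame
#'
#' The transform that maps the frame origin to (0,0,0) and the frame axes to
#' the world basis. For a left-handed frame the map is an improper
#' (mirroring) transform, flagged `proper = FALSE`.
#'
#' @param frame an `anatomical_frame`.
#' @return a `rigid_transform`.
#' @export
world_alignment <- function(frame) {
  r <- rbind(frame$x_axis, frame$y_axis, frame$z_axis)
  dimnames(r) <- NULL
  rigid_transform(r, drop(-r %*% frame$origin))
}

#' Frame JSON serialisation
#' @param frame an `anatomical_frame`. @param path file path.
#' @export
write_frame_json <- function(frame, path) {
  jsonlite::write_json(
    list(origin = frame$origin, x_axis = frame$x_axis,
         y_axis = frame$y_axis, z_axis = frame$z_axis,
         handedness = frame$handedness),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
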