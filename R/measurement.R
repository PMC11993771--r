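#' Six-parameter clinical error decomposition
#'
#' The residual transform between achieved and planned correction, expressed
#' in the anatomical frame, decomposed into three rotations and three
#' translations: rotation about x is the volar tilt error (volar positive),
#' rotation about y the radial inclination error, rotation about z the axial
#' rotation error; translation along z is the radial length / ulnar variance
#' error (lengthening positive), measured at the frame origin on the sigmoid
#' notch rim.
#'
#' @param rot_x_deg,rot_y_deg,rot_z_deg rotations in degrees.
#' @param trans_x_mm,trans_y_mm,trans_z_mm translations in mm.
#' @return list of class `clinical_errors`.
#' @export
clinical_errors <- function(rot_x_deg = 0, rot_y_deg = 0, rot_z_deg = 0,
                            trans_x_mm = 0, trans_y_mm = 0,
                            trans_z_mm = 0) {
  structure(list(rot_x_deg = rot_x_deg, rot_y_deg = rot_y_deg,
                 rot_z_deg = rot_z_deg, trans_x_mm = trans_x_mm,
                 trans_y_mm = trans_y_mm, trans_z_mm = trans_z_mm),
            class = "clinical_errors")
}

#' @export
print.clinical_errors <- function(x, ...) {
  cat(sprintf(paste0(
    "clinical_errors: volar tilt %+.2f deg, radial inclination %+.2f deg, ",
    "axial rotation %+.2f deg\n                 translations (%+.2f, %+.2f, ",
    "%+.2f) mm [z = ulnar variance]\n"),
    x$rot_x_deg, x$rot_y_deg, x$rot_z_deg,
    x$trans_x_mm, x$trans_y_mm, x$trans_z_mm))
  invisible(x)
}

#' Compose a transform from six clinical parameters
#'
#' Uses the extrinsic x-y-z Cardan convention `R = Rz(g) Ry(b) Rx(a)` about
#' the frame origin; translations are applied after the rotation. This is
#' the package's fixed rotation-sequence dialect (radiological sequences
#' vary between tools); [decompose_transform()] inverts it exactly.
#'
#' @param err a `clinical_errors` object.
#' @return a proper `rigid_transform`.
#' @export
compose_clinical <- function(err) {
  r <- rotation_about_axis("z", err$rot_z_deg) %*%
    rotation_about_axis("y", err$rot_y_deg) %*%
    rotation_about_axis("x", err$rot_x_deg)
  rigid_transform(r, c(err$trans_x_mm, err$trans_y_mm, err$trans_z_mm))
}

#' Decompose a transform into six clinical parameters
#'
#' Inverts [compose_clinical()]: extrinsic x-y-z Cardan angles
#' (`R = Rz(g) Ry(b) Rx(a)`), translations read directly. A gimbal guard
#' rejects |rotation about y| >= 60 degrees, far beyond any clinical
#' correction error.
#'
#' @param tf a proper `rigid_transform`.
#' @param gimbal_guard_deg guard limit in degrees.
#' @return a `clinical_errors` object; `compose_clinical()` of the result
#'   reproduces `tf` to 1e-9.
#' @export
decompose_transform <- function(tf, gimbal_guard_deg = 60) {
  if (!tf$proper)
    stop("decompose_transform requires a proper (non-mirroring) transform")
  r <- tf$rotation
  sb <- -r[3, 1]
  beta <- asin(pmin(1, pmax(-1, sb)))
  if (abs(beta) >= gimbal_guard_deg * pi / 180)
    stop("gimbal guard: |rotation about y| = ",
         format(abs(beta) * 180 / pi, digits = 4), " deg >= ",
         gimbal_guard_deg, " deg")
  alpha <- atan2(r[3, 2], r[3, 3])
  gamma <- atan2(r[2, 1], r[1, 1])
  clinical_errors(alpha * 180 / pi, beta * 180 / pi, gamma * 180 / pi,
                  tf$translation[1], tf$translation[2], tf$translation[3])
}

#' Measure correction errors of a surgical result against its plan
#'
#' The two-stage measurement: (1) ICP-align the result's proximal radius to
#' the planned model's proximal radius and apply the transform to the whole
#' result; (2) build the anatomical frame on the planned model and align
#' both models with the world coordinate system (origin to (0,0,0)); (3)
#' ICP-align the result's distal part to the planned distal part; (4)
#' express the residual displacement of the achieved distal fragment
#' relative to the plan (the inverse of the step-3 alignment) in the frame
#' and decompose it into the six clinical parameters. For left-handed
#' (mirrored) frames the basis conjugation yields mirrored-sign angles, as
#' intended for left-sided anatomy.
#'
#' @param result_mesh the post-surgery bone surface (`triangle_mesh`).
#' @param plan an `osteotomy_plan` (see [plan_correction()]).
#' @param landmarks `landmark_set` on the planned (corrected) model.
#' @param params an [icp_params()] block; the default
#'   [measurement_icp_params()] uses a tight convergence tolerance because
#'   stage-1 registration error propagates into every reported parameter.
#' @param margin dead zone around the osteotomy plane for region selection
#'   (mm). On the proximal side the dead zone is widened by 4 mm: the
#'   achieved fragment can dip below the plane by its residual correction
#'   error, and those vertices are continuous with the shaft surface, so
#'   distance-based trimming cannot reject them.
#' @return a `clinical_errors` object with attributes
#'   `proximal_residual` and `distal_residual` (mm).
#' @export
measure_errors <- function(result_mesh, plan, landmarks,
                           params = measurement_icp_params(),
                           margin = 2) {
  planned <- merge_meshes(plan$proximal_part, plan$distal_part_corrected)
  plane <- plan$osteotomy_plane  # normal points distally

  # stage 1: proximal alignment of result onto plan, in two passes -- the
  # plane-based region selection is only trustworthy once the result is
  # roughly aligned, so regions are re-marked after the first pass
  prox_margin <- margin + 4
  mov_prox <- tryCatch(
    restrict_to_region(result_mesh, plane, "negative", prox_margin),
    error = function(e) stop("measurement stage 1 (proximal ICP): ",
                             conditionMessage(e)))
  reg1a <- icp(mov_prox, plan$proximal_part, rigid_transform(), params)
  aligned_a <- apply_transform(reg1a$transform, result_mesh)
  mov_prox2 <- tryCatch(
    restrict_to_region(aligned_a, plane, "negative", prox_margin),
    error = function(e) stop("measurement stage 1 (proximal ICP): ",
                             conditionMessage(e)))
  reg1 <- icp(mov_prox2, plan$proximal_part, rigid_transform(), params)
  reg1$transform <- compose_transforms(reg1$transform, reg1a$transform)
  result_aligned <- apply_transform(reg1$transform, result_mesh)

  # stage 2: anatomical frame on the planned model, world alignment
  frame <- build_frame(planned, landmarks)
  w <- world_alignment(frame)
  planned_distal_w <- apply_transform(w, plan$distal_part_corrected)
  result_w <- apply_transform(w, result_aligned)
  plane_w <- plane3(transform_points(w, plane$point),
                    drop(w$rotation %*% plane$normal))

  # stage 3: distal alignment in world (= frame) coordinates
  mov_dist <- tryCatch(
    restrict_to_region(result_w, plane_w, "positive", margin),
    error = function(e) stop("measurement stage 3 (distal ICP): ",
                             conditionMessage(e)))
  reg3 <- icp(mov_dist, planned_distal_w, rigid_transform(), params)

  # stage 4: residual displacement of the achieved fragment, in the frame
  err_tf <- invert_transform(reg3$transform)
  out <- decompose_transform(err_tf)
  attr(out, "proximal_residual") <- reg1$mean_residual
  attr(out, "distal_residual") <- reg3$mean_residual
  out
}
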