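#' Plan a corrective osteotomy against a mirrored healthy reference
#'
#' Cuts the malunited radius at the osteotomy plane (whose normal must point
#' towards the distal fragment, the one carrying the styloid), then
#' ICP-aligns the distal fragment onto the corresponding distal region of
#' the mirrored healthy reference. The reference is assumed already
#' registered to the malunited proximal shaft (a prior [icp()] call on the
#' proximal region, decoupling reference-registration error from planning).
#'
#' @param malunited `triangle_mesh` of the malunited radius.
#' @param healthy_mirrored `triangle_mesh` of the mirrored contralateral
#'   radius, registered to the malunited proximal shaft.
#' @param plane osteotomy `plane3`, normal pointing distally.
#' @param params an [icp_params()] block (trimming recommended: the cut
#'   fragment only partially overlaps the reference).
#' @param init initial `rigid_transform` for the fragment alignment
#'   (identity by default; for severe deformities a coarse landmark-based
#'   initialisation, as a planner provides interactively, avoids ICP local
#'   minima).
#' @param margin dead zone (mm) around the plane for the reference region.
#' @return list of class `osteotomy_plan`: `osteotomy_plane`,
#'   `proximal_part`, `distal_part`, `distal_part_corrected`, `correction`
#'   (a proper `rigid_transform` taking the distal fragment from its
#'   malunited pose to the corrected pose), `reference_residual` (mm).
#' @export
plan_correction <- function(malunited, healthy_mirrored, plane,
                            params = icp_params(trim_mode = "auto_threshold"),
                            init = rigid_transform(), margin = 2) {
  parts <- cut_with_plane(malunited, plane)
  distal <- parts$positive
  proximal <- parts$negative
  if (nrow(distal$faces) == 0)
    stop("planning error: osteotomy plane produced an empty distal part")
  ref_pts_check <- signed_distance(healthy_mirrored$vertices, plane)
  if (!any(ref_pts_check > margin))
    stop("planning error: reference has no distal region beyond the plane")
  reg <- icp(distal, healthy_mirrored, init, params)
  correction <- reg$transform
  structure(list(osteotomy_plane = plane,
                 proximal_part = proximal,
                 distal_part = distal,
                 distal_part_corrected = apply_transform(correction, distal),
                 correction = correction,
                 reference_residual = reg$mean_residual),
            class = "osteotomy_plan")
}

#' @export
print.osteotomy_plan <- function(x, ...) {
  cat(sprintf(
    "osteotomy_plan: correction rotation %.2f deg, translation %.2f mm, reference residual %.4f mm\n",
    rotation_angle_deg(x$correction),
    sqrt(sum(x$correction$translation^2)), x$reference_residual))
  invisible(x)
}

#' Drill trajectory
#' @param entry 3D entry point (mm). @param direction 3-vector, normalised.
#' @param length,diameter positive dimensions (mm).
#' @return list of class `drill_trajectory`.
#' @export
drill_trajectory <- function(entry, direction, length, diameter = 2.5) {
  stopifnot(length > 0, diameter > 0)
  structure(list(entry = as.numeric(entry), direction = unit3(direction),
                 length = length, diameter = diameter),
            class = "drill_trajectory")
}

#' Back-transform drill trajectories to the uncorrected bone
#'
#' Drills are planned on the corrected distal fragment; reversing them with
#' the inverse of the planned correction places them on the malunited bone,
#' where the guide applies them, so the planned reduction is achieved once
#' the fragment is fixed.
#'
#' @param plan an `osteotomy_plan`.
#' @param drills list of `drill_trajectory` objects in the corrected pose.
#' @return list of `drill_trajectory` objects in the malunited pose;
#'   re-applying `plan$correction` restores the input to 1e-9.
#' @export
back_transform_drills <- function(plan, drills) {
  inv <- invert_transform(plan$correction)
  lapply(drills, function(d) {
    drill_trajectory(transform_points(inv, d$entry),
                     drop(inv$rotation %*% d$direction),
                     d$length, d$diameter)
  })
}

#' Plan JSON serialisation (correction matrix, plane and residual; meshes
#' are referenced by the STL paths supplied)
#' @param plan an `osteotomy_plan`. @param path file path.
#' @param mesh_paths optional named list of STL paths to record.
#' @export
write_plan_json <- function(plan, path, mesh_paths = NULL) {
  m <- rbind(cbind(plan$correction$rotation, plan$correction$translation),
             c(0, 0, 0, 1))
  jsonlite::write_json(
    list(correction = as.vector(t(m)),
         plane = list(point = plan$osteotomy_plane$point,
                      normal = plan$osteotomy_plane$normal),
         reference_residual = plan$reference_residual,
         mesh_paths = mesh_paths),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
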