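#' Average distance error between a scanned and a reference surface
#'
#' Registers the scanned mesh onto the reference with trimmed ICP (the
#' "automatic distance threshold" dialect: mean + 2 SD per iteration) and
#' reports the mean unsigned point-to-surface distance of all masked sample
#' points -- points trimmed during registration are re-included in the
#' distance summary. Registration can be disabled for analytic checks.
#'
#' @param reference fixed `triangle_mesh` (e.g. the virtual design).
#' @param scanned moving `triangle_mesh`, or an n x 3 matrix of scan
#'   points (optical scanners deliver point clouds; see
#'   [simulate_scan_points()]).
#' @param mask optional region restricting the scanned sample points to the
#'   outer contact surfaces: either a list `list(plane = , side = )`
#'   (see [restrict_to_region()]) or an integer vector of face indices of
#'   `scanned`.
#' @param params an [icp_params()] block.
#' @param register run ICP before measuring (default TRUE).
#' @return list of class `ade_result`: `mean_distance`, `sd_distance`
#'   (mm), `n_points`, `retained_fraction`.
#' @export
ade <- function(reference, scanned, mask = NULL,
                params = icp_params(trim_mode = "auto_threshold",
                                    sample_count = 1500L),
                register = TRUE) {
  if (nrow(reference$faces) == 0) stop("ade: empty mesh")
  if (inherits(scanned, "triangle_mesh")) {
    if (nrow(scanned$faces) == 0) stop("ade: empty mesh")
    sub <- scanned
    if (!is.null(mask) && is.numeric(mask) && is.null(names(mask))) {
      sub <- triangle_mesh(scanned$vertices,
                           scanned$faces[as.integer(mask), , drop = FALSE])
    }
    pts <- sample_mesh_points(sub, params$sample_count, params$seed)
  } else {
    pts <- to_points(scanned)
  }
  if (is.list(mask) && !is.null(mask$plane)) {
    s <- signed_distance(pts, mask$plane)
    keep <- if ((mask$side %||% "positive") == "positive") s > 0 else s < 0
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) < 100) stop("ade: mask leaves fewer than 100 sample points")
  retained <- 1
  if (register) {
    reg <- icp(pts, reference, rigid_transform(), params)
    pts <- transform_points(reg$transform, pts)
    retained <- reg$retained_fraction
  }
  d <- closest_points(reference, pts)$distance
  structure(list(mean_distance = mean(d), sd_distance = sd(d),
                 n_points = nrow(pts), retained_fraction = retained),
            class = "ade_result")
}

#' @export
print.ade_result <- function(x, ...) {
  cat(sprintf("ADE %.4f mm (SD %.4f) over %d points\n",
              x$mean_distance, x$sd_distance, x$n_points))
  invisible(x)
}

#' Pre-/post-sterilisation dimensional accuracy report
#'
#' One ADE row per available comparison: virtual design vs pre-sterilisation
#' scan, and pre- vs post-sterilisation scan. When the virtual design is not
#' available (as for externally produced guides) only the pre-vs-post row is
#' reported.
#'
#' @param virtual optional `triangle_mesh` of the designed guide.
#' @param pre,post `triangle_mesh` scans before/after sterilisation.
#' @param mask,params passed to [ade()].
#' @return data frame with columns `comparison`, `mean_distance`,
#'   `sd_distance`, `n_points`.
#' @export
sterilisation_report <- function(virtual = NULL, pre, post, mask = NULL,
                                 params = icp_params(
                                   trim_mode = "auto_threshold",
                                   sample_count = 1500L)) {
  rows <- list()
  if (!is.null(virtual)) {
    r <- ade(virtual, pre, mask, params)
    rows[[1]] <- data.frame(comparison = "virtual_vs_pre",
                            mean_distance = r$mean_distance,
                            sd_distance = r$sd_distance,
                            n_points = r$n_points)
  }
  r <- ade(pre, post, mask, params)
  rows[[length(rows) + 1L]] <- data.frame(comparison = "pre_vs_post",
                                          mean_distance = r$mean_distance,
                                          sd_distance = r$sd_distance,
                                          n_points = r$n_points)
  do.call(rbind, rows)
}
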