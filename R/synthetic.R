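#' Parameters of the parametric radius surrogate
#'
#' The surrogate is a swept surface of elliptical cross-sections with a
#' distal flare and a styloid prominence: landmarks, the shaft axis and all
#' induced transforms are analytic, so every fixture carries exact ground
#' truth. Default dimensions are adult-scale: a 120 mm distal segment, an
#' 8 x 6 mm elliptical shaft flaring to 14 x 10 mm at the articular rim,
#' an 8 mm styloid and a 3 mm lateral shaft bow.
#'
#' @param shaft_length length of the modelled segment (mm); the articular
#'   rim sits at `z = shaft_length`, distal is +z.
#' @param shaft_radius_a,shaft_radius_b elliptical shaft semi-axes (mm; a is
#'   radial/x, b is volar/y).
#' @param distal_flare_a,distal_flare_b semi-axes at the articular rim (mm).
#' @param flare_length length of the flared distal region (mm).
#' @param styloid_height styloid prominence above the rim (mm).
#' @param shaft_taper fractional widening of the shaft at its proximal end
#'   (the radius shaft is wider proximally; the taper also anchors
#'   registration along the shaft axis).
#' @param shaft_wobble fractional axial thickness modulation of the shaft
#'   (`1 + shaft_wobble * sin(2 pi u / wobble_wavelength)`): bones are not
#'   extrusions, and without it axial position would be nearly unobservable
#'   to surface registration. Symmetric about the centreline, zero at the
#'   articular rim.
#' @param wobble_wavelength wavelength of the modulation (mm).
#' @param shaft_bow lateral bow amplitude (mm, radial direction).
#' @param ring_spacing axial tessellation spacing (mm).
#' @param n_around vertices per cross-section ring (multiple of 4 so the
#'   radial, volar and ulnar meridians are exact vertices).
#' @param seed reserved for reproducibility bookkeeping.
#' @return list of class `radius_params`.
#' @export
radius_params <- function(shaft_length = 120, shaft_radius_a = 8,
                          shaft_radius_b = 6, distal_flare_a = 14,
                          distal_flare_b = 10, flare_length = 20,
                          styloid_height = 8, shaft_taper = 0.15,
                          shaft_wobble = 0.05, wobble_wavelength = 40,
                          shaft_bow = 3,
                          ring_spacing = 1.25, n_around = 48L,
                          seed = 1L) {
  p <- list(shaft_length = shaft_length, shaft_radius_a = shaft_radius_a,
            shaft_radius_b = shaft_radius_b, distal_flare_a = distal_flare_a,
            distal_flare_b = distal_flare_b, flare_length = flare_length,
            styloid_height = styloid_height, shaft_taper = shaft_taper,
            shaft_wobble = shaft_wobble,
            wobble_wavelength = wobble_wavelength,
            shaft_bow = shaft_bow,
            ring_spacing = ring_spacing, n_around = as.integer(n_around),
            seed = as.integer(seed))
  if (any(unlist(p[1:7]) <= 0) || shaft_bow < 0 || shaft_taper < 0 ||
      shaft_wobble < 0 || wobble_wavelength <= 0 || ring_spacing <= 0)
    stop("radius_params: dimensions must be positive")
  if (p$n_around %% 4L != 0L || p$n_around < 12L)
    stop("n_around must be a multiple of 4, >= 12")
  structure(p, class = "radius_params")
}

# internal: analytic cross-section of the surrogate at height u
radius_profile <- function(p, u) {
  L <- p$shaft_length
  w <- pmin(1, pmax(0, (u - (L - p$flare_length)) / p$flare_length))
  s <- w * w * (3 - 2 * w)  # smoothstep
  # modulation referenced to the rim so it vanishes exactly at u = L
  taper <- (1 + p$shaft_taper * (1 - u / L)) *
    (1 + p$shaft_wobble * sin(2 * pi * (u - L) / p$wobble_wavelength))
  a0 <- p$shaft_radius_a * taper
  b0 <- p$shaft_radius_b * taper
  list(a = a0 + s * (p$distal_flare_a - a0),
       b = b0 + s * (p$distal_flare_b - b0),
       cx = p$shaft_bow * sin(pi * u / L))
}

#' Generate a synthetic radius mesh with ground truth
#'
#' Builds the right-sided surrogate in canonical pose: distal is +z, radial
#' (styloid) is +x, volar is +y; the articular rim lies at
#' `z = shaft_length`. Returns the watertight mesh plus analytic landmarks
#' (independent of tessellation density) and the true central axis of the
#' 30-50 mm segment proximal to the CRP.
#'
#' @param params a [radius_params()] object.
#' @return list with `mesh` (`triangle_mesh`), `landmarks`
#'   (`landmark_set`), `axis_truth` (`axis_line`).
#' @export
generate_radius <- function(params = radius_params()) {
  p <- params
  L <- p$shaft_length
  us <- seq(0, L, length.out = max(2L, round(L / p$ring_spacing)) + 1L)
  th <- 2 * pi * (seq_len(p$n_around) - 1) / p$n_around
  nv <- p$n_around
  rings <- lapply(us, function(u) {
    pr <- radius_profile(p, u)
    lift <- if (u > L - p$flare_length) {
      w <- (u - (L - p$flare_length)) / p$flare_length
      p$styloid_height * (w * w) * pmax(0, cos(th))^3
    } else 0
    cbind(pr$cx + pr$a * cos(th), pr$b * sin(th), u + lift)
  })
  v <- do.call(rbind, rings)
  nr <- length(us)
  # side faces: quads between consecutive rings, outward winding
  f <- vector("list", nr - 1)
  for (i in seq_len(nr - 1)) {
    base <- (i - 1) * nv
    j <- seq_len(nv)
    jn <- c(seq_len(nv)[-1], 1L)
    f[[i]] <- rbind(cbind(base + j, base + jn, base + nv + j),
                    cbind(base + jn, base + nv + jn, base + nv + j))
  }
  faces <- do.call(rbind, f)
  # caps
  bot_c <- nrow(v) + 1L
  top_c <- nrow(v) + 2L
  top_ring <- (nr - 1) * nv + seq_len(nv)
  v <- rbind(v, c(radius_profile(p, 0)$cx, 0, 0),
             colMeans(v[top_ring, , drop = FALSE]))
  j <- seq_len(nv); jn <- c(seq_len(nv)[-1], 1L)
  faces <- rbind(faces,
                 cbind(jn, j, bot_c),                    # bottom, -z out
                 cbind(top_ring[j], top_ring[jn], top_c)) # top, +z out
  mesh <- triangle_mesh(v, faces)

  prd <- radius_profile(p, L)
  crp <- c(prd$cx - prd$a, 0, L)                     # ulnar rim (theta = pi)
  styloid <- c(prd$cx + prd$a, 0, L + p$styloid_height)  # theta = 0
  u_vr <- L - 10
  prv <- radius_profile(p, u_vr)
  volar_ref <- c(prv$cx, prv$b, u_vr)                # theta = pi/2
  lm <- landmark_set(crp, styloid, volar_ref, side = "right")

  # true axis: line fit of the analytic centreline 30-50 mm proximal of CRP
  uu <- seq(L - 50, L - 30, by = 0.1)
  cl <- cbind(p$shaft_bow * sin(pi * uu / L), 0, uu)
  pc <- prcomp(cl, center = TRUE)
  dirn <- pc$rotation[, 1]
  if (dirn[3] < 0) dirn <- -dirn
  axis_truth <- structure(list(point = colMeans(cl), direction = dirn),
                          class = "axis_line")
  list(mesh = mesh, landmarks = lm, axis_truth = axis_truth)
}

#' Malunion specification
#'
#' A dorsally angulated, shortened distal radius malunion: the distal
#' fragment is rotated about the frame axes at the osteotomy-plane centroid
#' and displaced proximally. Dorsal tilt and radial inclination loss are
#' entered as positive magnitudes (dorsal = negative volar rotation).
#'
#' @param plane osteotomy/fracture `plane3`, normal pointing distally.
#' @param dorsal_tilt_deg dorsal angulation (0-40 degrees).
#' @param radial_inclination_loss_deg inclination loss (degrees).
#' @param shortening_mm proximal displacement (0-10 mm).
#' @param axial_rotation_deg rotation about the shaft axis (degrees).
#' @return list of class `malunion_spec`.
#' @export
malunion_spec <- function(plane, dorsal_tilt_deg = 20,
                          radial_inclination_loss_deg = 5,
                          shortening_mm = 3, axial_rotation_deg = 0) {
  if (dorsal_tilt_deg < 0 || dorsal_tilt_deg > 40)
    stop("dorsal tilt must be in [0, 40] degrees")
  if (shortening_mm < 0 || shortening_mm > 10)
    stop("shortening must be in [0, 10] mm")
  structure(list(plane = plane, dorsal_tilt_deg = dorsal_tilt_deg,
                 radial_inclination_loss_deg = radial_inclination_loss_deg,
                 shortening_mm = shortening_mm,
                 axial_rotation_deg = axial_rotation_deg),
            class = "malunion_spec")
}

#' Induce a malunion on a healthy (canonical-pose) radius
#'
#' Cuts at the spec's plane and rigidly moves the distal fragment by the
#' transform composed from the spec: rotations about the canonical frame
#' axes at the plane centroid (`R = Rz Ry Rx`, dorsal tilt entering as a
#' negative x rotation), then shortening along -z. The junction is left as
#' an open step; the exact transform is returned as ground truth.
#'
#' @param healthy `triangle_mesh` in canonical pose (see
#'   [generate_radius()]).
#' @param spec a [malunion_spec()].
#' @param centre optional rotation centre; defaults to the centroid of the
#'   cut cross-section boundary.
#' @return list with `mesh` (malunited), `transform` (the malunion
#'   `rigid_transform`), `proximal`, `distal_original`.
#' @export
induce_malunion <- function(healthy, spec, centre = NULL) {
  parts <- cut_with_plane(healthy, spec$plane)
  if (nrow(parts$positive$faces) == 0)
    stop("malunion plane does not separate a distal fragment")
  if (is.null(centre)) {
    onplane <- abs(signed_distance(parts$positive$vertices, spec$plane)) < 1e-6
    centre <- if (any(onplane))
      colMeans(parts$positive$vertices[onplane, , drop = FALSE])
    else spec$plane$point
  }
  r <- rotation_about_axis("z", spec$axial_rotation_deg) %*%
    rotation_about_axis("y", -spec$radial_inclination_loss_deg) %*%
    rotation_about_axis("x", -spec$dorsal_tilt_deg)
  t <- centre - drop(r %*% centre) + c(0, 0, -spec$shortening_mm)
  tf <- rigid_transform(r, t)
  malunited <- merge_meshes(parts$negative, apply_transform(tf, parts$positive))
  list(mesh = malunited, transform = tf, proximal = parts$negative,
       distal_original = parts$positive)
}

#' Residual-error specification for one guide arm
#'
#' Per-parameter scales of the signed residual correction errors a guide arm
#' leaves after simulated surgery. Errors are sampled independently as
#' centred normals; the scale of each parameter is chosen so the expected
#' absolute error matches a target magnitude (`sigma = target /
#' sqrt(2/pi)`, the folded-normal mean relation).
#'
#' @param rot_sd_deg length-3 vector of rotation SDs (x, y, z; degrees).
#' @param trans_sd_mm length-3 vector of translation SDs (x, y, z; mm).
#' @return list of class `residual_error_spec`.
#' @export
residual_error_spec <- function(rot_sd_deg = c(3, 2, 3),
                                trans_sd_mm = c(1, 1, 1)) {
  stopifnot(length(rot_sd_deg) == 3, length(trans_sd_mm) == 3,
            all(rot_sd_deg >= 0), all(trans_sd_mm >= 0))
  structure(list(rot_sd_deg = rot_sd_deg, trans_sd_mm = trans_sd_mm),
            class = "residual_error_spec")
}

#' Arm error specifications emulating the study's observed magnitudes
#'
#' Normal scales derived from the published per-arm mean absolute errors via
#' the folded-normal relation `sigma = mean_abs / sqrt(2/pi)`: in-house
#' mean absolute rotation errors (2.61, 1.96, 3.39) degrees and translation
#' errors (0.9, 0.98, 0.9) mm; external (4.93, 3.13, 3.96) degrees and
#' (1.28, 1.08, 1.29) mm.
#'
#' @return named list with `in_house` and `external`
#'   [residual_error_spec()] objects.
#' @export
default_arm_specs <- function() {
  k <- sqrt(2 / pi)
  list(in_house = residual_error_spec(c(2.61, 1.96, 3.39) / k,
                                      c(0.9, 0.98, 0.9) / k),
       external = residual_error_spec(c(4.93, 3.13, 3.96) / k,
                                      c(1.28, 1.08, 1.29) / k))
}

# internal: sample one clinical_errors draw from a residual_error_spec
sample_residual <- function(spec) {
  r <- rnorm(3, 0, spec$rot_sd_deg)
  t <- rnorm(3, 0, spec$trans_sd_mm)
  clinical_errors(r[1], r[2], r[3], t[1], t[2], t[3])
}

#' Simulate surgery with a guide arm's residual errors
#'
#' Places the distal fragment at the planned corrected pose perturbed by a
#' residual transform composed from errors sampled in the anatomical frame
#' at the frame origin; the sampled six parameters are stored as ground
#' truth.
#'
#' @param case a `synthetic_case` (see [generate_case()]).
#' @param spec a [residual_error_spec()].
#' @param seed integer seed (fixed seed gives identical errors).
#' @return list with `mesh` (result bone), `injected`
#'   (`clinical_errors` truth).
#' @export
simulate_surgery <- function(case, spec, seed = 1L) {
  injected <- with_seed(seed, sample_residual(spec))
  w <- world_alignment(case$frame)
  p_frame <- compose_clinical(injected)
  p_world <- compose_transforms(invert_transform(w),
                                compose_transforms(p_frame, w))
  distal_result <- apply_transform(p_world, case$plan$distal_part_corrected)
  list(mesh = merge_meshes(case$plan$proximal_part, distal_result),
       injected = injected)
}

#' Simulated optical scan: vertex noise along normals
#'
#' Displaces every vertex along its outward normal by centred Gaussian
#' noise; `sigma = 0` returns the input unchanged. The default scale in the
#' study pipeline is 0.05 mm, the optical scanner's single-shot error.
#'
#' @param mesh a `triangle_mesh`. @param sigma noise SD in mm (>= 0).
#' @param seed integer seed.
#' @return a `triangle_mesh`.
#' @export
simulate_scan <- function(mesh, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(mesh)
  n <- vertex_normals(mesh)
  eps <- with_seed(seed, rnorm(nrow(mesh$vertices), 0, sigma))
  triangle_mesh(mesh$vertices + eps * n, mesh$faces, validate = FALSE)
}

#' Simulated optical scan as a point cloud
#'
#' Emulates the scanner output directly: `n` points resampled area-weighted
#' from the surface, each displaced along its face normal by centred
#' Gaussian noise of SD `sigma`. Unlike [simulate_scan()] (which perturbs
#' mesh vertices), each returned point carries the full noise magnitude,
#' matching a scanner's per-point error model.
#'
#' @param mesh a `triangle_mesh`. @param n number of scan points.
#' @param sigma noise SD in mm (>= 0). @param seed integer seed.
#' @return n x 3 matrix of scan points.
#' @export
simulate_scan_points <- function(mesh, n, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  areas <- face_areas(mesh)
  with_seed(seed, {
    fi <- sample.int(length(areas), n, replace = TRUE, prob = areas)
    r1 <- sqrt(runif(n)); r2 <- runif(n)
    a <- mesh$vertices[mesh$faces[fi, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[fi, 2], , drop = FALSE]
    cc <- mesh$vertices[mesh$faces[fi, 3], , drop = FALSE]
    pts <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * cc
    e1 <- b - a; e2 <- cc - a
    fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    fn <- fn / sqrt(rowSums(fn^2))
    pts + rnorm(n, 0, sigma) * fn
  })
}

#' Generate one complete synthetic case
#'
#' Healthy surrogate, mirrored reference (the mirrored contralateral of a
#' symmetric patient equals the healthy bone exactly), induced malunion with
#' stored transform, osteotomy plan via [plan_correction()], and the
#' anatomical frame of the planned model.
#'
#' @param seed integer seed driving all of the case's randomness.
#' @param malunion_ranges list of `c(min, max)` ranges for
#'   `dorsal_tilt_deg`, `radial_inclination_loss_deg`, `shortening_mm`,
#'   `axial_rotation_deg`.
#' @param radius_param_ranges optional list of `c(min, max)` ranges for
#'   numeric [radius_params()] fields to vary between cases.
#' @param params an [icp_params()] block for planning.
#' @param plane_offset_mm osteotomy plane distance proximal to the CRP
#'   (default 20 mm, transverse).
#' @return list of class `synthetic_case`: `healthy`, `healthy_mirrored`,
#'   `malunited`, `landmarks` (malunited pose), `landmarks_planned`,
#'   `malunion_transform`, `malunion`, `plan`, `frame`, `axis_truth`,
#'   `seed`.
#' @export
generate_case <- function(seed = 1L,
                          malunion_ranges = list(
                            dorsal_tilt_deg = c(10, 30),
                            radial_inclination_loss_deg = c(0, 10),
                            shortening_mm = c(2, 8),
                            axial_rotation_deg = c(-8, 8)),
                          radius_param_ranges = list(
                            shaft_radius_a = c(7, 9),
                            distal_flare_a = c(13, 15),
                            styloid_height = c(7, 9),
                            shaft_bow = c(2, 4)),
                          params = measurement_icp_params(),
                          plane_offset_mm = 20) {
  draws <- with_seed(seed, {
    rp <- lapply(radius_param_ranges, function(r) runif(1, r[1], r[2]))
    mu <- lapply(malunion_ranges, function(r) runif(1, r[1], r[2]))
    list(rp = rp, mu = mu)
  })
  rp <- do.call(radius_params, c(draws$rp, list(seed = seed)))
  gen <- generate_radius(rp)
  L <- rp$shaft_length
  plane <- plane3(c(0, 0, L - plane_offset_mm), c(0, 0, 1))
  mspec <- do.call(malunion_spec, c(list(plane = plane), draws$mu))
  mal <- induce_malunion(gen$mesh, mspec)
  # landmarks ride with the distal fragment
  lm_mal <- landmark_set(transform_points(mal$transform, gen$landmarks$crp),
                         transform_points(mal$transform,
                                          gen$landmarks$styloid_tip),
                         transform_points(mal$transform,
                                          gen$landmarks$volar_ref),
                         side = gen$landmarks$side)
  # mirrored healthy contralateral == healthy for the symmetric surrogate
  healthy_mirrored <- gen$mesh
  plan_params <- params
  plan_params$seed <- params$seed + 1L
  # coarse landmark-based init (the interactive positioning a planner does);
  # 1 mm jitter emulates manual placement so ICP does the real alignment
  lm_h <- rbind(gen$landmarks$crp, gen$landmarks$styloid_tip,
                gen$landmarks$volar_ref)
  jit <- with_seed(seed + 13L, matrix(runif(9, -1, 1), 3, 3))
  init <- kabsch(transform_points(mal$transform, lm_h) + jit, lm_h)
  plan <- plan_correction(mal$mesh, healthy_mirrored, plane, plan_params,
                          init = init)
  lm_planned <- landmark_set(
    transform_points(plan$correction, lm_mal$crp),
    transform_points(plan$correction, lm_mal$styloid_tip),
    transform_points(plan$correction, lm_mal$volar_ref),
    side = lm_mal$side)
  planned <- merge_meshes(plan$proximal_part, plan$distal_part_corrected)
  frame <- build_frame(planned, lm_planned)
  structure(list(healthy = gen$mesh, healthy_mirrored = healthy_mirrored,
                 malunited = mal$mesh, landmarks = lm_mal,
                 landmarks_planned = lm_planned,
                 malunion_transform = mal$transform, malunion = mal,
                 malunion_spec = mspec, plan = plan, frame = frame,
                 axis_truth = gen$axis_truth, radius_params = rp,
                 seed = seed),
            class = "synthetic_case")
}

#' Generate a whole synthetic study with measured and true errors
#'
#' For `n_cases` seeded cases, simulates surgery in both guide arms, runs
#' the full measurement pipeline on each result (optionally after a
#' simulated optical scan) and returns the per-case table of measured and
#' injected errors, ready for [study_table()].
#'
#' @param n_cases number of patients (default 16, the study cohort size).
#' @param arm_specs named list of [residual_error_spec()] per arm (default
#'   [default_arm_specs()]).
#' @param seed master integer seed.
#' @param scan_sigma optical-scan vertex noise SD in mm (0 = noiseless).
#' @param params an [icp_params()] block for planning and measurement.
#' @param keep_cases also return the full `synthetic_case` objects.
#' @param ... passed to [generate_case()].
#' @return list with `per_case` (data frame: case_id, guide_arm, measured
#'   rot_x..trans_z, true_rot_x..true_trans_z, stage residuals) and
#'   optionally `cases`.
#' @export
generate_study <- function(n_cases = 16L, arm_specs = default_arm_specs(),
                           seed = 1L, scan_sigma = 0,
                           params = measurement_icp_params(),
                           keep_cases = FALSE, ...) {
  rows <- list()
  cases <- if (keep_cases) vector("list", n_cases) else NULL
  for (i in seq_len(n_cases)) {
    case_seed <- (seed * 10000L + i * 17L) %% .Machine$integer.max
    case <- generate_case(seed = case_seed, params = params, ...)
    if (keep_cases) cases[[i]] <- case
    for (arm in names(arm_specs)) {
      arm_seed <- (case_seed + 7919L * match(arm, names(arm_specs))) %%
        .Machine$integer.max
      sim <- simulate_surgery(case, arm_specs[[arm]], seed = arm_seed)
      result <- if (scan_sigma > 0)
        simulate_scan(sim$mesh, scan_sigma, seed = arm_seed + 1L)
      else sim$mesh
      meas <- measure_errors(result, case$plan, case$landmarks_planned,
                             params)
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = i, guide_arm = arm,
        rot_x = meas$rot_x_deg, rot_y = meas$rot_y_deg,
        rot_z = meas$rot_z_deg, trans_x = meas$trans_x_mm,
        trans_y = meas$trans_y_mm, trans_z = meas$trans_z_mm,
        true_rot_x = sim$injected$rot_x_deg,
        true_rot_y = sim$injected$rot_y_deg,
        true_rot_z = sim$injected$rot_z_deg,
        true_trans_x = sim$injected$trans_x_mm,
        true_trans_y = sim$injected$trans_y_mm,
        true_trans_z = sim$injected$trans_z_mm,
        proximal_residual = attr(meas, "proximal_residual"),
        distal_residual = attr(meas, "distal_residual"))
    }
  }
  out <- list(per_case = do.call(rbind, rows))
  if (keep_cases) out$cases <- cases
  out
}

#' Error-level study simulation (no meshes)
#'
#' Samples the per-case injected errors of both arms directly from their
#' [residual_error_spec()] distributions, without the geometric pipeline.
#' Appropriate for statistical calibration at many replicates, given that
#' the geometric pipeline recovers injected errors to well under the
#' noninferiority margins (the end-to-end acceptance property).
#'
#' @inheritParams generate_study
#' @return data frame in the [study_table()] input schema.
#' @export
simulate_study_errors <- function(n_cases = 16L,
                                  arm_specs = default_arm_specs(),
                                  seed = 1L) {
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_cases)) {
      for (arm in names(arm_specs)) {
        e <- sample_residual(arm_specs[[arm]])
        rows[[length(rows) + 1L]] <- data.frame(
          case_id = i, guide_arm = arm,
          rot_x = e$rot_x_deg, rot_y = e$rot_y_deg, rot_z = e$rot_z_deg,
          trans_x = e$trans_x_mm, trans_y = e$trans_y_mm,
          trans_z = e$trans_z_mm)
      }
    }
    do.call(rbind, rows)
  })
}
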