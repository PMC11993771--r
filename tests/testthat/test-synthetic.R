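# ground-truthed synthetic anatomy

test_that("generate_radius is deterministic with analytic landmarks", {
  par <- coarse_radius_params()
  g1 <- generate_radius(par)
  g2 <- generate_radius(par)
  f1 <- tempfile(fileext = ".stl"); f2 <- tempfile(fileext = ".stl")
  write_stl(g1$mesh, f1); write_stl(g2$mesh, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # doubling tessellation density leaves stored landmarks unchanged
  fine <- radius_params(ring_spacing = par$ring_spacing / 2,
                        n_around = par$n_around * 2L)
  gf <- generate_radius(fine)
  expect_identical(gf$landmarks$crp, g1$landmarks$crp)
  expect_identical(gf$landmarks$styloid_tip, g1$landmarks$styloid_tip)
  expect_identical(gf$landmarks$volar_ref, g1$landmarks$volar_ref)
  # landmarks lie on (within 1 mm of) the mesh surface
  for (pt in list(g1$landmarks$crp, g1$landmarks$styloid_tip,
                  g1$landmarks$volar_ref))
    expect_lt(closest_points(g1$mesh, pt)$distance, 1)
  # mesh passes validity, frame constructible
  expect_silent(validate_mesh(g1$mesh))
  expect_s3_class(build_frame(g1$mesh, g1$landmarks), "anatomical_frame")
  expect_error(radius_params(shaft_length = -1), "positive")
})

test_that("induce_malunion stores the exact transform with correct signs", {
  gen <- generate_radius(coarse_radius_params())
  plane <- plane3(c(0, 0, 100), c(0, 0, 1))
  # all-zero spec leaves the bone unchanged
  null_spec <- malunion_spec(plane, 0, 0, 0, 0)
  mal0 <- induce_malunion(gen$mesh, null_spec)
  # same surface (the cut introduces split vertices but no displacement)
  expect_lt(max(closest_points(gen$mesh, mal0$mesh$vertices)$distance), 1e-9)
  expect_equal(mesh_area(mal0$mesh), mesh_area(gen$mesh), tolerance = 1e-9)
  expect_equal(mal0$transform$rotation, diag(3), tolerance = 1e-12)
  # dorsal tilt 20 deg reads back as -20 deg volar rotation
  spec <- malunion_spec(plane, dorsal_tilt_deg = 20,
                        radial_inclination_loss_deg = 0, shortening_mm = 0,
                        axial_rotation_deg = 0)
  dec <- decompose_transform(induce_malunion(gen$mesh, spec)$transform)
  expect_equal(dec$rot_x_deg, -20, tolerance = 1e-9)
  # random specs: stored rotation decomposes to the spec values
  set.seed(81)
  for (i in 1:20) {
    sp <- malunion_spec(plane, runif(1, 0, 35), runif(1, -10, 10),
                        runif(1, 0, 9), runif(1, -15, 15))
    dec <- decompose_transform(induce_malunion(gen$mesh, sp)$transform)
    expect_equal(dec$rot_x_deg, -sp$dorsal_tilt_deg, tolerance = 1e-9)
    expect_equal(dec$rot_y_deg, -sp$radial_inclination_loss_deg,
                 tolerance = 1e-9)
    expect_equal(dec$rot_z_deg, sp$axial_rotation_deg, tolerance = 1e-9)
  }
  expect_error(malunion_spec(plane, dorsal_tilt_deg = 50), "40")
})

test_that("simulate_scan: exact at sigma 0, folded-normal displacement", {
  gen <- generate_radius(coarse_radius_params())
  expect_identical(simulate_scan(gen$mesh, 0, 1), gen$mesh)
  noisy1 <- simulate_scan(gen$mesh, 0.05, seed = 1)
  noisy2 <- simulate_scan(gen$mesh, 0.05, seed = 2)
  expect_equal(nrow(noisy1$vertices), nrow(gen$mesh$vertices))
  expect_false(isTRUE(all.equal(noisy1$vertices, noisy2$vertices)))
  disp <- sqrt(rowSums((noisy1$vertices - gen$mesh$vertices)^2))
  expect_equal(mean(disp), 0.05 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("simulate_surgery: zero-scale exactness, determinism, recovery", {
  case <- generate_case(seed = 301)
  zero <- residual_error_spec(c(0, 0, 0), c(0, 0, 0))
  sim0 <- simulate_surgery(case, zero, seed = 1)
  planned <- merge_meshes(case$plan$proximal_part,
                          case$plan$distal_part_corrected)
  expect_equal(sim0$mesh$vertices, planned$vertices, tolerance = 1e-9)
  s1 <- simulate_surgery(case, default_arm_specs()$in_house, seed = 9)
  s2 <- simulate_surgery(case, default_arm_specs()$in_house, seed = 9)
  expect_identical(s1$injected, s2$injected)
  expect_identical(s1$mesh$vertices, s2$mesh$vertices)
  # injected truth recovered by the measurement pipeline, noiseless
  m <- measure_errors(s1$mesh, case$plan, case$landmarks_planned)
  expect_lt(max(abs(errors_vec(m)[1:3] - errors_vec(s1$injected)[1:3])), 0.2)
  expect_lt(max(abs(errors_vec(m)[4:6] - errors_vec(s1$injected)[4:6])), 0.1)
})

test_that("generate_study produces a reproducible paired table", {
  st1 <- simulate_study_errors(16, seed = 42)
  st2 <- simulate_study_errors(16, seed = 42)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(st1, f1, row.names = FALSE); write.csv(st2, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(nrow(st1), 32)
  expect_setequal(unique(st1$guide_arm), c("in_house", "external"))

  # mesh-backed study, small n for runtime: measured ~ injected
  st <- generate_study(n_cases = 2, seed = 7)
  pc <- st$per_case
  expect_equal(nrow(pc), 4)
  expect_lt(max(abs(pc$rot_x - pc$true_rot_x)), 0.2)
  expect_lt(max(abs(pc$trans_z - pc$true_trans_z)), 0.1)
  # study_table consumes the measured columns directly
  tab <- study_table(pc)
  expect_s3_class(tab$noninferiority$volar_tilt, "noninferiority_result")
})
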