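# anatomical coordinate system

test_that("central_axis: exact on a cylinder, equivariant under tilt", {
  cyl <- make_cylinder(r = 8, h = 80)
  ax <- central_axis(cyl, crp = c(0, 0, 80))
  expect_lt(angle_between_deg(ax$direction, c(0, 0, 1)), 1e-4)
  # tilt 10 degrees about x
  tf <- rigid_transform(rotation_about_axis("x", 10))
  ax2 <- central_axis(apply_transform(tf, cyl),
                      crp = transform_points(tf, c(0, 0, 80)))
  expect_lt(angle_between_deg(ax2$direction,
                              drop(tf$rotation %*% c(0, 0, 1))), 0.01)
  # short mesh: segment empty
  short <- make_cylinder(r = 8, h = 25)
  expect_error(central_axis(short, crp = c(0, 0, 25)), "insufficient shaft")
})

test_that("central_axis matches generator truth and ignores tessellation", {
  par <- coarse_radius_params()
  gen <- generate_radius(par)
  ax <- central_axis(gen$mesh, gen$landmarks$crp)
  expect_lt(angle_between_deg(ax$direction, gen$axis_truth$direction), 0.5)
  # refined tessellation changes the direction by < 0.2 degrees
  fine <- radius_params(ring_spacing = 1, n_around = 64L)
  coarse_same <- radius_params(ring_spacing = 2.5, n_around = 32L)
  axf <- central_axis(generate_radius(fine)$mesh,
                      generate_radius(fine)$landmarks$crp)
  axc <- central_axis(generate_radius(coarse_same)$mesh,
                      generate_radius(coarse_same)$landmarks$crp)
  expect_lt(angle_between_deg(axf$direction, axc$direction), 0.2)
  # straight shaft: axis equals +z
  straight <- generate_radius(radius_params(shaft_bow = 1e-9,
                                            ring_spacing = 2.5,
                                            n_around = 32L))
  axs <- central_axis(straight$mesh, straight$landmarks$crp)
  expect_lt(angle_between_deg(axs$direction, c(0, 0, 1)), 0.1)
})

test_that("build_frame: canonical case, volar flip and sign rules", {
  cyl <- make_cylinder(r = 8, h = 80)
  shift <- rigid_transform(diag(3), c(0, 0, -80))  # crp at origin
  cyl0 <- apply_transform(shift, cyl)
  lm <- landmark_set(c(0, 0, 0), c(10, 0, -2), c(0, 5, -10), "right")
  fr <- build_frame(cyl0, lm)
  expect_equal(fr$x_axis, c(1, 0, 0), tolerance = 1e-6)
  expect_equal(fr$y_axis, c(0, 1, 0), tolerance = 1e-6)
  expect_equal(fr$z_axis, c(0, 0, 1), tolerance = 1e-6)
  expect_equal(fr$handedness, "right")
  # volar reference on the other side flips y, handedness left
  lm2 <- landmark_set(c(0, 0, 0), c(10, 0, -2), c(0, -5, -10), "right")
  fr2 <- build_frame(cyl0, lm2)
  expect_equal(fr2$y_axis, c(0, -1, 0), tolerance = 1e-6)
  expect_equal(fr2$handedness, "left")
  # without volar_ref the side annotation decides
  lm3 <- landmark_set(c(0, 0, 0), c(10, 0, -2), NULL, "left")
  expect_equal(build_frame(cyl0, lm3)$y_axis, c(0, -1, 0), tolerance = 1e-6)
  # styloid too close to the axis
  lm4 <- landmark_set(c(0, 0, 0), c(1, 0, -2), c(0, 5, -10), "right")
  expect_error(build_frame(cyl0, lm4), "ill-conditioned")
})

test_that("frame construction is equivariant under rigid motion", {
  gen <- generate_radius(coarse_radius_params())
  fr <- build_frame(gen$mesh, gen$landmarks)
  set.seed(17)
  for (i in 1:3) {
    tf <- random_transform(max_angle_deg = 40, max_trans = 30)
    lm2 <- landmark_set(transform_points(tf, gen$landmarks$crp),
                        transform_points(tf, gen$landmarks$styloid_tip),
                        transform_points(tf, gen$landmarks$volar_ref),
                        gen$landmarks$side)
    fr2 <- build_frame(apply_transform(tf, gen$mesh), lm2)
    for (axn in c("x_axis", "y_axis", "z_axis"))
      expect_lt(angle_between_deg(fr2[[axn]],
                                  drop(tf$rotation %*% fr[[axn]])), 0.1)
    expect_lt(max(abs(fr2$origin - transform_points(tf, fr$origin))), 0.05)
  }
})

test_that("world_alignment maps the frame onto the world basis", {
  # canonical frame at the origin -> identity
  cyl <- make_cylinder(r = 8, h = 80)
  cyl0 <- apply_transform(rigid_transform(diag(3), c(0, 0, -80)), cyl)
  lm <- landmark_set(c(0, 0, 0), c(10, 0, -2), c(0, 5, -10), "right")
  fr <- build_frame(cyl0, lm)
  w <- world_alignment(fr)
  expect_equal(w$rotation, diag(3), tolerance = 1e-6)
  expect_equal(w$translation, c(0, 0, 0), tolerance = 1e-6)
  # translated frame
  fr_t <- fr
  fr_t$origin <- fr$origin + c(5, 5, 5)
  expect_equal(world_alignment(fr_t)$translation, c(-5, -5, -5),
               tolerance = 1e-6)
  # property: 100 seeded random proper frames
  set.seed(23)
  for (i in 1:100) {
    r <- random_transform()$rotation
    frame <- structure(list(origin = rnorm(3, sd = 50), x_axis = r[, 1],
                            y_axis = r[, 2], z_axis = r[, 3],
                            handedness = "right"),
                       class = "anatomical_frame")
    ww <- world_alignment(frame)
    expect_lt(max(abs(drop(ww$rotation %*% frame$x_axis) - c(1, 0, 0))),
              1e-9)
    expect_lt(max(abs(drop(ww$rotation %*% frame$z_axis) - c(0, 0, 1))),
              1e-9)
    expect_lt(max(abs(transform_points(ww, frame$origin))), 1e-9)
  }
  # left-handed frame yields an improper transform
  frL <- fr
  frL$y_axis <- -fr$y_axis
  frL$handedness <- "left"
  expect_false(world_alignment(frL)$proper)
})

test_that("landmark JSON round trip", {
  lm <- landmark_set(c(1, 2, 3), c(4, 5, 6), NULL, "left")
  f <- tempfile(fileext = ".json")
  write_landmarks_json(lm, f)
  lm2 <- read_landmarks_json(f)
  expect_equal(lm2$crp, lm$crp)
  expect_null(lm2$volar_ref)
  expect_equal(lm2$side, "left")
})
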