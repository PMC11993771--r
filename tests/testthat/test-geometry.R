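# mesh/transform/STL/cut primitives

test_that("STL round trip: ASCII single triangle and binary soup", {
  ascii <- tempfile(fileext = ".stl")
  writeLines(c(
    "solid one",
    "  facet normal 0 0 1",
    "    outer loop",
    "      vertex 0 0 0",
    "      vertex 1 0 0",
    "      vertex 0 1 0",
    "    endloop",
    "  endfacet",
    "endsolid one"), ascii)
  m <- read_stl(ascii)
  expect_equal(nrow(m$vertices), 3)
  expect_equal(nrow(m$faces), 1)
  expect_equal(sort(m$vertices[, 1]), c(0, 0, 1))

  # binary round trip of a 500+ vertex synthetic mesh
  cyl <- make_cylinder(n_around = 24, n_rings = 25)
  expect_gt(nrow(cyl$vertices), 500)
  f1 <- tempfile(fileext = ".stl")
  write_stl(cyl, f1, "binary")
  m1 <- read_stl(f1)
  # identical vertex sets (order may differ after welding)
  key <- function(v) sort(sprintf("%a_%a_%a", v[, 1], v[, 2], v[, 3]))
  # coordinates pass through float32; round trip of the re-read mesh is exact
  f2 <- tempfile(fileext = ".stl")
  write_stl(m1, f2, "binary")
  m2 <- read_stl(f2)
  expect_identical(key(m1$vertices), key(m2$vertices))
  expect_equal(nrow(m1$faces), nrow(cyl$faces))
  expect_equal(mesh_area(m1), mesh_area(cyl), tolerance = 1e-6)
  # binary files are byte-identical on rewrite
  f3 <- tempfile(fileext = ".stl")
  write_stl(m2, f3, "binary")
  expect_identical(readBin(f2, "raw", file.size(f2)),
                   readBin(f3, "raw", file.size(f3)))

  # ascii dialect round trip preserves geometry to float precision
  f4 <- tempfile(fileext = ".stl")
  write_stl(cyl, f4, "ascii")
  m4 <- read_stl(f4)
  expect_equal(mesh_area(m4), mesh_area(cyl), tolerance = 1e-6)
})

test_that("malformed STL inputs raise parse errors", {
  f <- tempfile(fileext = ".stl")
  cyl <- make_cylinder(n_around = 12, n_rings = 5)
  write_stl(cyl, f, "binary")
  raw <- readBin(f, "raw", file.size(f))
  writeBin(raw[1:(length(raw) - 50)], f)  # drop one facet
  expect_error(read_stl(f), "facet count mismatch.*byte offset 80")
  f2 <- tempfile(fileext = ".stl")
  writeLines(c("solid x", "  facet normal 0 0 1", "    outer loop",
               "      vertex 0 0 0", "      vertex 1 0 0",
               "    endloop", "  endfacet", "endsolid x"), f2)
  expect_error(read_stl(f2), "vertex")
  expect_error(read_stl(tempfile()), "not found")
})

test_that("cut_with_plane splits, conserves area, and handles misses", {
  cube <- make_cube()
  pl <- plane3(c(0, 0, 0.5), c(0, 0, 1))
  parts <- cut_with_plane(cube, pl)
  expect_equal(diff(range(parts$positive$vertices[, 3])), 0.5)
  expect_equal(diff(range(parts$negative$vertices[, 3])), 0.5)
  expect_true(all(signed_distance(parts$positive$vertices, pl) > -1e-6))
  expect_true(all(signed_distance(parts$negative$vertices, pl) < 1e-6))
  expect_equal(mesh_area(parts$positive) + mesh_area(parts$negative),
               mesh_area(cube), tolerance = 1e-9)
  # oblique plane through a cylinder: area conservation under splitting
  cyl <- make_cylinder()
  pl2 <- plane3(c(0, 0, 37.3), c(0.3, 0.2, 1))
  p2 <- cut_with_plane(cyl, pl2)
  expect_equal(mesh_area(p2$positive) + mesh_area(p2$negative),
               mesh_area(cyl), tolerance = 1e-6)
  # degenerate: plane misses the cube
  expect_warning(p3 <- cut_with_plane(cube, plane3(c(0, 0, 10), c(0, 0, 1))),
                 "does not intersect")
  expect_equal(nrow(p3$positive$faces), 0)
  expect_equal(mesh_area(p3$negative), mesh_area(cube), tolerance = 1e-12)
})

test_that("synthetic radius cut at osteotomy plane separates the styloid", {
  gen <- generate_radius(coarse_radius_params())
  L <- coarse_radius_params()$shaft_length
  pl <- plane3(c(0, 0, L - 20), c(0, 0, 1))
  parts <- cut_with_plane(gen$mesh, pl)
  sty <- gen$landmarks$styloid_tip
  d_pos <- min(closest_points(parts$positive, sty)$distance)
  d_neg <- min(closest_points(parts$negative, sty)$distance)
  expect_lt(d_pos, 1)   # styloid on the distal part
  expect_gt(d_neg, 5)   # far from the proximal part
})

test_that("mirror is an involution that preserves orientation bookkeeping", {
  pl <- plane3(c(0, 0, 0), c(1, 0, 0))
  expect_equal(transform_points(reflection_transform(pl), c(1, 0, 0)),
               c(-1, 0, 0))
  cyl <- make_cylinder(n_around = 12, n_rings = 5)
  m2 <- mirror_mesh(mirror_mesh(cyl, pl), pl)
  expect_equal(m2$vertices, cyl$vertices, tolerance = 1e-12)
  expect_equal(m2$faces, cyl$faces)
  expect_false(reflection_transform(pl)$proper)
  # mirroring flips properness under composition
  tf <- random_transform()
  expect_false(compose_transforms(reflection_transform(pl), tf)$proper)
})

test_that("rigid transforms compose, invert and validate", {
  p <- c(1, 0, 0)
  expect_equal(transform_points(rigid_transform(), p), p)
  rot90 <- rigid_transform(rotation_about_axis("z", 90))
  expect_equal(transform_points(rot90, p), c(0, 1, 0), tolerance = 1e-12)
  expect_error(rigid_transform(matrix(1:9, 3, 3)), "orthogonal")
  set.seed(11)
  worst <- 0
  for (i in 1:1000) {
    tf <- random_transform()
    res <- compose_transforms(tf, invert_transform(tf))
    worst <- max(worst, max(abs(res$rotation - diag(3))),
                 max(abs(res$translation)))
  }
  expect_lt(worst, 1e-9)
  # apply distributes over composition
  a <- random_transform(); b <- random_transform()
  pts <- matrix(rnorm(30), 10, 3)
  expect_equal(transform_points(compose_transforms(a, b), pts),
               transform_points(a, transform_points(b, pts)),
               tolerance = 1e-10)
})

test_that("transform and plane JSON round trip", {
  tf <- random_transform()
  f <- tempfile(fileext = ".json")
  write_transform_json(tf, f)
  tf2 <- read_transform_json(f)
  expect_equal(tf2$rotation, tf$rotation, tolerance = 1e-12)
  expect_equal(tf2$translation, tf$translation, tolerance = 1e-12)
  pl <- plane3(c(1, 2, 3), c(0.3, -0.4, 0.5))
  write_plane_json(pl, f)
  pl2 <- read_plane_json(f)
  expect_equal(pl2$normal, pl$normal, tolerance = 1e-12)
})
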