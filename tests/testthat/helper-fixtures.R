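# fixtures built in code: small meshes with known geometry, random rigid
# transforms, and a coarse radius surrogate for speed

# open cylinder along +z, radius r, from z = 0 to z = h, capped
make_cylinder <- function(r = 8, h = 80, n_around = 24, n_rings = 41) {
  th <- 2 * pi * (seq_len(n_around) - 1) / n_around
  zs <- seq(0, h, length.out = n_rings)
  v <- do.call(rbind, lapply(zs, function(z) cbind(r * cos(th),
                                                   r * sin(th), z)))
  f <- list()
  for (i in seq_len(n_rings - 1)) {
    base <- (i - 1) * n_around
    j <- seq_len(n_around)
    jn <- c(j[-1], 1L)
    f[[i]] <- rbind(cbind(base + j, base + jn, base + n_around + j),
                    cbind(base + jn, base + n_around + jn, base + n_around + j))
  }
  faces <- do.call(rbind, f)
  bot <- nrow(v) + 1L; top <- nrow(v) + 2L
  v <- rbind(v, c(0, 0, 0), c(0, 0, h))
  j <- seq_len(n_around); jn <- c(j[-1], 1L)
  topring <- (n_rings - 1) * n_around
  faces <- rbind(faces, cbind(jn, j, bot),
                 cbind(topring + j, topring + jn, top))
  triangle_mesh(v, faces)
}

# unit cube surface (12 triangles)
make_cube <- function(side = 1) {
  v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  dimnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = side
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = side
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = side
  triangle_mesh(v, f)
}

# flat square patch in the z = z0 plane, n x n quads over [0, side]^2
make_patch <- function(side = 30, n = 20, z0 = 0) {
  xs <- seq(0, side, length.out = n + 1)
  g <- as.matrix(expand.grid(xs, xs))
  v <- cbind(g, z0)
  dimnames(v) <- NULL
  f <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- (i - 1) * (n + 1) + j
      b <- a + 1
      cc <- a + n + 1
      d <- cc + 1
      f[[length(f) + 1L]] <- rbind(c(a, b, cc), c(b, d, cc))
    }
  }
  triangle_mesh(v, do.call(rbind, f))
}

# random proper rigid transform: rotation angle <= max_angle_deg,
# translation <= max_trans
random_transform <- function(max_angle_deg = 180, max_trans = 10) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, max_angle_deg) * pi / 180
  k <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  r <- diag(3) + sin(ang) * k + (1 - cos(ang)) * (k %*% k)
  rigid_transform(r, runif(3, -max_trans, max_trans))
}

# coarse, fast radius surrogate for tests that do not probe tessellation
coarse_radius_params <- function(seed = 1L) {
  radius_params(ring_spacing = 2.5, n_around = 32L, seed = seed)
}

angle_between_deg <- function(a, b) {
  acos(min(1, max(-1, sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

errors_vec <- function(e) {
  c(e$rot_x_deg, e$rot_y_deg, e$rot_z_deg,
    e$trans_x_mm, e$trans_y_mm, e$trans_z_mm)
}
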