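# A centred synthetic body used by several geometry tests.
cyl_body <- function(radius = 60, shape = c(40, 50, 50),
                     spacing = c(4, 4, 4)) {
  g <- grid_spec(shape, spacing, origin = -(shape - 1) / 2 * spacing)
  w <- mrdose:::grid_world_coords(g)
  inside <- w[, 2]^2 + w[, 3]^2 <= radius^2     # cylinder along SI
  mask_grid(array(as.numeric(inside), shape), grid = g)
}

test_that("beam frames follow the stated gantry convention", {
  b0 <- beam_config(c(0, 0, 0), 0)
  fr <- make_beam_frame(b0)
  expect_equal(fr$ez, c(0, -1, 0))      # anterior -> posterior
  fr180 <- make_beam_frame(beam_config(c(0, 0, 0), 180))
  expect_equal(fr180$ez, -fr$ez)
  for (g in c(0, 17, 45, 90, 133, 270, 359)) {
    fr <- make_beam_frame(beam_config(c(0, 0, 0), g))
    orc <- frame_oracle(g)
    expect_equal(fr$ez, orc$ez, tolerance = 1e-12)
    expect_equal(fr$ey, orc$ey, tolerance = 1e-12)
    # orthonormal right-handed triple with x-hat parallel to SI
    expect_equal(sum(fr$ez * fr$ex), 0)
    expect_equal(det(cbind(fr$ex, fr$ey, fr$ez)), 1, tolerance = 1e-12)
  }
  expect_error(beam_config(c(0, 0, 0), 360), "\\[0, 360\\)")
})

test_that("surface entry depth matches the cylinder closed form", {
  body <- cyl_body(radius = 60)
  for (g in c(0, 40, 110, 250)) {
    b <- beam_config(c(0, 0, 0), g, sad_mm = 1000)
    expect_equal(surface_entry_depth(body, b), 1000 - 60, tolerance = 4)
  }
  # body covering the full volume: entry at the volume boundary
  full <- cyl_body(radius = 1e6)
  b <- beam_config(c(0, 0, 0), 0)
  half_extent <- 50 * 4 / 2
  expect_equal(surface_entry_depth(full, b), 1000 - half_extent,
               tolerance = 4)
  # beam fully outside the body
  off <- beam_config(c(0, 0, 500), 0)
  expect_error(surface_entry_depth(body, off), "misses body")
})

test_that("extracting a constant volume gives a constant cuboid", {
  body <- cyl_body()
  v <- const_volume(2.5, shape = c(40, 50, 50), spacing = c(4, 4, 4))
  v$grid <- body$grid
  b <- beam_config(c(0, 0, 0), 30)
  cub <- extract_bev_cuboid(v, b, body = body, shape = c(60, 16, 16))
  # inside the body footprint the cuboid is exactly the constant
  inside <- extract_bev_cuboid(body, b, "nearest", body = body,
                               shape = c(60, 16, 16))
  expect_true(all(abs(cub$values[inside$values == 1] - 2.5) < 1e-9))
})

test_that("cuboid sampling recovers patient coordinates analytically", {
  g <- grid_spec(c(40, 50, 50), c(4, 4, 4), origin = -c(39, 49, 49) * 2)
  w <- mrdose:::grid_world_coords(g)
  body <- cyl_body()
  for (axis in 1:3) {
    v <- volume_grid(array(w[, axis], g$shape), grid = g)
    b <- beam_config(c(0, 0, 0), 55)
    ed <- surface_entry_depth(body, b)
    cub <- extract_bev_cuboid(v, b, body = body, shape = c(40, 8, 8),
                              entry_depth_mm = ed)
    fr <- make_beam_frame(b)
    ax <- mrdose:::bev_axis_coords(cub)
    entry <- fr$source + ed * fr$ez
    # compare at interior samples (central rays, mid depths)
    for (k in c(5, 20, 35)) for (j in 3:6) for (i in 3:6) {
      p <- entry + ax$z[k] * fr$ez + ax$y[j] * fr$ey + ax$x[i] * fr$ex
      expect_equal(cub$values[k, j, i], p[axis], tolerance = 1e-6)
    }
  }
})

test_that("insert after extract reproduces a smooth beam within 2% RMS", {
  g <- grid_spec(c(40, 50, 50), c(4, 4, 4), origin = -c(39, 49, 49) * 2)
  w <- mrdose:::grid_world_coords(g)
  # compactly supported Gaussian blob near the beam path
  f <- exp(-((w[, 1])^2 + (w[, 2] - 10)^2 + (w[, 3])^2) / (2 * 20^2))
  f[f < 1e-3] <- 0
  v <- volume_grid(array(f, g$shape), grid = g, quantity = "DOSE_GY")
  body <- cyl_body()
  b <- beam_config(c(0, 0, 0), 20)
  cub <- extract_bev_cuboid(v, b, body = body, shape = c(80, 32, 32),
                            spacing_mm = 2)
  back <- insert_bev_dose(cub, g)
  # compare inside the cuboid footprint only
  foot <- insert_bev_dose(bev_cuboid(array(1, c(80, 32, 32)), b,
                                     cub$entry_depth_mm), g)
  sel <- foot$values > 0.999 & v$values > 0
  rms <- sqrt(mean((back$values[sel] - v$values[sel])^2)) /
    sqrt(mean(v$values[sel]^2))
  expect_lt(rms, 0.02)
  # zero cuboid inserts to a zero volume
  z <- insert_bev_dose(bev_cuboid(array(0, c(10, 4, 4)), b, 900), g)
  expect_true(all(z$values == 0))
})

test_that("opposed beams insert mirror-symmetric dose", {
  g <- grid_spec(c(21, 41, 41), c(4, 4, 4), origin = -c(20, 40, 40) * 2)
  cubvals <- array(exp(-((1:40) - 10)^2 / 50), c(40, 8, 8))
  b0 <- beam_config(c(0, 0, 0), 0)
  b180 <- beam_config(c(0, 0, 0), 180)
  v0 <- insert_bev_dose(bev_cuboid(cubvals, b0, 920, lateral_shift_mm = 0),
                        g)
  v180 <- insert_bev_dose(bev_cuboid(cubvals, b180, 920,
                                     lateral_shift_mm = 0), g)
  # reflect v180 through the isocenter transverse axes (AP and LR flip)
  flipped <- v180$values[, rev(seq_len(41)), rev(seq_len(41))]
  expect_equal(v0$values, flipped, tolerance = 1e-9)
})

test_that("gantry rotation is equivariant with volume rotation", {
  # rotating the volume by 90 deg about SI and the gantry by 90 deg
  # yields the same cuboid up to interpolation error
  g <- grid_spec(c(30, 45, 45), c(4, 4, 4), origin = -c(29, 44, 44) * 2)
  f <- smooth_random_field(c(30, 45, 45), seed = 20)
  v <- volume_grid(f, grid = g)
  # rotate by +90 deg about SI: (S, A, L) -> (S, -L, A)
  rot <- v$values
  for (k in seq_len(30)) rot[k, , ] <- t(f[k, , ])[rev(seq_len(45)), ]
  vr <- volume_grid(rot, grid = g)
  body <- cyl_body(radius = 80, shape = c(30, 45, 45))
  b1 <- beam_config(c(0, 0, 0), 30)
  b2 <- beam_config(c(0, 0, 0), 120)
  ed <- 1000 - 80
  c1 <- extract_bev_cuboid(v, b1, shape = c(40, 8, 8),
                           entry_depth_mm = ed)
  c2 <- extract_bev_cuboid(vr, b2, shape = c(40, 8, 8),
                           entry_depth_mm = ed)
  sel <- abs(c1$values) > 1e-9 & abs(c2$values) > 1e-9
  expect_lt(max(abs(c1$values[sel] - c2$values[sel])) /
              max(abs(c1$values[sel])), 0.02)
})

test_that("beam-set enumeration reproduces the stated counts and order", {
  beams <- enumerate_beam_set(c(0, 0, 0))
  expect_length(beams, 540)
  expect_length(enumerate_beam_set(c(0, 0, 0), 0, 0, 360), 1)
  # deterministic order: SI outer, AP middle, angle inner
  expect_equal(beams[[1]]$isocenter, c(-40, 0, 0))
  expect_equal(beams[[2]]$gantry_deg, 10)
  expect_equal(beams[[37]]$isocenter, c(-40, 30, 0))
  expect_error(enumerate_beam_set(c(0, 0, 0), 0, 0, 7), "divide 360")
  expect_length(enumerate_beam_set(c(0, 0, 0), c(0, 1), c(0, 1, 2), 30),
                2 * 3 * 12)
})
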