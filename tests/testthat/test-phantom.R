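small_spec <- function() phantom_spec(shape = c(40, 48, 56),
                                      spacing_mm = c(4, 4, 4))

test_that("phantom generation is deterministic per seed", {
  a <- generate_phantom(small_spec(), seed = 5)
  b <- generate_phantom(small_spec(), seed = 5)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$mri$values, b$mri$values)
  expect_identical(a$ac$values, b$ac$values)
  c2 <- generate_phantom(small_spec(), seed = 6)
  expect_false(identical(a$ct$values, c2$ct$values))
})

test_that("phantom tissue classes have the intended CT/MRI signatures", {
  case <- generate_phantom(small_spec(), seed = 7)
  # CT cavities are detected by the HU threshold step
  air <- extract_ct_air_mask(case$ct)
  inside_air <- air$values == 1 & case$body$values == 1
  expect_gt(sum(inside_air), 0)
  # bone confounders: dark on MRI yet dense on CT, never labelled AC
  bone_like <- case$mri$values < 0.3 & case$ct$values > 300 &
    case$body$values == 1
  expect_gt(sum(bone_like), 0)
  expect_equal(sum(bone_like & case$ac$values == 1), 0)
  # MRI cavities are dark
  expect_lt(mean(case$mri$values[case$ac$values == 1]), 0.2)
  # structures are disjoint from bone and inside the body
  expect_true(all(case$ptv$values <= case$body$values))
  expect_true(all(case$ac$values <= case$body$values))
})

test_that("the MRI bias field is smooth at the voxel scale", {
  set.seed(8)
  f <- mrdose:::smooth_field(c(40, 48, 56))
  bias <- 1 + 0.12 * f
  d1 <- abs(bias[-1, , ] - bias[-40, , ]) / bias[-1, , ]
  expect_lt(max(d1), 0.01)
})

test_that("water-phantom depth dose matches the 1D marching oracle", {
  # homogeneous water body, no lateral structure
  g <- grid_spec(c(40, 60, 60), c(4, 4, 4), origin = -c(39, 59, 59) * 2)
  ct <- volume_grid(array(0, g$shape), grid = g, quantity = "HU")
  body <- mask_grid(array(1, g$shape), grid = g)
  p <- oracle_params(drift_per_mm = 0)   # drift off: separable profile
  b <- beam_config(c(0, 0, 0), 0)
  ed <- surface_entry_depth(body, b)
  cub <- oracle_beam_cuboid(ct, b, p, shape = c(50, 16, 16),
                            entry_depth_mm = ed)
  # independent 1D march on the same density ray (j = 4 is y = +1 mm
  # with the 10 mm window shift; the ray is water after the
  # partial-volume surface sample)
  rho_vol <- volume_grid(array(1, g$shape), grid = g,
                         quantity = "DOSE_GY")
  rho_ray <- pmax(extract_bev_cuboid(rho_vol, b, shape = c(50, 16, 16),
                                     entry_depth_mm = ed)$values[, 4, 8],
                  p$density_floor)
  want <- march_ray_oracle(rho_ray, 2, p$mu_eff, p$buildup_mm)
  got <- cub$values[, 4, 8]
  ratio <- got[2:50] / want[2:50]   # constant lateral factor only
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
  expect_equal(which.max(got), which.max(want))
})

test_that("a cavity causes a dose dip and distal rebuild-up", {
  g <- grid_spec(c(40, 60, 60), c(4, 4, 4), origin = -c(39, 59, 59) * 2)
  hu <- array(0, g$shape)
  body <- mask_grid(array(1, g$shape), grid = g)
  # air slab 40 mm thick perpendicular to a gantry-0 beam
  w <- mrdose:::grid_world_coords(g)
  slab <- w[, 2] < 40 & w[, 2] > 0
  hu[slab] <- -1000
  ct_cav <- volume_grid(hu, grid = g, quantity = "HU")
  ct_hom <- volume_grid(array(0, g$shape), grid = g, quantity = "HU")
  p <- oracle_params(drift_per_mm = 0)
  b <- beam_config(c(0, -20, 0), 0)
  cav <- oracle_beam_cuboid(ct_cav, b, p, body = body,
                            shape = c(80, 16, 16),
                            entry_depth_mm = 880)
  hom <- oracle_beam_cuboid(ct_hom, b, p, body = body,
                            shape = c(80, 16, 16),
                            entry_depth_mm = 880)
  centre_cav <- cav$values[, 4, 8]
  centre_hom <- hom$values[, 4, 8]
  # entry plane at A = 100 mm; the slab at A in (0, 40) spans depths
  # 60-100 mm, i.e. k about 32..50
  inside <- 35:48
  expect_true(all(centre_cav[inside] < centre_hom[inside]))
  # rebuild-up beyond the cavity exit (deepest dip near k = 51)
  expect_gt(max(centre_cav[52:60]) / min(centre_cav[45:51]), 1.2)
})

test_that("oracle dose is bitwise reproducible without noise", {
  case <- generate_phantom(small_spec(), seed = 9)
  b <- beam_config(mrdose:::ptv_center(case), 70)
  p <- oracle_params()
  d1 <- oracle_beam_cuboid(case$ct, b, p, body = case$body,
                           shape = c(60, 16, 16))
  d2 <- oracle_beam_cuboid(case$ct, b, p, body = case$body,
                           shape = c(60, 16, 16))
  expect_identical(d1$values, d2$values)
  expect_equal(d1$lateral_shift_mm, 10)
  # the cuboid argmax sits on the drift side of the window (y >= 0)
  ax <- mrdose:::bev_axis_coords(d1)
  am <- arrayInd(which.max(d1$values), dim(d1$values))
  expect_gte(ax$y[am[2]], 0)
})

test_that("training labels are noisier than test labels", {
  case <- generate_phantom(small_spec(), seed = 10)
  b <- beam_config(mrdose:::ptv_center(case), 0)
  p <- oracle_params()
  clean <- oracle_beam_cuboid(case$ct, b, p, body = case$body,
                              shape = c(60, 16, 16))
  noisy <- function(sig, seed) {
    set.seed(seed)
    oracle_beam_cuboid(case$ct, b, p, body = case$body,
                       shape = c(60, 16, 16), noise_sigma = sig)
  }
  tr <- noisy(p$label_noise_sigma_train, 1)
  te <- noisy(p$label_noise_sigma_test, 1)
  hi <- clean$values >= 0.1 * max(clean$values)
  rel_tr <- sd((tr$values[hi] - clean$values[hi]) / clean$values[hi])
  rel_te <- sd((te$values[hi] - clean$values[hi]) / clean$values[hi])
  expect_gt(rel_tr, 2 * rel_te)
  expect_lt(rel_te, 0.05)
})

test_that("dataset assembly follows the split and beam-count contract", {
  ds <- build_beam_dataset(n_train = 1, n_val = 1, n_test = 1,
                           beams_per_patient = 4, spec = small_spec(),
                           shape = c(40, 8, 8), seed = 3)
  expect_length(ds$train, 4)
  expect_length(ds$val, 4)
  expect_length(ds$test, 4)
  pids <- lapply(c("train", "val", "test"), function(sp)
    unique(vapply(ds[[sp]], `[[`, 0, "patient")))
  expect_length(Reduce(intersect, pids), 0)
  # dose normalization: training maximum is exactly 1
  expect_equal(max(vapply(ds$train, function(s) max(s$dose), 0)), 1)
  s <- ds$train[[1]]
  expect_identical(dim(s$mri), c(40L, 8L, 8L))
  expect_true(all(s$ac %in% c(0, 1)))
})

test_that("on-disk dataset generation writes a complete manifest", {
  dir <- tempfile("synthds")
  on.exit(unlink(dir, recursive = TRUE))
  mp <- generate_dataset(dir, n_train = 1, n_val = 0, n_test = 0,
                         beams_per_patient = 2, spec = small_spec(),
                         shape = c(40, 8, 8), seed = 2)
  m <- yaml::read_yaml(mp)
  expect_length(m$patients, 1)
  p1 <- m$patients[[1]]
  for (f in c("mri", "ct", "body", "ptv", "ac"))
    expect_true(file.exists(file.path(dir, p1[[f]])))
  expect_length(p1$beams, 2)
  d <- read_volume(file.path(dir, p1$beams[[1]]$dose),
                   quantity = "DOSE_GY")
  expect_identical(d$grid$shape, c(40L, 8L, 8L))
})
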