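make_ct <- function(values, spacing = c(1, 1, 1)) {
  volume_grid(values, spacing = spacing, quantity = "HU")
}

test_that("air extraction uses a strict -300 HU cut", {
  v <- array(0, c(3, 3, 3))
  v[1, 1, 1] <- -500
  v[2, 1, 1] <- -300   # exactly at threshold: not air
  v[3, 1, 1] <- -299.9
  ct <- make_ct(v)
  m <- extract_ct_air_mask(ct)
  expect_equal(m$values[1, 1, 1], 1)
  expect_equal(m$values[2, 1, 1], 0)
  expect_equal(m$values[3, 1, 1], 0)
  expect_error(extract_ct_air_mask(const_volume(0)), "quantity mismatch")
})

test_that("all-water CT gives an empty air mask; toy counts are exact", {
  expect_equal(sum(extract_ct_air_mask(make_ct(array(0, c(4, 4, 4))))$values),
               0)
  v <- array(100, c(5, 5, 5))
  v[c(1, 30, 77)] <- -400
  expect_equal(sum(extract_ct_air_mask(make_ct(v))$values), 3)
})

test_that("18-connectivity joins edges but not corners", {
  m <- array(0, c(3, 3, 3))
  m[1, 1, 1] <- 1
  m[2, 2, 2] <- 1   # full-diagonal corner neighbour
  corner <- label_components_18(mask_grid(m, spacing = c(1, 1, 1)))
  expect_equal(corner$n_components, 2)
  m2 <- array(0, c(3, 3, 3))
  m2[1, 1, 1] <- 1
  m2[2, 2, 1] <- 1  # edge-sharing neighbour
  edge <- label_components_18(mask_grid(m2, spacing = c(1, 1, 1)))
  expect_equal(edge$n_components, 1)
})

test_that("component labelling matches the flood-fill oracle on random masks", {
  set.seed(11)
  for (rep in 1:40) {
    m <- array(rbinom(16^3, 1, runif(1, 0.05, 0.35)), c(16, 16, 16))
    got <- label_components_18(mask_grid(m, spacing = c(1, 1, 1)))
    want <- floodfill_labels(m, 18)
    expect_identical(partition_signature(got$labels$values),
                     partition_signature(want))
    # label order is deterministic: component k's first voxel precedes
    # component k+1's in linear order
    firsts <- vapply(seq_len(got$n_components), function(k)
      min(which(got$labels$values == k)), 0)
    expect_true(all(diff(firsts) > 0))
    # volumes sum exactly to the mask volume
    expect_equal(sum(got$volumes_cc),
                 sum(m) * prod(c(1, 1, 1)) / 1000)
  }
})

test_that("cavity filling uses the neighbour-shell median per component", {
  v <- array(1000, c(3, 3, 3))
  m <- array(0, c(3, 3, 3))
  m[2, 2, 2] <- 1
  # neighbour shell = 26 neighbours; give them known values
  shell_vals <- c(10, 20, 30, 40, 50)
  v[] <- rep(shell_vals, length.out = 27)
  v[2, 2, 2] <- -800
  ct <- make_ct(v)
  filled <- fill_air_components(ct, mask_grid(m, spacing = c(1, 1, 1)))
  expect_equal(filled$values[2, 2, 2], median(v[-14]))
  expect_equal(filled$values[-14], v[-14])  # outside mask unchanged
})

test_that("filling is component-independent and the empty mask is identity", {
  v <- array(0, c(9, 3, 3))
  v[6:9, , ] <- 1000
  v[2, 2, 2] <- -900   # cavity in the 0-HU medium
  v[8, 2, 2] <- -900   # cavity in the 1000-HU medium
  m <- array(0, dim(v))
  m[2, 2, 2] <- 1
  m[8, 2, 2] <- 1
  ct <- make_ct(v)
  filled <- fill_air_components(ct, mask_grid(m, spacing = c(1, 1, 1)))
  expect_equal(filled$values[2, 2, 2], 0)
  expect_equal(filled$values[8, 2, 2], 1000)
  empty <- mask_grid(array(0, dim(v)), spacing = c(1, 1, 1))
  expect_identical(fill_air_components(ct, empty)$values, ct$values)
})

test_that("a mask filling the whole volume has no neighbour shell", {
  ct <- make_ct(array(-500, c(3, 3, 3)))
  m <- mask_grid(array(1, c(3, 3, 3)), spacing = c(1, 1, 1))
  expect_error(fill_air_components(ct, m), "shell")
})

test_that("MRI cavity insertion stamps exactly -700 HU and wins overlaps", {
  set.seed(12)
  v <- array(rnorm(64, 30, 10), c(4, 4, 4))
  v[1, 1, 1] <- -500                     # CT air overlapping the MRI AC
  ct <- make_ct(v)
  ac <- array(0, c(4, 4, 4))
  ac[1:2, 1, 1] <- 1
  acm <- mask_grid(ac, spacing = c(1, 1, 1))
  out <- correct_ct_air(ct, acm)
  expect_identical(out$values[1:2, 1, 1], c(-700, -700))
  empty <- mask_grid(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
  filled <- fill_air_components(ct, extract_ct_air_mask(ct))
  expect_identical(insert_mri_air(filled, empty)$values, filled$values)
  g2 <- mask_grid(array(0, c(3, 3, 3)), spacing = c(2, 2, 2))
  expect_error(insert_mri_air(filled, g2), "grid mismatch")
})

test_that("volume filtering keeps components at or above the threshold", {
  # voxel volume 1 mm^3: a 2000-voxel and a 500-voxel component
  m <- array(0, c(30, 30, 30))
  m[1:20, 1:10, 1:10] <- 1          # 2.0 cm^3
  m[25:29, 1:10, 1:10] <- 1         # 0.5 cm^3
  comp <- label_components_18(mask_grid(m, spacing = c(1, 1, 1)))
  kept <- filter_components_by_volume(comp, 1.0)
  expect_equal(sum(kept$values), 2000)
  all_kept <- filter_components_by_volume(comp, 0)
  expect_identical(all_kept$values, m)
  # exactly 1.00 cm^3 is retained (inclusive threshold)
  m2 <- array(0, c(12, 12, 12))
  m2[1:10, 1:10, 1:10] <- 1
  comp2 <- label_components_18(mask_grid(m2, spacing = c(1, 1, 1)))
  expect_equal(sum(filter_components_by_volume(comp2, 1.0)$values), 1000)
})

test_that("dice coefficient handles identity, disjoint and empty masks", {
  mk <- function(idx, shape = c(4, 4, 4)) {
    v <- array(0, shape)
    v[idx] <- 1
    mask_grid(v, spacing = c(1, 1, 1))
  }
  a <- mk(1:4)
  expect_equal(dice_coefficient(a, a), 1.0)
  expect_equal(dice_coefficient(mk(1:4), mk(5:8)), 0.0)
  expect_equal(dice_coefficient(mk(1:4), mk(3:6)), 0.5)
  expect_equal(dice_coefficient(mk(integer(0)), mk(integer(0))), 1.0)
  b <- mask_grid(array(0, c(4, 4, 4)), spacing = c(2, 2, 2))
  expect_error(dice_coefficient(a, b), "grid mismatch")
})

test_that("cavity volume stats report both filtering levels", {
  m <- array(0, c(30, 30, 30))
  m[1:20, 1:10, 1:10] <- 1
  m[25:29, 1:10, 1:10] <- 1
  st <- ac_volume_stats(mask_grid(m, spacing = c(1, 1, 1)), 1.0)
  expect_equal(st$n, c(2L, 1L))
  expect_equal(st$mean_cc, c(1.25, 2.0))
  expect_equal(st$min_cc[1], 0.5)
})
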