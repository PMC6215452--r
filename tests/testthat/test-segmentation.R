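test_that("Bernsen thresholding follows the per-voxel rule", {
  # constant image: zero contrast everywhere -> all background
  const <- voxel_volume(array(50, c(12, 12, 12)), 0.1)
  expect_false(any(bernsen_threshold(const, 3, 10)$grid))
  # step edge 0|100: bright side bone, dark side background near the edge
  g <- array(0, c(12, 12, 24)); g[, , 13:24] <- 100
  vol <- voxel_volume(g, 0.1)
  seg <- bernsen_threshold(vol, 3, 50)
  expect_true(all(seg$grid[, , 13:15]))     # bright side within one window
  expect_false(any(seg$grid[, , 9:12]))     # dark side within one window
  # direct per-voxel oracle over the whole image
  oracle <- array(FALSE, dim(g))
  d <- dim(g)
  for (k in seq_len(d[3])) {
    win <- g[, , max(1, k - 3):min(d[3], k + 3)]
    # contrast along the step axis only varies with k; use global win stats
    lo <- min(win); hi <- max(win)
    oracle[, , k] <- (hi - lo >= 50) & (g[, , k] > (hi + lo) / 2)
  }
  # the ball window sees the same min/max as the slab window here
  expect_identical(seg$grid, oracle)
  # shift invariance
  seg2 <- bernsen_threshold(voxel_volume(g + 123, 0.1), 3, 50)
  expect_identical(seg$grid, seg2$grid)
})

test_that("remove_floating keeps exactly the largest component", {
  g <- array(FALSE, c(20, 20, 20))
  g[5:14, 5:14, 5:14] <- TRUE                       # 1000-voxel block
  singles <- rbind(c(1, 1, 1), c(18, 2, 2), c(2, 18, 2), c(2, 2, 18),
                   c(18, 18, 18), c(1, 10, 18), c(18, 10, 1),
                   c(10, 1, 18), c(10, 18, 1), c(1, 18, 10))
  for (s in seq_len(nrow(singles))) g[t(singles[s, , drop = FALSE])] <- TRUE
  bv <- binary_volume(g, 0.1)
  out <- remove_floating(bv)
  expect_equal(sum(out$grid), 1000)
  expect_true(all(out$grid[5:14, 5:14, 5:14]))
  # removal-only contract and idempotence
  expect_true(all(!out$grid | bv$grid))
  expect_identical(remove_floating(out)$grid, out$grid)
  # single component: identity
  one <- binary_volume(array(TRUE, c(4, 4, 4)), 0.1)
  expect_identical(remove_floating(one)$grid, one$grid)
  expect_error(remove_floating(binary_volume(array(FALSE, c(4, 4, 4)))),
               "empty")
})

test_that("isotropic resampling follows the axial factor 3f", {
  spec <- resample_spec(pixel_resolution_mm = 0.5, slice_thickness_mm = 1.0)
  expect_equal(spec$f, 2)
  g <- array(rnorm(10 * 8 * 8), c(10, 8, 8))
  vol <- voxel_volume(g, c(1.0, 0.5, 0.5))          # (slice, row, col)
  out <- resample_isotropic(vol, spec)
  expect_equal(out$spacing_mm, rep(0.5 / 3, 3), tolerance = 1e-12)
  # axial factor 3f = 6, in-plane factor 3
  expect_equal(dim(out$grid), c((10 - 1) * 6 + 1, (8 - 1) * 3 + 1,
                                (8 - 1) * 3 + 1))
  # cube voxels preserved when f = 1
  spec1 <- resample_spec(0.5, 0.5)
  out1 <- resample_isotropic(voxel_volume(g, 0.5), spec1)
  expect_equal(dim(out1$grid), (dim(g) - 1) * 3 + 1)
  # constants reproduce exactly
  cv <- voxel_volume(array(7, c(6, 6, 6)), c(1, 0.5, 0.5))
  expect_equal(range(resample_isotropic(cv, spec)$grid), c(7, 7),
               tolerance = 1e-12)
  # binary masks stay binary (nearest neighbour)
  bm <- binary_volume(array(rep(c(TRUE, FALSE), 108), c(6, 6, 6)),
                      c(1, 0.5, 0.5))
  rb <- resample_isotropic(bm, spec)
  expect_s3_class(rb, "binary_volume")
})

test_that("background subtraction cancels constants and smooth ramps", {
  const <- voxel_volume(array(42, c(24, 24, 24)), 0.1)
  out <- background_subtract(const, 2, 8)
  expect_equal(range(out$grid), c(0, 0))
  # linear ramp + binary structure: ramp suppressed
  d <- c(32, 32, 32)
  ramp <- outer(outer(seq(0, 30, length.out = d[1]), rep(0, d[2]), "+"),
                rep(0, d[3]), "+")
  g <- array(FALSE, d); g[, 14:18, 14:18] <- TRUE   # a single beam
  vol <- voxel_volume(100 * g + ramp, 0.1)
  out <- background_subtract(vol, 2, 10)
  inner <- out$grid[8:24, , ]
  beam <- g[8:24, , ]
  expect_gt(mean(inner[beam]), 50)
  expect_lt(mean(inner[!beam]), 5)
  # 1-voxel impulses removed by the small median
  set.seed(3)
  imp <- array(0, d)
  imp[sample(length(imp), 200)] <- 500
  outi <- background_subtract(voxel_volume(imp, 0.1), 2, 10)
  expect_equal(max(outi$grid), 0)
  expect_error(background_subtract(const, 8, 2), "small_radius")
})

test_that("protocol 1 recovers a clean high-contrast phantom (Dice >= 0.95)", {
  cl <- scaffold()
  clean <- corrupt_ct(cl$volume, bone_value = 100, gradient_amplitude = 0,
                      impulse_frac = 0, seed = 1)
  seg <- run_protocol(clean, protocol_spec(1, window_radius_px = 5,
                                           contrast_threshold = 30))
  expect_gte(dice(seg, cl$volume), 0.95)
})

test_that("protocol 4 output is invariant to adding a constant", {
  cl <- make_connected_lattice(c(48, 48, 48), 0.05)
  grey <- corrupt_ct(cl$volume, seed = 3)
  s1 <- run_protocol(grey, p4_spec())
  grey2 <- voxel_volume(grey$grid + 500, grey$spacing_mm)
  s2 <- run_protocol(grey2, p4_spec())
  expect_identical(s1$grid, s2$grid)
})

test_that("protocol 4 on a structure-free noise volume segments ~nothing", {
  empty <- binary_volume(array(FALSE, c(48, 48, 48)), 0.05)
  noise <- corrupt_ct(empty, seed = 9)
  seg <- run_protocol(noise, p4_spec())
  expect_lte(bone_fraction(seg), 0.01)
})

test_that("protocol ids outside 1-4 are rejected", {
  expect_error(protocol_spec(5), "protocol")
  expect_error(protocol_spec(0), "protocol")
})

test_that("filters are translation-equivariant away from boundaries", {
  set.seed(21)
  g <- array(runif(18^3), c(18, 18, 18))
  med <- cancellous:::cpp_median_filter(g, 2L, 0L)
  gs <- g
  gs[2:18, , ] <- g[1:17, , ]               # shift along axis 1
  meds <- cancellous:::cpp_median_filter(gs, 2L, 0L)
  expect_equal(meds[6:14, 4:15, 4:15], med[5:13, 4:15, 4:15],
               tolerance = 1e-12)
})
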