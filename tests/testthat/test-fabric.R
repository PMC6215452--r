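test_that("direction sets are uniform, antipodally unique and seeded", {
  d <- sample_directions(2049, seed = 1)
  expect_equal(nrow(d), 2049)
  expect_equal(rowSums(unclass(d)^2), rep(1, 2049), tolerance = 1e-12)
  # no antipodal duplicates: all pairwise |dot| < 1
  m <- unclass(d)
  gram <- abs(m %*% t(m))
  diag(gram) <- 0
  expect_lt(max(gram), 1 - 1e-9)
  # second-moment uniformity: mean outer product ~ I/3
  M <- crossprod(m) / nrow(m)
  expect_lt(norm(M - diag(3) / 3, "F"), 0.01)
  # determinism / seed sensitivity
  expect_identical(unclass(sample_directions(2049, seed = 1)), m)
  expect_false(identical(unclass(sample_directions(2049, seed = 2)), m))
  expect_error(sample_directions(10), ">= 50")
})

test_that("star sampling matches plate geometry and is direction-symmetric", {
  ph <- make_plate_stack(c(96, 96, 96), 0.05, normal = c(0, 0, 1),
                         plate_thickness_mm = 0.3, gap_mm = 0.9)
  voi <- sphere_voi(c(2.4, 2.4, 2.4), 2)
  dirs <- sample_directions(256, seed = 2)
  m <- star_sample(ph$volume, voi, dirs, n_points = 1500, seed = 4)
  # along the plate normal the intercept is the plate thickness
  along <- which(abs(unclass(dirs)[, 3]) > 0.995)
  if (length(along) > 0)
    expect_equal(mean(m$mean_l[along]), 0.3, tolerance = 0.05 / 0.3)
  # negating all directions leaves the measure unchanged (bidirectional rays)
  neg <- structure(-unclass(dirs), class = class(dirs))
  m2 <- star_sample(ph$volume, voi, neg, n_points = 1500, seed = 4)
  expect_equal(m$mean_l, m2$mean_l, tolerance = 1e-12)
  # errors on empty / sparse VOIs
  empty <- binary_volume(array(FALSE, c(24, 24, 24)), 0.05)
  expect_error(star_sample(empty, sphere_voi(c(0.6, 0.6, 0.6), 0.5), dirs),
               "no bone")
})

test_that("star lengths in a fully solid VOI are direction-independent", {
  solid <- binary_volume(array(TRUE, c(48, 48, 48)), 0.1)
  voi <- sphere_voi(c(2.35, 2.35, 2.35), 2)
  dirs <- sample_directions(128, seed = 3)
  m <- star_sample(solid, voi, dirs, n_points = 2000, seed = 5)
  expect_true(all(m$censored_frac == 1))
  # all-direction means agree within Monte-Carlo tolerance
  expect_lt((max(m$mean_l) - min(m$mean_l)) / mean(m$mean_l), 0.1)
  # chord-geometry oracle: mean chord through uniform interior points of a
  # sphere of radius R, for any direction, is 3R/2
  expect_equal(mean(m$mean_l), 3 * 2 / 2, tolerance = 0.05)
})

test_that("MIL matches an intersection-count oracle on plates", {
  ph <- make_plate_stack(c(96, 96, 96), 0.05, normal = c(0, 0, 1),
                         plate_thickness_mm = 0.3, gap_mm = 0.9)
  voi <- sphere_voi(c(2.4, 2.4, 2.4), 2)
  dirs <- structure(rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)),
                    class = c("direction_set", "matrix"))
  m <- mil_measure(ph$volume, voi, dirs)
  # oracle: lines along the normal cross 2 interfaces per period, so
  # MIL = total length / crossings = period / 2
  expect_equal(m$value[1], (0.3 + 0.9) / 2, tolerance = 0.15)
  # exactly in-plane lines never cross an interface when they start inside
  # a plate or a gap: censored to the VOI diameter
  expect_true(all(m$censored[2:3]))
  expect_true(all(m$value[2:3] == 4))
})

test_that("MIL on the isotropic phantom is nearly direction-independent", {
  # VOI spans ~18 grain radii so directional sampling noise is small
  iso <- make_isotropic_boolean(c(96, 96, 96), 0.05, grain_radius_mm = 0.25,
                                target_bvtv = 0.3, seed = 6)
  voi <- sphere_voi(c(2.35, 2.35, 2.35), 2.2)
  dirs <- sample_directions(256, seed = 4)
  m <- mil_measure(iso$volume, voi, dirs, grid_spacing_mm = 0.1)
  expect_lt(max(m$value) / min(m$value), 1.2)
})

test_that("fabric fit inverts a known quadric exactly", {
  dirs <- sample_directions(512, seed = 7)
  n <- unclass(dirs)
  M <- diag(c(4, 2.25, 1))
  v <- 1 / sqrt(rowSums((n %*% M) * n))
  meas <- structure(data.frame(value = v),
                    class = c("directional_measure", "data.frame"),
                    dirs = dirs, method = "svd")
  f <- fit_fabric_tensor(meas)
  # H = M^(-1/2) -> eigenvalues prop. (1, 2/3, 1/2): e1/e3 = 2
  expect_equal(f$DA, 2, tolerance = 1e-9)
  expect_equal(f$evals / f$evals[1], c(1, 2 / 3, 1 / 2), tolerance = 1e-9)
  # primary axis is z (largest directional value), tertiary is x
  expect_lt(angle_deg(f$evecs[1, ], c(0, 0, 1)), 1e-5)
  expect_lt(angle_deg(f$evecs[3, ], c(1, 0, 0)), 1e-5)
  # tensor reconstructs from its eigenpairs and has trace 3
  expect_equal(sum(diag(f$tensor)), 3, tolerance = 1e-12)
  R <- t(f$evecs)
  expect_equal(R %*% diag(f$evals) %*% t(R), f$tensor, tolerance = 1e-10)
})

test_that("constant directional values give the isotropic tensor", {
  dirs <- sample_directions(256, seed = 8)
  meas <- structure(data.frame(value = rep(1.7, 256)),
                    class = c("directional_measure", "data.frame"),
                    dirs = dirs, method = "svd")
  f <- fit_fabric_tensor(meas)
  expect_equal(f$DA, 1, tolerance = 1e-9)
  expect_equal(f$evals, c(1, 1, 1), tolerance = 1e-9)
  expect_equal(f$tensor, diag(3), tolerance = 1e-9)
})

test_that("DA >= 1 and eigenvector signs are stable across reruns", {
  ph <- small_rods()
  voi <- sphere_voi(c(1.6, 1.6, 1.6), 1.4)
  f1 <- fabric_voi(ph$volume, voi, "svd", n_directions = 512,
                   n_points = 1500, seed = 5)
  f2 <- fabric_voi(ph$volume, voi, "svd", n_directions = 512,
                   n_points = 1500, seed = 5)
  expect_gte(f1$DA, 1)
  expect_identical(f1$evecs, f2$evecs)
  expect_identical(f1$evals, f2$evals)
})

test_that("rod lattice fabric recovers the rod axis with DA > 1.5", {
  ax <- c(0.4, -0.2, 1); ax <- ax / sqrt(sum(ax^2))
  ph <- make_rod_lattice(c(96, 96, 96), 0.05, axis = ax, rod_radius_mm = 0.2,
                         pitch_mm = 1, jitter_frac = 0.3, seed = 13)
  voi <- sphere_voi(c(2.4, 2.4, 2.4), 2.1)
  for (method in c("svd", "mil")) {
    f <- fabric_voi(ph$volume, voi, method, n_directions = 1024,
                    n_points = 2500, seed = 6)
    expect_lt(angle_deg(f$evecs[1, ], ax), 5)
    expect_gt(f$DA, 1.5)
  }
})

test_that("SVD and MIL primary directions agree on anisotropic phantoms", {
  ph <- small_rods()
  voi <- sphere_voi(c(1.6, 1.6, 1.6), 1.4)
  fs <- fabric_voi(ph$volume, voi, "svd", n_directions = 1024,
                   n_points = 2500, seed = 7)
  fm <- fabric_voi(ph$volume, voi, "mil", n_directions = 1024, seed = 7)
  expect_lt(angle_deg(fs$evecs[1, ], fm$evecs[1, ]), 10)
})

test_that("DA is invariant under uniform spatial rescaling", {
  ph <- small_rods()
  voi <- sphere_voi(c(1.6, 1.6, 1.6), 1.4)
  f1 <- fabric_voi(ph$volume, voi, "svd", n_directions = 512,
                   n_points = 2000, seed = 8)
  scaled <- binary_volume(ph$volume$grid, ph$volume$spacing_mm * 2)
  f2 <- fabric_voi(scaled, sphere_voi(c(3.2, 3.2, 3.2), 2.8), "svd",
                   n_directions = 512, n_points = 2000, seed = 8)
  expect_equal(f2$DA, f1$DA, tolerance = 0.05)
})

test_that("batch fabric accounts for every VOI and captures failures", {
  ph <- small_rods()
  mask <- binary_volume(array(TRUE, dim(ph$volume$grid)),
                        ph$volume$spacing_mm)
  vois <- ccp_pack(mask, 0.8)
  # add a VOI centred in pure background to force one failure
  empty_vol <- binary_volume(array(FALSE, c(64, 64, 64)), 0.05)
  tab <- batch_fabric(ph$volume, vois, "svd", n_directions = 256,
                      n_points = 800, seed = 9)
  expect_equal(nrow(tab), nrow(vois))
  expect_true(all(tab$ok))
  tab2 <- batch_fabric(empty_vol, vois, "svd", n_directions = 256,
                       n_points = 800, seed = 9)
  expect_equal(nrow(tab2), nrow(vois))
  expect_false(any(tab2$ok))
  expect_match(tab2$error[1], "bone")
  # determinism
  tab3 <- batch_fabric(ph$volume, vois, "svd", n_directions = 256,
                       n_points = 800, seed = 9)
  expect_identical(tab, tab3)
  # dispersion of u1 across VOIs of a uniform-fabric phantom
  u1 <- as.matrix(tab[, c("u1x", "u1y", "u1z")])
  angs <- apply(u1, 1, angle_deg, b = c(0, 0, 1))
  expect_lt(max(angs), 10)
})
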