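test_that("rod lattice hits the analytic bone fraction and is deterministic", {
  ph <- make_rod_lattice(c(64, 64, 64), 0.05, axis = c(0, 0, 1),
                         rod_radius_mm = 0.2, pitch_mm = 1.0,
                         jitter_frac = 0, seed = 3)
  # solid rods: fraction = pi r^2 / pitch^2, counted over an interior window
  # spanning whole lattice periods (boundary rods are partially clipped)
  win <- 11:50                              # world 0.5 mm .. 2.45 mm: 2 pitches
  expect_equal(mean(ph$volume$grid[, win, win]), pi * 0.2^2 / 1.0^2,
               tolerance = 0.01 / (pi * 0.04))
  expect_equal(ph$truth$fabric_axes[1, ], c(0, 0, 1))
  ph2 <- make_rod_lattice(c(64, 64, 64), 0.05, axis = c(0, 0, 1),
                          rod_radius_mm = 0.2, pitch_mm = 1.0,
                          jitter_frac = 0, seed = 3)
  expect_identical(ph$volume$grid, ph2$volume$grid)
  # jittered generator is deterministic too
  j1 <- make_rod_lattice(c(32, 32, 32), 0.05, rod_radius_mm = 0.2,
                         pitch_mm = 1, jitter_frac = 0.5, seed = 9)
  j2 <- make_rod_lattice(c(32, 32, 32), 0.05, rod_radius_mm = 0.2,
                         pitch_mm = 1, jitter_frac = 0.5, seed = 9)
  expect_identical(j1$volume$grid, j2$volume$grid)
  expect_error(make_rod_lattice(c(16, 16, 16), 0.05, rod_radius_mm = 0.6,
                                pitch_mm = 1, seed = 1),
               "pitch")
})

test_that("plate stack has the analytic slab fraction and gap spacing", {
  # 80 voxels at 0.05 mm span exactly four 1 mm periods
  ph <- make_plate_stack(c(80, 64, 64), 0.05, normal = c(0, 0, 1),
                         plate_thickness_mm = 0.2, gap_mm = 0.8)
  expect_equal(bone_fraction(ph$volume), 0.2, tolerance = 0.02 / 0.2)
  expect_equal(ph$truth$fabric_axes[3, ], c(0, 0, 1))
  expect_equal(ph$truth$tb_sp_mm, 0.8)
  # spacing estimate equals the gap within one voxel (interior region:
  # gaps at the open volume boundary would admit oversized spheres)
  reg <- sphere_voi(c(1.6, 1.6, 2), 1.5)
  expect_equal(trabecular_spacing(ph$volume, reg), 0.8,
               tolerance = 0.05 / 0.8)
  expect_error(make_plate_stack(c(16, 16, 16), 0.05, normal = c(0, 0, 0),
                                plate_thickness_mm = 0.2, gap_mm = 0.8),
               "zero length")
})

test_that("isotropic Boolean phantom reaches the target bone fraction", {
  ph <- make_isotropic_boolean(c(64, 64, 64), 0.05, grain_radius_mm = 0.25,
                               target_bvtv = 0.3, seed = 4)
  expect_gte(bone_fraction(ph$volume), 0.28)
  expect_lte(bone_fraction(ph$volume), 0.32)
  expect_true(all(diff(ph$truth$fabric_eigenvalues) <= 0))
  # a grain larger than the volume overshoots any moderate target
  expect_error(make_isotropic_boolean(c(16, 16, 16), 1, grain_radius_mm = 40,
                                      target_bvtv = 0.5, seed = 1),
               "grain")
})

test_that("corrupt_ct is the identity when all corruption is off", {
  ph <- small_rods()
  g <- corrupt_ct(ph$volume, bone_value = 100, gradient_amplitude = 0,
                  impulse_frac = 0, blur_sigma_vox = 0, seed = 1)
  expect_identical(g$grid, 100 * ph$volume$grid)
})

test_that("corrupt_ct impulse fraction matches a counting oracle", {
  ph <- small_rods()
  base <- 100 * ph$volume$grid
  g <- corrupt_ct(ph$volume, bone_value = 100, gradient_amplitude = 0,
                  impulse_frac = 0.05, seed = 2)
  n_imp <- round(0.05 * length(base))
  # salt voxels (value 250) can arise only from impulses: exactly half of them
  expect_equal(sum(g$grid == 250), floor(n_imp / 2))
  # pepper hits on bone voxels: zeros where the truth was bone
  pepper_on_bone <- sum(g$grid == 0 & base == 100)
  expect_equal(pepper_on_bone / (n_imp / 2), bone_fraction(ph$volume),
               tolerance = 0.1)
  # deterministic under seed
  g2 <- corrupt_ct(ph$volume, bone_value = 100, gradient_amplitude = 0,
                   impulse_frac = 0.05, seed = 2)
  expect_identical(g$grid, g2$grid)
})

test_that("connected scaffold is a single 26-connected component", {
  cl <- scaffold()
  kept <- remove_floating(cl$volume)
  expect_identical(kept$grid, cl$volume$grid)
})

test_that("bone phantom records usable geometric ground truth", {
  ph <- make_bone_phantom()
  expect_equal(ph$truth$long_axis, c(0, 0, 1))
  # principal axis within 2 degrees of +z by construction symmetry
  pa <- principal_axis(ph$volume, proximal_hint_mm = c(0, 0, 1000))
  expect_lt(angle_deg(pa, c(0, 0, 1)), 2)
  # condyle sphere fits recover the known centres within half a voxel
  for (w in c("medial", "lateral")) {
    fs <- fit_sphere(condyle_surface_points(ph, w))
    err <- sqrt(sum((fs$center - ph$truth$condyle_centers_mm[w, ])^2))
    expect_lt(err, 0.5 * ph$volume$spacing_mm[1])
  }
  # frame built from the truth values is exactly orthonormal right-handed
  fr <- build_frame(ph$truth$long_axis,
                    ph$truth$condyle_centers_mm["medial", ],
                    ph$truth$condyle_centers_mm["lateral", ], "right")
  B <- rbind(fr$x_axis, fr$y_axis, fr$z_axis)
  expect_equal(B %*% t(B), diag(3), tolerance = 1e-12)
  expect_equal(pracma_cross_test(fr$x_axis, fr$y_axis), fr$z_axis,
               tolerance = 1e-12)
  expect_error(make_bone_phantom(condyle_sep_mm = 40), "disjoint")
})

test_that("score table generator respects its variance components", {
  # no noise: identical columns, ICC(2,k) = 1, no missing cells
  t0 <- make_score_table(12, bone_sd = 1.5, scorer_sd = 0, residual_sd = 0,
                         na_frac = 0, seed = 5)
  expect_false(anyNA(t0))
  expect_equal(icc2k(t0)$icc, 1)
  # pure noise at large n: ICC near 0
  t1 <- make_score_table(200, bone_sd = 0, scorer_sd = 0.3, residual_sd = 2,
                         seed = 6)
  expect_lt(abs(icc2k(t1)$icc), 0.2)
  # NA fraction honoured
  t2 <- make_score_table(50, na_frac = 0.2, seed = 7)
  expect_equal(mean(is.na(t2)), 0.2, tolerance = 0.01)
})

test_that("allometry generator: noiseless data recovers the line exactly", {
  d <- make_allometry_sample(30, slope = 2, intercept = 1, noise_sd = 0,
                             seed = 8)
  fit <- major_axis(d$x, d$y)
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("phantom truth validates its invariants", {
  expect_error(phantom_truth(fabric_axes = matrix(1, 3, 3)), "orthonormal")
  expect_error(phantom_truth(fabric_eigenvalues = c(1, 2, 3)), "descending")
})
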