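test_that("principal axis recovers a capsule's long axis, also after rotation", {
  pts <- capsule_points()
  ax <- principal_axis(pts, proximal_hint_mm = c(0, 0, 100))
  expect_lt(angle_deg(ax, c(0, 0, 1)), 2)
  # hint orients the sign
  ax_down <- principal_axis(pts, proximal_hint_mm = c(0, 0, -100))
  expect_lt(sum(ax * ax_down), 0)
  # rotated capsule: axis maps by the same rotation
  R <- rotmat(c(1, 2, 0.5), 0.7)
  ptsR <- pts %*% t(R)
  axR <- principal_axis(ptsR, proximal_hint_mm = as.numeric(R %*% c(0, 0, 100)))
  expect_lt(angle_deg(axR, as.numeric(R %*% c(0, 0, 1))), 2)
  # a cube has three equal inertia moments: no distinct long axis
  cube <- binary_volume(array(TRUE, c(15, 15, 15)), 0.5)
  expect_error(principal_axis(cube, c(0, 0, 10)), "degenerate")
})

test_that("sphere fitting is exact on exact data and robust to noise", {
  set.seed(5)
  u <- matrix(rnorm(60), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(5 * u, 2, c(1, 2, 3), "+")
  fit <- fit_sphere(pts)
  expect_equal(fit$center, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(fit$radius, 5, tolerance = 1e-9)
  expect_lt(fit$rms_residual, 1e-9)
  # Monte-Carlo recovery under Gaussian noise sd 0.05
  errs <- replicate(50, {
    noisy <- pts + matrix(rnorm(60, 0, 0.05), ncol = 3)
    sqrt(sum((fit_sphere(noisy)$center - c(1, 2, 3))^2))
  })
  expect_lt(mean(errs), 0.05 * sqrt(3 / 20) * 5)
  # coplanar points are rejected
  flat <- cbind(rnorm(10), rnorm(10), 0)
  expect_error(fit_sphere(flat), "coplanar")
})

test_that("frame construction gives the documented right-handed axes", {
  fr <- build_frame(c(0, 0, 1), c(-5, 0, 0), c(5, 0, 0), "right")
  expect_equal(fr$x_axis, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$y_axis, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(fr$z_axis, c(0, 0, 1), tolerance = 1e-12)
  # property: orthonormal right-handed for arbitrary valid inputs
  set.seed(7)
  for (i in 1:20) {
    z <- rnorm(3); z <- z / sqrt(sum(z^2))
    med <- rnorm(3); lat <- rnorm(3)
    if (angle_deg(z, lat - med) < 5) next
    fr <- build_frame(z, med, lat, "right")
    B <- rbind(fr$x_axis, fr$y_axis, fr$z_axis)
    expect_equal(B %*% t(B), diag(3), tolerance = 1e-12)
    expect_equal(pracma_cross_test(fr$x_axis, fr$y_axis), fr$z_axis,
                 tolerance = 1e-12)
  }
  expect_error(build_frame(c(0, 0, 1), c(0, 0, 0), c(0, 0, 0)), "distinct")
  expect_error(build_frame(c(1, 0, 0), c(-5, 0, 0), c(5, 0, 0)), "parallel")
})

test_that("frame construction is rotation-equivariant", {
  R <- rotmat(c(0.2, -1, 0.4), 1.1)
  z <- c(0.1, 0.2, 1); z <- z / sqrt(sum(z^2))
  med <- c(-4, 0.5, 0); lat <- c(5, -0.2, 0.3)
  f1 <- build_frame(z, med, lat, "right")
  f2 <- build_frame(as.numeric(R %*% z), as.numeric(R %*% med),
                    as.numeric(R %*% lat), "right")
  for (axn in c("x_axis", "y_axis", "z_axis"))
    expect_equal(f2[[axn]], as.numeric(R %*% f1[[axn]]), tolerance = 1e-10)
})

test_that("left bones mirror to the same anatomically referenced angles", {
  # right femur and its mirrored (left) twin: world x negated
  z <- c(0, 0.05, 1); z <- z / sqrt(sum(z^2))
  med_r <- c(-5, 0.3, 0.2); lat_r <- c(5, -0.1, 0.1)
  v_r <- c(0.15, sin(0.3), cos(0.3))          # a fabric axis on the right bone
  mir <- function(v) c(-v[1], v[2], v[3])
  fr_r <- build_frame(z, med_r, lat_r, "right")
  # the left bone's geometry is the mirror image; labels stay anatomical
  fr_l <- build_frame(mir(z), mir(med_r), mir(lat_r), "left")
  a_r <- inclination_angles(express_in_frame(v_r, fr_r))
  a_l <- inclination_angles(express_in_frame(mir(v_r), fr_l))
  expect_equal(a_l, a_r, tolerance = 1e-9)
})

test_that("axial mean handles antipodal input and known dispersions", {
  m <- axial_mean(rbind(c(0, 0, 1), c(0, 0, -1)))
  expect_equal(m$axis, c(0, 0, 1))
  expect_equal(m$r_bar, 1)
  # two axes +-10 degrees about z in the xz-plane
  th <- 10 * pi / 180
  m2 <- axial_mean(rbind(c(sin(th), 0, cos(th)), c(-sin(th), 0, cos(th))))
  expect_equal(m2$axis, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(m2$r_bar, cos(th), tolerance = 1e-12)
  # invariance to arbitrary sign flips
  set.seed(9)
  v <- matrix(rnorm(300), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  v <- sweep(v, 2, c(0.2, 0.1, 3), "+")
  v <- v / sqrt(rowSums(v^2))
  flips <- sample(c(-1, 1), 100, replace = TRUE)
  m3 <- axial_mean(v)
  m4 <- axial_mean(v * flips)
  expect_equal(m3$axis, m4$axis, tolerance = 1e-12)
  expect_equal(m3$r_bar, m4$r_bar, tolerance = 1e-12)
  # concentrated axial sample about z recovers the pole
  set.seed(10)
  w <- cbind(rnorm(100, 0, 0.02), rnorm(100, 0, 0.02), 1)
  w <- w / sqrt(rowSums(w^2))
  m5 <- axial_mean(w * sample(c(-1, 1), 100, replace = TRUE))
  expect_lt(angle_deg(m5$axis, c(0, 0, 1)), 3)
})

test_that("inclination angles follow the stated sign conventions", {
  expect_equal(inclination_angles(c(0, 0, 1)),
               c(anterior_incl_deg = 0, medial_incl_deg = 0))
  v <- c(0, sin(20 * pi / 180), cos(20 * pi / 180))
  expect_equal(inclination_angles(v)[["anterior_incl_deg"]], 20,
               tolerance = 1e-9)
  expect_equal(inclination_angles(v)[["medial_incl_deg"]], 0,
               tolerance = 1e-9)
  # medial is towards -x
  vm <- c(-sin(10 * pi / 180), 0, cos(10 * pi / 180))
  expect_equal(inclination_angles(vm)[["medial_incl_deg"]], 10,
               tolerance = 1e-9)
  # rotation-matrix oracle: compose anterior then medial rotations
  a <- 17 * pi / 180; b <- -8 * pi / 180
  v2 <- rotmat(c(1, 0, 0), -a) %*% c(0, 0, 1)   # rotate +z towards +y
  expect_equal(inclination_angles(as.numeric(v2))[["anterior_incl_deg"]],
               17, tolerance = 1e-9)
  expect_error(inclination_angles(c(1, 0, 0)), "undefined")
})

test_that("equal-angle projection matches tan(theta/2) and round-trips", {
  p0 <- stereo_project(c(0, 0, 1), "north")
  expect_equal(c(p0$x, p0$y), c(0, 0))
  p90 <- stereo_project(c(1, 0, 0), "north")
  expect_equal(c(p90$x, p90$y), c(1, 0), tolerance = 1e-12)
  p45 <- stereo_project(c(0, sin(pi / 4), cos(pi / 4)), "north")
  expect_equal(c(p45$x, p45$y), c(0, tan(pi / 8)), tolerance = 1e-6)
  expect_equal(p45$y, 0.41421, tolerance = 1e-4)
  # antipodal flip into the chosen hemisphere
  ps <- stereo_project(c(0, sin(pi / 4), cos(pi / 4)), "south")
  expect_equal(c(ps$x, ps$y), c(0, -tan(pi / 8)), tolerance = 1e-12)
  # round trip on random axes
  set.seed(11)
  for (i in 1:20) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    if (v[3] < 0) v <- -v
    back <- stereo_unproject(stereo_project(v, "north"))
    expect_equal(back, v, tolerance = 1e-12)
  }
})
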