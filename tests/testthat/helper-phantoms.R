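# shared small fixtures, built once per test run

angle_deg <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  acos(min(1, abs(sum(a * b)))) * 180 / pi
}

agg1 <- function(row) aggregate_scores(score_table(matrix(row, nrow = 1)))[1]

# independent fcc-lattice oracle: enumerate layered ccp sites from the
# closed-form site equations over an L x L x L cube with voxel pitch sp,
# and keep sites by brute-force voxel-counting containment (out-of-grid
# voxel centres count as outside the mask)
fcc_oracle <- function(r = 1, L = 8, sp = 0.1, min_frac = 0.95) {
  dz <- 2 * r * sqrt(2 / 3)
  ctr <- rep(L / 2, 3)
  nmax <- ceiling(sqrt(3) * L / (2 * r)) + 2
  sites <- list()
  for (m in -nmax:nmax) for (j in -nmax:nmax) for (i in -nmax:nmax) {
    s3 <- (m %% 3)
    sites[[length(sites) + 1]] <-
      c(2 * r * i + (j %% 2) * r + s3 * r,
        sqrt(3) * r * j + s3 * r / sqrt(3),
        dz * m) + ctr
  }
  sites <- do.call(rbind, sites)
  n_vox <- round(L / sp) + 1
  gx_ext <- (-ceiling(1.5 * r / sp):(n_vox - 1 + ceiling(1.5 * r / sp))) * sp
  in_grid <- gx_ext >= -1e-12 & gx_ext <= L + 1e-12
  ok3 <- outer(outer(in_grid, in_grid, "&"), in_grid, "&")
  keep <- apply(sites, 1, function(s) {
    if (any(s < -r) || any(s > L + r)) return(FALSE)
    q1 <- (gx_ext - s[3])^2
    q2 <- (gx_ext - s[2])^2
    q3 <- (gx_ext - s[1])^2
    inside <- outer(outer(q1, q2, "+"), q3, "+") <= r^2
    sum(inside & ok3) / sum(inside) >= min_frac
  })
  sites[keep, , drop = FALSE]
}

pracma_cross_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotmat <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * ct + st * K + (1 - ct) * outer(a, a)
}

# small axis-aligned rod lattice (64^3), cached
small_rods <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- make_rod_lattice(c(64, 64, 64), 0.05, axis = c(0, 0, 1),
                               rod_radius_mm = 0.2, pitch_mm = 1,
                               jitter_frac = 0.3, seed = 11)
    val
  }
})

# connected scaffold for segmentation experiments (96^3), cached
scaffold <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- make_connected_lattice(c(96, 96, 96), 0.05)
    val
  }
})

# protocol-4 spec matched to corrupt_ct defaults (bone grey value 100)
p4_spec <- function() protocol_spec(4, small_median_radius_px = 2,
                                    large_median_radius_px = 12,
                                    mean3d_radius_px = 2,
                                    global_threshold = 45)

# capsule point cloud along +z, for inertia-axis tests
capsule_points <- function(n = 4000, length = 20, radius = 2, seed = 1) {
  set.seed(seed)
  z <- runif(n, 0, length)
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th), z)
}
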