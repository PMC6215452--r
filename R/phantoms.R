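#' Synthetic trabecular phantoms
#'
#' Generators for every input the analysis pipeline consumes: binary
#' trabecular volumes with known fabric, greyscale pseudo-CT with background
#' drift and impulse noise, whole-bone phantoms with known long axis and
#' condyle centres, rater score tables and bivariate allometry samples.
#' All generators are deterministic under a fixed seed and use a private
#' random stream (the caller's `.Random.seed` is untouched).
#'
#' @name phantoms
NULL

# run code with a private, explicitly seeded RNG stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

round_half_up <- function(x) floor(x + 0.5)

#' Parallel-rod trabecular lattice phantom
#'
#' Cylindrical rods of radius `rod_radius_mm` run along `axis` with their
#' centres on a square lattice of period `pitch_mm` in the perpendicular
#' plane, each jittered by up to `jitter_frac * pitch_mm / 2`. Emulates
#' strongly aligned trabecular tracts; the primary fabric direction of the
#' result is `axis` by construction.
#'
#' @param shape_vox grid dimensions, array order (slice, row, col).
#' @param spacing_mm voxel size (scalar or per-axis, array order).
#' @param axis rod direction, world (x, y, z); normalised internally.
#' @param rod_radius_mm rod radius; must be < `pitch_mm / 2`.
#' @param pitch_mm lattice period between rod centres.
#' @param jitter_frac lateral jitter as a fraction of the pitch, in \[0, 1).
#' @param seed integer seed for the jitter stream.
#' @return list with elements `volume` (a [binary_volume()]) and `truth`
#'   (a [phantom_truth()] with `fabric_axes[1, ] == axis`).
#' @export
make_rod_lattice <- function(shape_vox, spacing_mm, axis = c(0, 0, 1),
                             rod_radius_mm, pitch_mm, jitter_frac = 0,
                             seed = 1) {
  axis <- unitize(axis, "axis")
  if (rod_radius_mm <= 0 || rod_radius_mm >= pitch_mm / 2)
    stop("rod radius must be in (0, pitch/2): rods must not merge")
  if (jitter_frac < 0 || jitter_frac >= 1) stop("jitter_frac must be in [0,1)")
  spacing_mm <- rep_len(spacing_mm, 3)
  pq <- perp_basis(axis)                       # world xyz
  p_arr <- xyz_to_arr(pq[1, ])
  q_arr <- xyz_to_arr(pq[2, ])
  ext <- (shape_vox - 1) * spacing_mm
  corners <- as.matrix(expand.grid(c(0, ext[1]), c(0, ext[2]), c(0, ext[3])))
  u <- corners %*% p_arr
  v <- corners %*% q_arr
  ci <- floor(min(u) / pitch_mm) - 1L
  cj <- floor(min(v) / pitch_mm) - 1L
  nu <- ceiling(max(u) / pitch_mm) + 1L - ci + 1L
  nv <- ceiling(max(v) / pitch_mm) + 1L - cj + 1L
  half <- jitter_frac * pitch_mm / 2
  jit <- with_seed(seed, list(
    u = matrix(stats::runif(nu * nv, -half, half), nu, nv),
    v = matrix(stats::runif(nu * nv, -half, half), nu, nv)))
  grid <- cpp_fill_rods(as.integer(shape_vox), spacing_mm, p_arr, q_arr,
                        pitch_mm, rod_radius_mm, ci, cj, jit$u, jit$v)
  vol <- binary_volume(grid, spacing_mm)
  truth <- phantom_truth(
    fabric_axes = rbind(axis, pq[1, ], pq[2, ]),
    fabric_eigenvalues = c(1.8, 0.6, 0.6),
    bvtv = bone_fraction(vol),
    tb_sp_mm = pitch_mm - 2 * rod_radius_mm)
  list(volume = vol, truth = truth)
}

#' Parallel-plate trabecular phantom
#'
#' Solid slabs of thickness `plate_thickness_mm` separated by gaps of
#' `gap_mm`, normal to `normal`. Emulates plate-like trabeculae; the tertiary
#' fabric direction of the result is `normal` and the trabecular spacing is
#' the gap by construction.
#'
#' @inheritParams make_rod_lattice
#' @param normal plate normal, world (x, y, z).
#' @param plate_thickness_mm slab thickness.
#' @param gap_mm inter-slab gap (= nominal Tb.Sp).
#' @return list with `volume` and `truth` (`fabric_axes[3, ] == normal`).
#' @export
make_plate_stack <- function(shape_vox, spacing_mm, normal = c(0, 0, 1),
                             plate_thickness_mm, gap_mm) {
  normal <- unitize(normal, "normal")
  if (plate_thickness_mm <= 0 || gap_mm <= 0)
    stop("thickness and gap must be positive")
  spacing_mm <- rep_len(spacing_mm, 3)
  n_arr <- xyz_to_arr(normal)
  period <- plate_thickness_mm + gap_mm
  a1 <- (seq_len(shape_vox[1]) - 1) * spacing_mm[1] * n_arr[1]
  a2 <- (seq_len(shape_vox[2]) - 1) * spacing_mm[2] * n_arr[2]
  a3 <- (seq_len(shape_vox[3]) - 1) * spacing_mm[3] * n_arr[3]
  s <- outer(outer(a1, a2, "+"), a3, "+") %% period
  grid <- s < plate_thickness_mm
  vol <- binary_volume(grid, spacing_mm)
  pq <- perp_basis(normal)
  truth <- phantom_truth(
    fabric_axes = rbind(pq[1, ], pq[2, ], normal),
    fabric_eigenvalues = c(1.25, 1.25, 0.5),
    bvtv = bone_fraction(vol),
    tb_sp_mm = gap_mm)
  list(volume = vol, truth = truth)
}

#' Connected trabecular scaffold phantom
#'
#' Union of a primary rod lattice along `axis` and a thinner transverse rod
#' lattice sharing the same (unjittered) lattice coordinates, so every cross
#' strut intersects the primary rods: the bone phase is a single 26-connected
#' network -- like real cancellous bone, and unlike the plain rod lattice
#' whose rods are mutually disconnected. This is the standard phantom for
#' segmentation-recovery experiments, where largest-component cleaning would
#' otherwise discard most of a disconnected structure. The primary fabric
#' direction remains the (thicker, denser) rod axis.
#'
#' @inheritParams make_rod_lattice
#' @param rod_radius_mm,pitch_mm primary rod lattice parameters.
#' @param cross_radius_mm radius of the transverse bracing struts
#'   (< `rod_radius_mm` keeps the fabric dominated by the primary rods).
#' @return list with `volume` and `truth` (`fabric_axes[1, ] == axis`).
#' @export
make_connected_lattice <- function(shape_vox, spacing_mm, axis = c(0, 0, 1),
                                   rod_radius_mm = 0.2, pitch_mm = 1,
                                   cross_radius_mm = 0.12) {
  axis <- unitize(axis, "axis")
  spacing_mm <- rep_len(spacing_mm, 3)
  rods <- make_rod_lattice(shape_vox, spacing_mm, axis, rod_radius_mm,
                           pitch_mm, jitter_frac = 0, seed = 1)
  pq <- perp_basis(axis)
  # cross struts along both transverse directions, sharing the unjittered
  # lattice coordinates of the primary rods so every strut meets them
  ext <- sqrt(sum(((shape_vox - 1) * spacing_mm)^2))
  n <- ceiling(ext / pitch_mm) + 2
  zjit <- matrix(0, 2 * n + 3, 2 * n + 3)
  cross1 <- cpp_fill_rods(as.integer(shape_vox), spacing_mm,
                          xyz_to_arr(pq[2, ]), xyz_to_arr(axis),
                          pitch_mm, cross_radius_mm, -(n + 1L), -(n + 1L),
                          zjit, zjit)
  cross2 <- cpp_fill_rods(as.integer(shape_vox), spacing_mm,
                          xyz_to_arr(pq[1, ]), xyz_to_arr(axis),
                          pitch_mm, cross_radius_mm, -(n + 1L), -(n + 1L),
                          zjit, zjit)
  vol <- binary_volume(rods$volume$grid | cross1 | cross2, spacing_mm)
  truth <- rods$truth
  truth$bvtv <- bone_fraction(vol)
  list(volume = vol, truth = truth)
}

#' Isotropic Boolean-model phantom
#'
#' Union of equal spheres at uniform random centres, added one at a time
#' until the bone fraction reaches `target_bvtv`. Having no preferred
#' direction, its fabric tensor is isotropic (DA close to 1).
#'
#' @inheritParams make_rod_lattice
#' @param grain_radius_mm radius of the spherical grains.
#' @param target_bvtv target bone volume fraction in (0, 1); achieved within
#'   +- 0.02 provided the grain volume is small relative to the volume.
#' @return list with `volume` and `truth` (equal eigenvalues).
#' @export
make_isotropic_boolean <- function(shape_vox, spacing_mm, grain_radius_mm,
                                   target_bvtv, seed = 1) {
  if (target_bvtv <= 0 || target_bvtv >= 1)
    stop("target_bvtv must be in (0, 1)")
  spacing_mm <- rep_len(spacing_mm, 3)
  ext <- (shape_vox - 1) * spacing_mm
  v_grain <- 4 / 3 * pi * grain_radius_mm^3
  v_tot <- prod(ext + spacing_mm)
  n_max <- ceiling(3 * (-log(1 - target_bvtv)) * v_tot / v_grain) + 200
  centers <- with_seed(seed, cbind(stats::runif(n_max, 0, ext[1]),
                                   stats::runif(n_max, 0, ext[2]),
                                   stats::runif(n_max, 0, ext[3])))
  grid <- cpp_fill_spheres(as.integer(shape_vox), spacing_mm, centers,
                           grain_radius_mm, target_bvtv)
  if (attr(grid, "n_used") < 0)
    stop("target bone fraction unreachable with this grain radius")
  attr(grid, "n_used") <- NULL
  vol <- binary_volume(grid, spacing_mm)
  if (abs(bone_fraction(vol) - target_bvtv) > 0.02)
    stop("achieved bone fraction outside +-0.02 of target; ",
         "use a smaller grain radius")
  truth <- phantom_truth(fabric_axes = diag(3),
                         fabric_eigenvalues = c(1, 1, 1) + c(2, 1, 0) * 1e-12,
                         bvtv = bone_fraction(vol),
                         tb_sp_mm = NA_real_)
  list(volume = vol, truth = truth)
}

#' Corrupt a binary phantom into pseudo-CT greyscale
#'
#' Adds the noise regime of low-powered scans of dense specimens: a smooth
#' low-frequency background field (beam-hardening-like drift) spanning
#' `[0, gradient_amplitude]`, salt-and-pepper impulse noise, and optional
#' Gaussian blur.
#'
#' @param binary a [binary_volume()] ground truth.
#' @param bone_value grey value of the bone phase.
#' @param gradient_amplitude peak-to-peak amplitude of the background drift.
#' @param impulse_frac fraction of voxels replaced by impulses, in \[0, 1);
#'   half are set to `2.5 * bone_value` (salt), half to 0 (pepper).
#' @param blur_sigma_vox Gaussian blur sigma in voxels (0 = none).
#' @param seed integer seed.
#' @return a [voxel_volume()] on the same grid.
#' @export
corrupt_ct <- function(binary, bone_value = 100, gradient_amplitude = 40,
                       impulse_frac = 0.05, blur_sigma_vox = 0, seed = 1) {
  stopifnot(inherits(binary, "binary_volume"))
  if (impulse_frac < 0 || impulse_frac >= 1)
    stop("impulse_frac must be in [0, 1)")
  d <- dim(binary$grid)
  g <- bone_value * binary$grid
  with_seed(seed, {
    if (gradient_amplitude > 0) {
      ph <- stats::runif(3, 0, 2 * pi)
      s1 <- sin(2 * pi * (seq_len(d[1]) - 1) / d[1] + ph[1])
      s2 <- sin(2 * pi * (seq_len(d[2]) - 1) / d[2] + ph[2])
      s3 <- sin(2 * pi * (seq_len(d[3]) - 1) / d[3] + ph[3])
      fld <- outer(outer(s1, s2, "+"), s3, "+")
      fld <- (fld - min(fld)) / (max(fld) - min(fld)) * gradient_amplitude
      g <- g + fld
    }
    if (blur_sigma_vox > 0)
      g <- cpp_gaussian_blur(g, rep_len(blur_sigma_vox, 3))
    if (impulse_frac > 0) {
      n_imp <- round(impulse_frac * length(g))
      at <- sample.int(length(g), n_imp)
      salt <- seq_len(n_imp) %% 2 == 0
      g[at[salt]] <- 2.5 * bone_value
      g[at[!salt]] <- 0
    }
  })
  dim(g) <- d
  voxel_volume(g, binary$spacing_mm, binary$origin_mm)
}

#' Whole-bone phantom with condyles and a trabecular metaphysis
#'
#' A femur-like right-side phantom: a hollow cortical tube along +z (world)
#' with end caps, two condylar spheres at the distal end separated along the
#' mediolateral (x) axis, and a proximal metaphyseal plug filled with a rod
#' lattice whose axis is given in `fill_spec`. The cortex is a thin shell --
#' like a real long bone -- so local thresholding, which assigns uniform
#' solid interiors to background, segments the whole phantom, and the rods
#' abut the proximal cap so the bone phase is one connected network. The
#' ground truth records the long axis, condyle centres and the fill axis, so
#' the full anatomical pipeline can be checked end to end.
#'
#' @param length_mm total proximodistal length.
#' @param shaft_radius_mm outer shaft radius.
#' @param cortex_mm cortical wall (and cap) thickness.
#' @param head_depth_mm depth of the proximal trabecular plug.
#' @param condyle_radius_mm radius of each condylar sphere.
#' @param condyle_sep_mm distance between the two condyle centres.
#' @param spacing_mm isotropic voxel size.
#' @param fill_spec list with `axis` (world xyz rod direction),
#'   `rod_radius_mm`, `pitch_mm`, `jitter_frac`, `seed`.
#' @return list with `volume` (whole bone), `cancellous_mask`
#'   (the metaphyseal plug available for VOI packing) and `truth`.
#' @export
make_bone_phantom <- function(length_mm = 36, shaft_radius_mm = 5,
                              cortex_mm = 1, head_depth_mm = 10,
                              condyle_radius_mm = 4.5, condyle_sep_mm = 10,
                              spacing_mm = 0.25,
                              fill_spec = list(axis = c(0, 0, 1),
                                               rod_radius_mm = 0.45,
                                               pitch_mm = 1.5,
                                               jitter_frac = 0.25,
                                               seed = 1)) {
  if (condyle_sep_mm <= 0) stop("condyle separation must be positive")
  if (condyle_sep_mm / 2 > shaft_radius_mm + condyle_radius_mm)
    stop("condyles are disjoint from the shaft")
  margin <- 2 * spacing_mm
  half_w <- max(shaft_radius_mm, condyle_sep_mm / 2 + condyle_radius_mm) +
    margin
  # world extents: x,y in [-half_w, half_w], z in [-margin, length + margin]
  nx <- ceiling(2 * half_w / spacing_mm) + 1
  nz <- ceiling((length_mm + 2 * margin) / spacing_mm) + 1
  shape <- c(nz, nx, nx)
  sp <- rep(spacing_mm, 3)
  origin_arr <- c(-margin, -half_w, -half_w)    # (z, y, x)
  z <- origin_arr[1] + (seq_len(shape[1]) - 1) * spacing_mm
  y <- origin_arr[2] + (seq_len(shape[2]) - 1) * spacing_mm
  x <- origin_arr[3] + (seq_len(shape[3]) - 1) * spacing_mm
  zero2 <- outer(y * 0, x * 0, "+") > 1          # all-FALSE slice
  R2 <- outer(y^2, x^2, "+")                    # squared distance to z-axis
  cr <- condyle_radius_mm
  c_med <- c(-condyle_sep_mm / 2, 0, cr)        # world xyz
  c_lat <- c(condyle_sep_mm / 2, 0, cr)
  w <- cortex_mm
  r_in <- shaft_radius_mm - w                   # endosteal radius
  plug_lo <- length_mm - head_depth_mm          # metaphyseal plug z-range
  plug_hi <- length_mm - w
  grid <- array(FALSE, shape)
  # rod fill over the whole grid, masked into the plug below
  fs <- utils::modifyList(list(axis = c(0, 0, 1), rod_radius_mm = 0.45,
                               pitch_mm = 1.5, jitter_frac = 0.25, seed = 1),
                          fill_spec)
  rods <- make_rod_lattice(shape, sp, fs$axis, fs$rod_radius_mm, fs$pitch_mm,
                           fs$jitter_frac, fs$seed)$volume$grid
  head_mask <- array(FALSE, shape)
  for (i in seq_len(shape[1])) {
    zi <- z[i]
    in_tube <- zi >= cr && zi <= length_mm
    cap <- in_tube && (zi <= cr + w || zi >= length_mm - w)
    shell <- if (!in_tube) zero2
             else if (cap) R2 <= shaft_radius_mm^2
             else R2 <= shaft_radius_mm^2 & R2 >= r_in^2
    cond <- outer(y^2, (x - c_med[1])^2, "+") + (zi - c_med[3])^2 <= cr^2 |
            outer(y^2, (x - c_lat[1])^2, "+") + (zi - c_lat[3])^2 <= cr^2
    plug <- if (zi >= plug_lo && zi <= plug_hi) R2 <= r_in^2 else zero2
    head_mask[i, , ] <- plug
    grid[i, , ] <- shell | cond | (plug & rods[i, , ])
  }
  vol <- binary_volume(grid, sp, origin_arr)
  truth <- phantom_truth(
    fabric_axes = rbind(unitize(fs$axis), perp_basis(unitize(fs$axis))),
    fabric_eigenvalues = c(1.8, 0.6, 0.6),
    bvtv = bone_fraction(vol),
    tb_sp_mm = fs$pitch_mm - 2 * fs$rod_radius_mm,
    condyle_centers_mm = rbind(medial = c_med, lateral = c_lat),
    long_axis = c(0, 0, 1))
  list(volume = vol,
       cancellous_mask = binary_volume(head_mask, sp, origin_arr),
       truth = truth)
}

#' Surface points of a phantom condyle
#'
#' Extracts voxel centres on the outer surface of one condylar sphere of a
#' [make_bone_phantom()] output, excluding the region merged with the shaft,
#' for use with [fit_sphere()].
#'
#' @param phantom output of [make_bone_phantom()].
#' @param which `"medial"` or `"lateral"`.
#' @param max_points subsample size (deterministic thinning).
#' @return n x 3 matrix of world (x, y, z) points in mm.
#' @export
condyle_surface_points <- function(phantom, which = c("medial", "lateral"),
                                   max_points = 500) {
  which <- match.arg(which)
  vol <- phantom$volume
  tr <- phantom$truth
  ctr <- tr$condyle_centers_mm[which, ]          # world xyz
  r <- ctr[3]          # condyle touches the z = 0 plane, so centre z = radius
  sp <- vol$spacing_mm
  idx <- which(vol$grid, arr.ind = TRUE)
  pos <- index_to_mm(vol, idx)                   # array order (z, y, x)
  xyz <- pos[, c(3, 2, 1), drop = FALSE]
  dd <- sqrt((xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 +
               (xyz[, 3] - ctr[3])^2)
  shell <- dd >= r - 1.5 * max(sp) & dd <= r + 0.5 * max(sp)
  # keep the distal hemisphere, clear of the shaft
  keep <- shell & (xyz[, 3] < r)
  pts <- xyz[keep, , drop = FALSE]
  if (nrow(pts) > max_points)
    pts <- pts[round(seq(1, nrow(pts), length.out = max_points)), ,
               drop = FALSE]
  pts
}

#' Two-way rater score table with known variance components
#'
#' `score = mid-scale + bone effect + scorer effect + residual`, rounded
#' half-up to the feature's categorical scale and clipped to its range, with
#' missing cells ("n/a") inserted at rate `na_frac`.
#'
#' @param n_bones number of bones (rows).
#' @param n_scorers number of scorers (columns).
#' @param bone_sd,scorer_sd,residual_sd standard deviations of the normal
#'   variance components.
#' @param na_frac fraction of cells set to NA, in \[0, 1).
#' @param seed integer seed.
#' @param feature feature id (1: extent 0-3; 2: orientation 0-8;
#'   3: association 0-2); sets the scale range.
#' @return a [score_table()].
#' @export
make_score_table <- function(n_bones, n_scorers = 5, bone_sd = 1,
                             scorer_sd = 0.3, residual_sd = 0.5,
                             na_frac = 0, seed = 1, feature = 2) {
  stopifnot(bone_sd >= 0, scorer_sd >= 0, residual_sd >= 0,
            na_frac >= 0, na_frac < 1)
  rng <- feature_scale(feature)
  mu <- mean(rng)
  with_seed(seed, {
    b <- stats::rnorm(n_bones, 0, bone_sd)
    s <- stats::rnorm(n_scorers, 0, scorer_sd)
    e <- matrix(stats::rnorm(n_bones * n_scorers, 0, residual_sd),
                n_bones, n_scorers)
    sc <- round_half_up(mu + outer(b, s, "+") + e)
    sc <- pmin(pmax(sc, rng[1]), rng[2])
    if (na_frac > 0)
      sc[sample.int(length(sc), round(na_frac * length(sc)))] <- NA
    score_table(sc, feature = feature)
  })
}

#' Bivariate allometry sample
#'
#' `x` uniform on `x_range`; `y = intercept + slope * x + e` with
#' `sd(e) = noise_sd * x^hetero_power` (heteroscedastic for
#' `hetero_power > 0`).
#'
#' @param n sample size (>= 3).
#' @param slope,intercept line parameters.
#' @param noise_sd baseline residual standard deviation.
#' @param hetero_power power of `x` scaling the residual sd.
#' @param seed integer seed.
#' @param x_range range of the uniform predictor.
#' @return data.frame with columns `x`, `y`.
#' @export
make_allometry_sample <- function(n, slope = 1, intercept = 0, noise_sd = 0,
                                  hetero_power = 0, seed = 1,
                                  x_range = c(1, 10)) {
  if (n < 3) stop("n must be >= 3")
  with_seed(seed, {
    x <- stats::runif(n, x_range[1], x_range[2])
    e <- if (noise_sd > 0)
      stats::rnorm(n, 0, noise_sd * x^hetero_power) else numeric(n)
    data.frame(x = x, y = intercept + slope * x + e)
  })
}
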