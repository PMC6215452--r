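#' Spherical volumes of interest
#'
#' Fabric is computed per spherical VOI (spheres avoid corner effects).
#' VOIs tile the cancellous region in a cubic close-packed (fcc) arrangement
#' with nearest-neighbour centre distance exactly `2 * radius`, so adjacent
#' spheres touch without overlapping and each part of the bone is analysed
#' only once.
#'
#' @name voi
NULL

#' @param center_mm world (x, y, z) centre in mm.
#' @param radius_mm sphere radius (> 0).
#' @rdname voi
#' @export
sphere_voi <- function(center_mm, radius_mm) {
  stopifnot(length(center_mm) == 3, radius_mm > 0)
  structure(list(center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm), class = "sphere_voi")
}

# fcc site coordinates (world xyz) for layer m, row j, col i: hexagonal
# layers stacked along +z with ABC offsets; nearest-neighbour distance 2r.
ccp_site <- function(i, j, m, r) {
  dz <- 2 * r * sqrt(2 / 3)
  cbind(2 * r * i + (j %% 2) * r + (m %% 3) * r,
        sqrt(3) * r * j + (m %% 3) * r / sqrt(3),
        dz * m)
}

#' Pack a mask with close-packed spherical VOIs
#'
#' Generates a cubic close-packed sphere lattice ([111] stacking along z by
#' default, optionally rotated), and retains each VOI whose sphere lies
#' within the cancellous mask up to the containment tolerance: at least
#' `min_contained_frac` of its voxels must fall on TRUE mask voxels. This is
#' the reproducible surrogate for manual pruning of peripheral VOIs that
#' would include more than minimal cortical bone or medullary cavity.
#'
#' @param mask a [binary_volume()]; TRUE marks the cancellous region.
#' @param radius_mm VOI radius (>= 2 voxels).
#' @param offset_mm lattice translation, world (x, y, z).
#' @param orientation 3x3 rotation applied to the lattice.
#' @param min_contained_frac minimum fraction of VOI voxels inside the mask.
#' @return a `voi_set`: data.frame with columns id, cx, cy, cz, radius_mm,
#'   n_voxels, contained_frac, plus lattice metadata attributes. Empty (with
#'   a warning) if the mask admits no VOI.
#' @export
ccp_pack <- function(mask, radius_mm, offset_mm = c(0, 0, 0),
                     orientation = diag(3), min_contained_frac = 0.95) {
  stopifnot(inherits(mask, "binary_volume"))
  sp <- mask$spacing_mm
  if (radius_mm < 2 * max(sp)) stop("VOI radius must be >= 2 voxels")
  d <- dim(mask$grid)
  # world-extent corners (xyz) of the grid
  lo_arr <- mask$origin_mm
  hi_arr <- mask$origin_mm + (d - 1) * sp
  lo <- arr_to_xyz(lo_arr); hi <- arr_to_xyz(hi_arr)
  r <- radius_mm
  # generate lattice sites covering the (rotated) bounding box
  span <- sqrt(sum((hi - lo)^2))
  ctr <- (lo + hi) / 2
  nmax <- ceiling(span / (2 * r)) + 2
  ij <- expand.grid(i = -nmax:nmax, j = -nmax:nmax, m = -nmax:nmax)
  sites <- ccp_site(ij$i, ij$j, ij$m, r)
  sites <- sweep(sites %*% t(orientation), 2,
                 ctr + as.numeric(offset_mm), "+")
  keep <- sites[, 1] >= lo[1] - r & sites[, 1] <= hi[1] + r &
          sites[, 2] >= lo[2] - r & sites[, 2] <= hi[2] + r &
          sites[, 3] >= lo[3] - r & sites[, 3] <= hi[3] + r
  sites <- sites[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(sites)), function(s) {
    ov <- sphere_mask_overlap(mask, sites[s, ], r)
    if (ov$frac >= min_contained_frac)
      data.frame(cx = sites[s, 1], cy = sites[s, 2], cz = sites[s, 3],
                 radius_mm = r, n_voxels = ov$n_total,
                 contained_frac = ov$frac)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    warning("mask too small: no VOI satisfies the containment rule")
    out <- data.frame(cx = numeric(0), cy = numeric(0), cz = numeric(0),
                      radius_mm = numeric(0), n_voxels = integer(0),
                      contained_frac = numeric(0))
  }
  out <- cbind(id = seq_len(nrow(out)), out)
  structure(out, class = c("voi_set", "data.frame"),
            radius_mm = r, offset_mm = offset_mm, orientation = orientation)
}

# fraction of the voxels of a sphere (centre world xyz, radius mm) that fall
# on TRUE voxels of `mask`; out-of-grid voxels count as outside the mask
sphere_mask_overlap <- function(mask, center_xyz, radius_mm) {
  sp <- mask$spacing_mm
  d <- dim(mask$grid)
  c_arr <- xyz_to_arr(center_xyz)
  idx_c <- (c_arr - mask$origin_mm) / sp + 1
  rng <- lapply(1:3, function(a)
    floor(idx_c[a] - radius_mm / sp[a]):ceiling(idx_c[a] + radius_mm / sp[a]))
  g1 <- (rng[[1]] - idx_c[1]) * sp[1]
  g2 <- (rng[[2]] - idx_c[2]) * sp[2]
  g3 <- (rng[[3]] - idx_c[3]) * sp[3]
  inside <- outer(outer(g1^2, g2^2, "+"), g3^2, "+") <= radius_mm^2
  n_total <- sum(inside)
  ok1 <- rng[[1]] >= 1 & rng[[1]] <= d[1]
  ok2 <- rng[[2]] >= 1 & rng[[2]] <= d[2]
  ok3 <- rng[[3]] >= 1 & rng[[3]] <= d[3]
  sub <- mask$grid[rng[[1]][ok1], rng[[2]][ok2], rng[[3]][ok3], drop = FALSE]
  ins_in <- inside[ok1, ok2, ok3, drop = FALSE]
  n_in <- sum(sub & ins_in)
  list(frac = n_in / n_total, n_total = n_total)
}

#' Drop VOIs overlapping an exclusion mask
#'
#' Removes any VOI whose overlap fraction with the exclusion mask (cracks,
#' deformed regions, medullary cavity) exceeds `max_excluded_frac`.
#'
#' @param vois a `voi_set` from [ccp_pack()].
#' @param exclusion_mask a [binary_volume()] co-registered with the VOI grid;
#'   TRUE marks voxels to avoid.
#' @param max_excluded_frac maximum tolerated overlap fraction.
#' @return the filtered `voi_set`, with an `excluded_frac` column.
#' @export
exclude_vois <- function(vois, exclusion_mask, max_excluded_frac = 0.05) {
  stopifnot(inherits(vois, "voi_set"), inherits(exclusion_mask,
                                                "binary_volume"))
  if (nrow(vois) == 0) return(vois)
  fr <- vapply(seq_len(nrow(vois)), function(s) {
    sphere_mask_overlap(exclusion_mask,
                        c(vois$cx[s], vois$cy[s], vois$cz[s]),
                        vois$radius_mm[s])$frac
  }, numeric(1))
  vois$excluded_frac <- fr
  out <- vois[fr <= max_excluded_frac, , drop = FALSE]
  attributes(out)[c("radius_mm", "offset_mm", "orientation")] <-
    attributes(vois)[c("radius_mm", "offset_mm", "orientation")]
  class(out) <- c("voi_set", "data.frame")
  out
}

#' Mean trabecular spacing (Tb.Sp)
#'
#' Mean local thickness of the background (non-bone) phase, using the
#' largest-inscribed-sphere definition computed from the Euclidean distance
#' transform.
#'
#' @param binary a [binary_volume()].
#' @param region optional [sphere_voi()]; the statistic is restricted to
#'   voxels inside it.
#' @return mean spacing in mm.
#' @export
trabecular_spacing <- function(binary, region = NULL) {
  stopifnot(inherits(binary, "binary_volume"))
  g <- binary$grid
  sp <- binary$spacing_mm
  sel <- NULL
  if (!is.null(region)) {
    c_arr <- xyz_to_arr(region$center_mm)
    idx_c <- (c_arr - binary$origin_mm) / sp + 1
    d <- dim(g)
    rng <- lapply(1:3, function(a) {
      max(1, floor(idx_c[a] - region$radius_mm / sp[a])):
        min(d[a], ceiling(idx_c[a] + region$radius_mm / sp[a]))
    })
    g <- g[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    g1 <- (rng[[1]] - idx_c[1]) * sp[1]
    g2 <- (rng[[2]] - idx_c[2]) * sp[2]
    g3 <- (rng[[3]] - idx_c[3]) * sp[3]
    sel <- outer(outer(g1^2, g2^2, "+"), g3^2, "+") <= region$radius_mm^2
  }
  n_bone <- if (is.null(sel)) sum(g) else sum(g & sel)
  n_bg <- if (is.null(sel)) sum(!g) else sum(!g & sel)
  if (n_bone == 0 || n_bg == 0)
    stop("region must contain both bone and background phases")
  th <- cpp_local_thickness(!g, sp)
  use <- !g & (if (is.null(sel)) TRUE else sel) & th > 0
  mean(th[use])
}

#' Continuum-scale rule for a VOI
#'
#' TRUE iff the VOI diameter spans at least five mean trabecular spacings,
#' the usual threshold for the continuum assumption of cancellous bone to
#' hold (and hence for a fabric tensor to be meaningful).
#'
#' @param voi a [sphere_voi()].
#' @param tb_sp_mm mean trabecular spacing in mm (> 0).
#' @return logical.
#' @export
continuum_ok <- function(voi, tb_sp_mm) {
  stopifnot(tb_sp_mm > 0)
  2 * voi$radius_mm >= 5 * tb_sp_mm
}
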