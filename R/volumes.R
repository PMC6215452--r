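#' 3D image volumes
#'
#' Volumes are stored as plain 3D arrays in CT-stack convention: array axes
#' are (slice, row, column), which map to world axes (z, y, x). A voxel with
#' (1-based) array index (i, j, k) has its centre at world position
#' `origin_mm + (index - 1) * spacing_mm` along each array axis. `spacing_mm`
#' and `origin_mm` are given in array-axis order; direction vectors in the
#' user-facing API (fabric axes, anatomical axes) are in world (x, y, z)
#' order. Use [xyz_to_arr()] / [arr_to_xyz()] to convert.
#'
#' @param grid numeric (or logical for [binary_volume()]) 3D array.
#' @param spacing_mm per-axis voxel size in mm, array-axis order (z, y, x).
#'   A scalar is recycled.
#' @param origin_mm world position of voxel (1,1,1), array-axis order.
#' @return An object of class `voxel_volume` or `binary_volume`.
#' @export
voxel_volume <- function(grid, spacing_mm = 1, origin_mm = c(0, 0, 0)) {
  grid <- as_grid(grid, logical = FALSE)
  if (!all(is.finite(grid))) stop("voxel values must be finite")
  new_volume(grid, spacing_mm, origin_mm, "voxel_volume")
}

#' @rdname voxel_volume
#' @export
binary_volume <- function(grid, spacing_mm = 1, origin_mm = c(0, 0, 0)) {
  grid <- as_grid(grid, logical = TRUE)
  new_volume(grid, spacing_mm, origin_mm, "binary_volume")
}

new_volume <- function(grid, spacing_mm, origin_mm, class) {
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3)
  origin_mm <- rep_len(as.numeric(origin_mm), 3)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("all spacing components must be positive")
  if (any(dim(grid) < 1)) stop("grid must be non-empty")
  structure(list(grid = grid, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = c(class, "volume"))
}

as_grid <- function(grid, logical) {
  if (is.null(dim(grid)) || length(dim(grid)) != 3)
    stop("grid must be a 3D array")
  if (logical) {
    if (!is.logical(grid)) {
      g <- array(as.logical(grid != 0), dim(grid))
      grid <- g
    }
  } else {
    if (!is.numeric(grid)) storage.mode(grid) <- "double"
    if (is.integer(grid)) storage.mode(grid) <- "double"
  }
  grid
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing (z,y,x) = %s mm\n",
              class(x)[1], paste(dim(x$grid), collapse = " x "),
              paste(signif(x$spacing_mm, 4), collapse = ", ")))
  if (inherits(x, "binary_volume"))
    cat(sprintf("  bone fraction %.4f\n", bone_fraction(x)))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$grid)

#' Bone volume fraction (BV/TV) of a binary volume
#' @param vol a `binary_volume`.
#' @return fraction of voxels in the bone (TRUE) phase.
#' @export
bone_fraction <- function(vol) {
  stopifnot(inherits(vol, "binary_volume"))
  mean(vol$grid)
}

#' Convert direction vectors between world (x,y,z) and array (z,y,x) order
#' @param v length-3 numeric vector.
#' @return the reversed vector.
#' @export
xyz_to_arr <- function(v) rev(v)

#' @rdname xyz_to_arr
#' @export
arr_to_xyz <- function(v) rev(v)

# world positions (array order, mm) of 1-based voxel indices (n x 3 matrix)
index_to_mm <- function(vol, idx) {
  sweep(sweep(idx - 1, 2, vol$spacing_mm, "*"), 2, vol$origin_mm, "+")
}

# unit-normalise with zero-length check
unitize <- function(v, what = "vector") {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop(what, " has zero length")
  v / n
}

# Dice overlap of two binary volumes (same grid)
#' Dice similarity coefficient between two binary volumes
#' @param a,b `binary_volume`s on the same grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a$grid), dim(b$grid)))
  2 * sum(a$grid & b$grid) / (sum(a$grid) + sum(b$grid))
}

#' Mirror a volume about its mid-sagittal plane
#'
#' Reflects the world x axis (array axis 3), used to convert left-side
#' elements to right-side geometry before anatomical frame construction.
#' @param vol a volume.
#' @return the reflected volume.
#' @export
mirror_volume <- function(vol) {
  vol$grid <- vol$grid[, , dim(vol$grid)[3]:1, drop = FALSE]
  vol
}

#' Ground truth descriptor for synthetic phantoms
#'
#' @param fabric_axes 3x3 matrix with rows u1, u2, u3 (world xyz), orthonormal.
#' @param fabric_eigenvalues descending positive triple.
#' @param bvtv bone volume fraction in \[0,1\].
#' @param tb_sp_mm nominal trabecular spacing (mm).
#' @param condyle_centers_mm optional 2x3 matrix (medial, lateral; world xyz).
#' @param long_axis optional unit vector (world xyz).
#' @return object of class `phantom_truth`.
#' @export
phantom_truth <- function(fabric_axes = NULL, fabric_eigenvalues = NULL,
                          bvtv = NA_real_, tb_sp_mm = NA_real_,
                          condyle_centers_mm = NULL, long_axis = NULL) {
  if (!is.null(fabric_axes)) {
    stopifnot(is.matrix(fabric_axes), all(dim(fabric_axes) == c(3, 3)))
    gram <- fabric_axes %*% t(fabric_axes)
    if (max(abs(gram - diag(3))) > 1e-8)
      stop("fabric_axes must be orthonormal")
  }
  if (!is.null(fabric_eigenvalues)) {
    stopifnot(length(fabric_eigenvalues) == 3)
    if (any(diff(fabric_eigenvalues) > 0) || any(fabric_eigenvalues <= 0))
      stop("eigenvalues must be positive and descending")
  }
  structure(list(fabric_axes = fabric_axes,
                 fabric_eigenvalues = fabric_eigenvalues,
                 bvtv = bvtv, tb_sp_mm = tb_sp_mm,
                 condyle_centers_mm = condyle_centers_mm,
                 long_axis = long_axis),
            class = "phantom_truth")
}

# complete an orthonormal basis (p, q) perpendicular to unit vector a
perp_basis <- function(a) {
  e <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- unitize(pracma_cross(a, e))
  q <- pracma_cross(a, p)
  rbind(p, q)
}

# plain cross product (kept local; no dependency needed for one line)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# angle in degrees between two axes (antipodally symmetric)
axis_angle_deg <- function(a, b) {
  a <- unitize(a); b <- unitize(b)
  acos(pmin(1, abs(sum(a * b)))) * 180 / pi
}
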