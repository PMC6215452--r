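#' Fabric tensor estimation
#'
#' The directional arrangement of trabeculae in a VOI is summarised by a
#' symmetric positive-definite fabric tensor H. A directional measure v(n) --
#' the star length scale (cube root of the mean cubed intercept length
#' through sampled bone points; the star volume distribution, the default) or
#' the mean intercept length (MIL) -- is sampled over a quasi-uniform set of
#' orientations, an ellipsoid is fitted by least squares to
#' `n' M n = 1 / v(n)^2`, and the fabric tensor is `H = M^(-1/2)`,
#' trace-normalised to 3 so the isotropic fabric is the identity. Its
#' eigenvectors u1, u2, u3 (eigenvalues e1 >= e2 >= e3) are the principal
#' fabric directions, and DA = e1/e3 is the degree of anisotropy.
#'
#' @name fabric
NULL

#' Quasi-uniform direction set
#'
#' A Fibonacci lattice of `n` antipodally unique unit vectors on the upper
#' hemisphere, rigidly rotated by a seeded random rotation (so no direction
#' is systematically aligned with the voxel grid).
#'
#' @param n number of directions (>= 50); 2,049 by default.
#' @param seed integer seed for the random rotation.
#' @return `direction_set`: an n x 3 matrix of world (x, y, z) unit vectors
#'   with the rotation stored as attribute `rotation`.
#' @export
sample_directions <- function(n = 2049, seed = 1) {
  if (n < 50) stop("n must be >= 50")
  i <- seq_len(n)
  z <- (i - 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(1 - z^2)
  dirs <- cbind(rho * cos(phi), rho * sin(phi), z)
  rot <- with_seed(seed, random_rotation())
  dirs <- dirs %*% t(rot)
  structure(dirs, class = c("direction_set", "matrix"),
            rotation = rot, seed = seed)
}

# uniform random rotation from the QR decomposition of a Gaussian matrix
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# bone voxel positions (0-based index * spacing, array order) inside a VOI,
# plus the VOI centre in the same coordinates
voi_bone_points <- function(binary, voi) {
  sp <- binary$spacing_mm
  d <- dim(binary$grid)
  c_arr <- xyz_to_arr(voi$center_mm) - binary$origin_mm
  idx_c <- c_arr / sp + 1
  rng <- lapply(1:3, function(a) {
    lo <- max(1, floor(idx_c[a] - voi$radius_mm / sp[a]))
    hi <- min(d[a], ceiling(idx_c[a] + voi$radius_mm / sp[a]))
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(lengths(rng) == 0)) return(list(points = NULL, center = c_arr))
  sub <- binary$grid[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  g1 <- (rng[[1]] - idx_c[1]) * sp[1]
  g2 <- (rng[[2]] - idx_c[2]) * sp[2]
  g3 <- (rng[[3]] - idx_c[3]) * sp[3]
  inside <- outer(outer(g1^2, g2^2, "+"), g3^2, "+") <= voi$radius_mm^2
  idx <- which(sub & inside, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list(points = NULL, center = c_arr))
  pts <- cbind((rng[[1]][idx[, 1]] - 1) * sp[1],
               (rng[[2]][idx[, 2]] - 1) * sp[2],
               (rng[[3]][idx[, 3]] - 1) * sp[3])
  list(points = pts, center = c_arr)
}

#' Star length sampling (star volume distribution)
#'
#' Samples `n_points` points uniformly within the bone phase of the VOI
#' (with replacement when fewer bone voxels exist) and, for each direction,
#' casts a bidirectional ray from each point, measuring the uninterrupted
#' bone intercept length through it, censored at the VOI sphere boundary.
#'
#' @param binary a [binary_volume()] (segmented scan).
#' @param voi a [sphere_voi()].
#' @param dirs a [sample_directions()] set.
#' @param n_points number of sampled bone points (4,000 by default).
#' @param seed seed for point sampling.
#' @param step_mm ray-march step (default half the smallest voxel side).
#' @return `directional_measure`: data.frame with per-direction `value`
#'   (star length scale, mm), `mean_l`, `mean_l3`, `censored_frac`; the
#'   direction set and method are attached as attributes.
#' @export
star_sample <- function(binary, voi, dirs, n_points = 4000, seed = 1,
                        step_mm = NULL) {
  stopifnot(inherits(binary, "binary_volume"), inherits(voi, "sphere_voi"))
  vb <- voi_bone_points(binary, voi)
  if (is.null(vb$points)) stop("VOI contains no bone phase")
  if (nrow(vb$points) < 10) stop("fewer than 10 bone voxels in VOI")
  if (is.null(step_mm)) step_mm <- 0.5 * min(binary$spacing_mm)
  pick <- with_seed(seed, sample.int(nrow(vb$points), n_points,
                                     replace = nrow(vb$points) < n_points))
  pts <- vb$points[pick, , drop = FALSE]
  dirs_arr <- as.matrix(unclass(dirs))[, 3:1, drop = FALSE]  # xyz -> arr
  res <- cpp_star_sample(binary$grid, binary$spacing_mm, vb$center,
                         voi$radius_mm, dirs_arr, pts, step_mm)
  out <- data.frame(value = res[, 2]^(1 / 3), mean_l = res[, 1],
                    mean_l3 = res[, 2], censored_frac = res[, 3])
  structure(out, class = c("directional_measure", "data.frame"),
            dirs = dirs, method = "svd", n_points = n_points)
}

#' Mean intercept length measurement
#'
#' For each direction, lays a parallel grid of test lines through the VOI
#' sphere and computes MIL = total line length / number of bone--background
#' intersections. Directions whose line grid meets no interface are censored
#' to the VOI diameter and flagged.
#'
#' @inheritParams star_sample
#' @param grid_spacing_mm spacing of the parallel line grid (default three
#'   times the smallest voxel side; must be >= the voxel size). MIL is a
#'   ratio of totals pooled over the whole grid, so a moderate line density
#'   suffices.
#' @return `directional_measure` with per-direction `value` (MIL, mm),
#'   `crossings`, `censored` flag.
#' @export
mil_measure <- function(binary, voi, dirs, grid_spacing_mm = NULL,
                        step_mm = NULL) {
  stopifnot(inherits(binary, "binary_volume"), inherits(voi, "sphere_voi"))
  spmin <- min(binary$spacing_mm)
  if (is.null(grid_spacing_mm)) grid_spacing_mm <- 3 * spmin
  if (grid_spacing_mm < spmin) stop("grid_spacing_mm must be >= voxel size")
  if (is.null(step_mm)) step_mm <- spmin
  c_arr <- xyz_to_arr(voi$center_mm) - binary$origin_mm
  dirs_arr <- as.matrix(unclass(dirs))[, 3:1, drop = FALSE]
  res <- cpp_mil(binary$grid, binary$spacing_mm, c_arr, voi$radius_mm,
                 dirs_arr, grid_spacing_mm, step_mm)
  censored <- res[, 2] == 0
  mil <- ifelse(censored, 2 * voi$radius_mm, res[, 1] / pmax(res[, 2], 1))
  out <- data.frame(value = mil, crossings = res[, 2],
                    bone_length = res[, 3], censored = censored)
  structure(out, class = c("directional_measure", "data.frame"),
            dirs = dirs, method = "mil")
}

#' Fit a fabric tensor to a directional measure
#'
#' Least-squares fit of the quadric `n' M n = 1 / v(n)^2` to the directional
#' values, fabric tensor `H = M^(-1/2)` trace-normalised to 3,
#' eigen-decomposition sorted descending. Each eigenvector is flipped so its
#' largest-magnitude component is positive (fabric directions are axes; the
#' sign carries no meaning), making repeated runs sign-stable.
#'
#' @param measure a `directional_measure` from [star_sample()] or
#'   [mil_measure()].
#' @return `fabric_result`: list with `tensor` (3x3, trace 3), `evals`
#'   (e1 >= e2 >= e3), `evecs` (3x3, rows u1, u2, u3, world xyz), `DA`,
#'   `method`, `n_directions`.
#' @export
fit_fabric_tensor <- function(measure) {
  dirs <- attr(measure, "dirs")
  v <- measure$value
  if (is.null(dirs) || nrow(dirs) < 6)
    stop("at least 6 independent directions are required")
  if (any(!is.finite(v)) || any(v <= 0))
    stop("directional values must be positive and finite")
  n <- as.matrix(unclass(dirs))
  A <- cbind(n[, 1]^2, n[, 2]^2, n[, 3]^2,
             2 * n[, 1] * n[, 2], 2 * n[, 1] * n[, 3], 2 * n[, 2] * n[, 3])
  b <- 1 / v^2
  m <- qr.solve(A, b)
  M <- matrix(c(m[1], m[4], m[5],
                m[4], m[2], m[6],
                m[5], m[6], m[3]), 3, 3)
  eM <- eigen(M, symmetric = TRUE)
  if (any(eM$values <= 0)) {
    worst <- order(abs(A %*% m - b), decreasing = TRUE)[1:5]
    stop("fitted quadric is not positive definite; ",
         "largest residuals at directions ",
         paste(worst, collapse = ", "))
  }
  evals <- eM$values^(-1 / 2)            # H = M^(-1/2)
  ord <- order(evals, decreasing = TRUE)
  evals <- evals[ord]
  evecs <- eM$vectors[, ord, drop = FALSE]
  scale <- 3 / sum(evals)
  evals <- evals * scale
  # sign convention: largest-magnitude component positive
  for (i in 1:3) {
    j <- which.max(abs(evecs[, i]))
    if (evecs[j, i] < 0) evecs[, i] <- -evecs[, i]
  }
  H <- evecs %*% diag(evals) %*% t(evecs)
  structure(list(tensor = H, evals = evals, evecs = t(evecs),
                 DA = evals[1] / evals[3],
                 method = attr(measure, "method"),
                 n_directions = nrow(dirs)),
            class = "fabric_result")
}

#' @export
print.fabric_result <- function(x, ...) {
  cat(sprintf("<fabric_result> method %s, DA = %.3f\n", x$method, x$DA))
  cat(sprintf("  e = (%.3f, %.3f, %.3f)\n",
              x$evals[1], x$evals[2], x$evals[3]))
  cat(sprintf("  u1 = (% .3f, % .3f, % .3f)\n",
              x$evecs[1, 1], x$evecs[1, 2], x$evecs[1, 3]))
  invisible(x)
}

#' Fabric of one VOI
#'
#' Convenience wrapper: directional measurement (star volume distribution or
#' MIL) followed by the tensor fit.
#'
#' @inheritParams star_sample
#' @param method `"svd"` (star volume distribution, default) or `"mil"`.
#' @param n_directions size of the direction set.
#' @param ... passed to [star_sample()] or [mil_measure()].
#' @return a `fabric_result`.
#' @export
fabric_voi <- function(binary, voi, method = c("svd", "mil"),
                       n_directions = 2049, n_points = 4000, seed = 1, ...) {
  method <- match.arg(method)
  dirs <- sample_directions(n_directions, seed = seed)
  m <- if (method == "svd")
    star_sample(binary, voi, dirs, n_points = n_points, seed = seed, ...)
  else
    mil_measure(binary, voi, dirs, ...)
  fit_fabric_tensor(m)
}

#' Batch fabric analysis over a VOI set
#'
#' One fabric tensor per VOI; per-VOI failures are recorded without aborting
#' the batch.
#'
#' @param binary a [binary_volume()].
#' @param vois a `voi_set` from [ccp_pack()].
#' @param method,n_directions,n_points,seed see [fabric_voi()].
#' @param ... passed to the measurement routine.
#' @return data.frame with one row per VOI: centre, e1-e3, DA, eigenvector
#'   components (world xyz), method, `ok` flag and error message.
#' @export
batch_fabric <- function(binary, vois, method = c("svd", "mil"),
                         n_directions = 2049, n_points = 4000, seed = 1,
                         ...) {
  method <- match.arg(method)
  dirs <- sample_directions(n_directions, seed = seed)
  rows <- lapply(seq_len(nrow(vois)), function(s) {
    voi <- sphere_voi(c(vois$cx[s], vois$cy[s], vois$cz[s]),
                      vois$radius_mm[s])
    base <- data.frame(id = vois$id[s], cx = voi$center_mm[1],
                       cy = voi$center_mm[2], cz = voi$center_mm[3],
                       radius_mm = voi$radius_mm)
    fr <- tryCatch({
      m <- if (method == "svd")
        star_sample(binary, voi, dirs, n_points = n_points,
                    seed = seed + s, ...)
      else mil_measure(binary, voi, dirs, ...)
      fit_fabric_tensor(m)
    }, error = function(e) e)
    if (inherits(fr, "error")) {
      cbind(base, data.frame(e1 = NA, e2 = NA, e3 = NA, DA = NA,
                             u1x = NA, u1y = NA, u1z = NA,
                             u2x = NA, u2y = NA, u2z = NA,
                             u3x = NA, u3y = NA, u3z = NA,
                             method = method, ok = FALSE,
                             error = conditionMessage(fr)))
    } else {
      cbind(base, data.frame(e1 = fr$evals[1], e2 = fr$evals[2],
                             e3 = fr$evals[3], DA = fr$DA,
                             u1x = fr$evecs[1, 1], u1y = fr$evecs[1, 2],
                             u1z = fr$evecs[1, 3],
                             u2x = fr$evecs[2, 1], u2y = fr$evecs[2, 2],
                             u2z = fr$evecs[2, 3],
                             u3x = fr$evecs[3, 1], u3y = fr$evecs[3, 2],
                             u3z = fr$evecs[3, 3],
                             method = method, ok = TRUE, error = ""))
    }
  })
  do.call(rbind, rows)
}
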