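#' Anatomical referencing of fabric directions
#'
#' A femoral anatomical coordinate system is built from the principal axis of
#' inertia of the whole bone (the long axis; +z proximal) and the centres of
#' two spheres fitted to the distal condyles: +y (anterior) is the normalised
#' cross product of z with the medial-to-lateral condyle vector, and
#' +x (lateral) completes the right-handed frame (x = y x z). Left bones are
#' mirrored about their sagittal plane before frame construction, so left and
#' right elements yield directly comparable angles. Mean fabric directions
#' are the antipodally normalised vectorial mean of per-VOI primary fabric
#' axes, reported as anterior/medial inclination angles and as equal-angle
#' (Wulff) stereographic coordinates.
#'
#' @name anatomy
NULL

#' Principal (long) axis of a bone
#'
#' Eigenvector of the inertia tensor of the geometry with the smallest
#' moment, i.e. the long axis, with its sign oriented towards a
#' caller-supplied proximal hint point.
#'
#' @param geometry a [binary_volume()] (voxel point cloud) or an n x 3 matrix
#'   of world (x, y, z) surface points in mm.
#' @param proximal_hint_mm world point known to lie proximally; resolves the
#'   sign of the axis.
#' @return unit vector, world (x, y, z).
#' @export
principal_axis <- function(geometry, proximal_hint_mm = c(0, 0, 1e6)) {
  if (inherits(geometry, "binary_volume")) {
    idx <- which(geometry$grid, arr.ind = TRUE)
    pos <- index_to_mm(geometry, idx)
    pts <- pos[, c(3, 2, 1), drop = FALSE]        # array (z,y,x) -> xyz
  } else {
    pts <- as.matrix(geometry)
    stopifnot(ncol(pts) == 3)
  }
  ctr <- colMeans(pts)
  pc <- sweep(pts, 2, ctr)
  cov3 <- crossprod(pc) / nrow(pc)
  # inertia tensor: I = trace(C) Id - C; its smallest moment corresponds to
  # the largest covariance eigenvalue
  ei <- eigen(cov3, symmetric = TRUE)
  moments <- sum(ei$values) - ei$values   # ascending; smallest = long axis
  if ((moments[2] - moments[1]) < 0.01 * max(abs(moments)))
    stop("inertia moments nearly degenerate: supply the long axis manually")
  ax <- ei$vectors[, 1]
  if (sum(ax * (proximal_hint_mm - ctr)) < 0) ax <- -ax
  unitize(ax)
}

#' Least-squares sphere fit
#'
#' Algebraic (linear) fit followed by Gauss-Newton geometric refinement.
#'
#' @param points n x 3 matrix (n >= 4) of world (x, y, z) points, not
#'   coplanar.
#' @return list with `center`, `radius`, `rms_residual`.
#' @export
fit_sphere <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 4) stop("at least 4 points are required")
  A <- cbind(2 * pts, 1)
  if (qr(A)$rank < 4)
    stop("points are coplanar or otherwise ill-conditioned")
  b <- rowSums(pts^2)
  sol <- qr.solve(A, b)
  ctr <- sol[1:3]
  r <- sqrt(sol[4] + sum(ctr^2))
  # geometric refinement: minimise sum (|p - c| - r)^2
  for (it in 1:20) {
    dv <- sweep(pts, 2, ctr)
    dist <- sqrt(rowSums(dv^2))
    res <- dist - r
    J <- cbind(-dv / dist, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 4))
    ctr <- ctr + step[1:3]
    r <- r + step[4]
    if (max(abs(step)) < 1e-12) break
  }
  dist <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  list(center = unname(ctr), radius = unname(r),
       rms_residual = sqrt(mean((dist - r)^2)))
}

#' Build the femoral anatomical frame
#'
#' @param long_axis unit long axis (+ proximal), world (x, y, z).
#' @param medial_center,lateral_center condyle sphere centres, world mm.
#' @param side `"right"` or `"left"`; left geometry is mirrored about the
#'   bone's sagittal plane (the plane spanned by the long axis and the
#'   anterior axis) before construction, so use [express_in_frame()] to
#'   reference fabric axes measured on the original left geometry.
#' @return `anatomical_frame`: list with orthonormal right-handed rows
#'   `x_axis` (+lateral), `y_axis` (+anterior), `z_axis` (+proximal),
#'   `origin_mm` (condyle midpoint), `side`, and `mirror_normal` (unit normal
#'   of the mirroring plane, NULL for right bones).
#' @export
build_frame <- function(long_axis, medial_center, lateral_center,
                        side = c("right", "left")) {
  side <- match.arg(side)
  z <- unitize(long_axis, "long_axis")
  cvec <- as.numeric(lateral_center) - as.numeric(medial_center)
  if (sqrt(sum(cvec^2)) < 1e-12) stop("condyle centres must be distinct")
  if (axis_angle_deg(z, cvec) < 1e-6)
    stop("long axis is parallel to the condyle vector")
  mirror_normal <- NULL
  if (side == "left") {
    # sagittal-plane normal: condyle vector component perpendicular to z
    mn <- unitize(cvec - sum(cvec * z) * z)
    cvec <- cvec - 2 * sum(cvec * mn) * mn
    mirror_normal <- mn
  }
  y <- unitize(pracma_cross(z, cvec))
  x <- pracma_cross(y, z)
  structure(list(x_axis = x, y_axis = y, z_axis = z,
                 origin_mm = (as.numeric(medial_center) +
                                as.numeric(lateral_center)) / 2,
                 side = side, mirror_normal = mirror_normal),
            class = "anatomical_frame")
}

#' Express a world vector in an anatomical frame
#'
#' Returns the (x = lateral, y = anterior, z = proximal) components. For
#' left-side frames the vector is first mirrored about the bone's sagittal
#' plane, matching the mirroring applied to the geometry.
#'
#' @param v world (x, y, z) vector.
#' @param frame an [build_frame()] result.
#' @return length-3 numeric vector of frame components.
#' @export
express_in_frame <- function(v, frame) {
  v <- as.numeric(v)
  if (!is.null(frame$mirror_normal))
    v <- v - 2 * sum(v * frame$mirror_normal) * frame$mirror_normal
  c(sum(v * frame$x_axis), sum(v * frame$y_axis), sum(v * frame$z_axis))
}

#' Vectorial mean of fabric axes
#'
#' Fabric directions are axes (sign-free), so each vector is first flipped
#' into the hemisphere of the running resultant, then a second pass re-aligns
#' every axis to the first-pass mean (removing order dependence) before the
#' normalised vector sum is taken.
#'
#' @param vectors n x 3 matrix of unit axes (world xyz, or frame components).
#' @param frame optional [build_frame()]; if given, axes are expressed in it
#'   first.
#' @return `mean_direction`: list with unit `axis` (flipped into the +z
#'   hemisphere), resultant length `r_bar` in \[0, 1\], and `n`.
#' @export
axial_mean <- function(vectors, frame = NULL) {
  m <- as.matrix(vectors)
  if (nrow(m) < 1) stop("at least one vector is required")
  if (!is.null(frame))
    m <- t(apply(m, 1, express_in_frame, frame = frame))
  m <- m / sqrt(rowSums(m^2))
  resultant <- m[1, ]
  for (i in seq_len(nrow(m))[-1]) {
    s <- if (sum(m[i, ] * resultant) < 0) -1 else 1
    resultant <- resultant + s * m[i, ]
  }
  # second pass: align all axes to the first-pass mean
  ref <- resultant / sqrt(sum(resultant^2))
  signs <- sign(m %*% ref)
  signs[signs == 0] <- 1
  total <- colSums(m * as.numeric(signs))
  r <- sqrt(sum(total^2))
  if (r < 1e-9 * nrow(m))
    stop("degenerate axis set: zero resultant")
  axis <- total / r
  # antipodal normalisation into the +z hemisphere
  if (axis[3] < 0 || (axis[3] == 0 && (axis[2] < 0 ||
                                       (axis[2] == 0 && axis[1] < 0))))
    axis <- -axis
  structure(list(axis = axis, r_bar = r / nrow(m), n = nrow(m)),
            class = "mean_direction")
}

#' Inclination angles of a mean fabric direction
#'
#' Anterior inclination: signed angle between +z (proximal) and the
#' projection of the axis onto the sagittal (y-z) plane, positive anteriorly.
#' Medial inclination: the analogue in the coronal (x-z) plane, positive
#' medially (towards -x).
#'
#' @param dir a `mean_direction` (components already in the anatomical
#'   frame) or a length-3 frame-component vector.
#' @param frame optional [build_frame()]; if given, `dir` is taken as a
#'   world vector and expressed in the frame first.
#' @return named vector `c(anterior_incl_deg, medial_incl_deg)`.
#' @export
inclination_angles <- function(dir, frame = NULL) {
  v <- if (inherits(dir, "mean_direction")) dir$axis else as.numeric(dir)
  if (!is.null(frame)) v <- express_in_frame(v, frame)
  v <- unitize(v)
  if (v[3] < 0) v <- -v                    # proximal-pointing representative
  if (abs(v[2]) < 1e-12 && abs(v[3]) < 1e-12)
    stop("axis lies in the transverse plane: anterior inclination undefined")
  if (abs(v[1]) < 1e-12 && abs(v[3]) < 1e-12)
    stop("axis lies in the transverse plane: medial inclination undefined")
  c(anterior_incl_deg = atan2(v[2], v[3]) * 180 / pi,
    medial_incl_deg = atan2(-v[1], v[3]) * 180 / pi)
}

#' Equal-angle (Wulff) stereographic projection
#'
#' Projects a unit axis onto the unit disc: radius `tan(theta / 2)` with
#' `theta` the angle from the chosen pole, azimuth preserved. The axis is
#' first flipped into the chosen hemisphere, so every axis maps inside the
#' disc.
#'
#' @param axis unit vector (frame or world components).
#' @param hemisphere `"north"` (+z pole) or `"south"` (-z pole).
#' @return `stereo_point`: list with `x`, `y` in the unit disc and
#'   `hemisphere`.
#' @export
stereo_project <- function(axis, hemisphere = c("north", "south")) {
  hemisphere <- match.arg(hemisphere)
  v <- unitize(as.numeric(axis))
  pole_z <- if (hemisphere == "north") 1 else -1
  if (v[3] * pole_z < 0) v <- -v
  theta <- acos(pmin(1, abs(v[3])))
  r <- tan(theta / 2)
  rho <- sqrt(v[1]^2 + v[2]^2)
  if (rho < 1e-15) {
    xy <- c(0, 0)
  } else {
    xy <- r * c(v[1], v[2]) / rho
  }
  structure(list(x = xy[1], y = xy[2], hemisphere = hemisphere),
            class = "stereo_point")
}

#' Inverse equal-angle projection
#'
#' @param pt a `stereo_point` (or list with `x`, `y`, `hemisphere`).
#' @return unit axis in the chosen hemisphere.
#' @export
stereo_unproject <- function(pt) {
  r <- sqrt(pt$x^2 + pt$y^2)
  theta <- 2 * atan(r)
  pole_z <- if (identical(pt$hemisphere, "south")) -1 else 1
  if (r < 1e-15) return(c(0, 0, pole_z))
  c(sin(theta) * pt$x / r, sin(theta) * pt$y / r, pole_z * cos(theta))
}
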