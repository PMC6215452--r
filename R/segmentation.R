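#' CT segmentation protocols
#'
#' Four segmentation protocols for extracting the cancellous bone phase from
#' greyscale CT stacks, differing by scan quality:
#' \describe{
#'   \item{1}{Bernsen local thresholding + floating-voxel removal (clean
#'     micro-CT).}
#'   \item{2}{Isotropic cubic upsampling (in-plane factor 3, axial factor
#'     `3 f` with `f` = slice thickness / pixel resolution), then protocol 1
#'     (anisotropic medical CT).}
#'   \item{3}{In-plane-only resampling to isotropic voxels, low-radius 3D
#'     median denoising, then protocol 1.}
#'   \item{4}{Median-filter background subtraction (low-radius 3D median
#'     minus chained large-radius 2D medians), low-radius 3D mean smoothing,
#'     then a global high-pass threshold (noisy scans of dense specimens).}
#' }
#' @name segmentation
NULL

#' Resampling specification
#'
#' Captures the anisotropy ratio `f = slice_thickness / pixel_resolution` and
#' the in-plane upsampling multiplier. The axial axis is resampled by
#' `upsample_multiplier * f` so that output voxels are isotropic cubes of
#' side `pixel_resolution / upsample_multiplier`.
#'
#' @param pixel_resolution_mm in-plane pixel size.
#' @param slice_thickness_mm axial slice thickness.
#' @param upsample_multiplier in-plane upsampling factor (default 3).
#' @return object of class `resample_spec` with the derived factor `f`.
#' @export
resample_spec <- function(pixel_resolution_mm, slice_thickness_mm,
                          upsample_multiplier = 3) {
  stopifnot(pixel_resolution_mm > 0, slice_thickness_mm > 0,
            upsample_multiplier >= 1)
  f <- slice_thickness_mm / pixel_resolution_mm
  structure(list(pixel_resolution_mm = pixel_resolution_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 f = f, upsample_multiplier = upsample_multiplier),
            class = "resample_spec")
}

#' Bernsen local thresholding
#'
#' A voxel is bone iff the local contrast (max - min over a ball window of
#' `window_radius_px`) reaches `contrast_threshold` AND its value exceeds the
#' local mid-grey `(max + min) / 2`. Voxels in low-contrast windows are
#' assigned to the background: with the contrast threshold set fairly high,
#' this keeps uniform dense non-bone material (e.g. dried marrow) out of the
#' bone phase.
#'
#' @param vol a [voxel_volume()].
#' @param window_radius_px window radius in voxels (>= 1).
#' @param contrast_threshold minimum local max - min contrast.
#' @return a [binary_volume()].
#' @export
bernsen_threshold <- function(vol, window_radius_px = 5,
                              contrast_threshold = 30) {
  stopifnot(inherits(vol, "voxel_volume"), window_radius_px >= 1)
  if (!all(is.finite(vol$grid))) stop("input contains non-finite voxels")
  mm <- cpp_minmax_filter(vol$grid, as.integer(window_radius_px))
  contrast <- mm$max - mm$min
  mid <- (mm$max + mm$min) / 2
  bone <- contrast >= contrast_threshold & vol$grid > mid
  binary_volume(bone, vol$spacing_mm, vol$origin_mm)
}

#' Remove floating voxels
#'
#' Keeps only the largest 26-connected foreground component; cancellous bone
#' forms a single connected network, so disconnected fragments are
#' segmentation noise. Never adds voxels.
#'
#' @param binary a [binary_volume()].
#' @return a [binary_volume()] containing the largest component.
#' @export
remove_floating <- function(binary) {
  stopifnot(inherits(binary, "binary_volume"))
  if (!any(binary$grid)) stop("empty foreground: nothing to keep")
  binary_volume(cpp_largest_component(binary$grid),
                binary$spacing_mm, binary$origin_mm)
}

#' Resample a stack to isotropic voxels
#'
#' In-plane axes are upsampled by `upsample_multiplier`, the axial (slice)
#' axis by `upsample_multiplier * f`, using separable cubic-convolution
#' interpolation for greyscale (nearest neighbour for binary masks). When
#' `f < 1` (slices thinner than pixels), only the in-plane axes are resampled
#' to match the slice thickness, per the protocol-3 branch.
#'
#' @param vol a [voxel_volume()] or [binary_volume()].
#' @param spec a [resample_spec()].
#' @return a resampled volume with isotropic spacing.
#' @export
resample_isotropic <- function(vol, spec) {
  stopifnot(inherits(spec, "resample_spec"))
  m <- spec$upsample_multiplier
  if (spec$f >= 1) {
    factor <- c(m * spec$f, m, m)        # (axial, row, col)
    out_spacing <- rep(spec$pixel_resolution_mm / m, 3)
  } else {
    # in-plane-only branch: make voxels isotropic at the slice thickness
    factor <- c(1, 1 / spec$f, 1 / spec$f)
    out_spacing <- rep(spec$slice_thickness_mm, 3)
  }
  d <- dim(vol$grid)
  out_dim <- as.integer(pmax(1, round((d - 1) * factor) + 1))
  nearest <- inherits(vol, "binary_volume")
  g <- cpp_resample(vol$grid + 0, out_dim, factor, nearest)
  if (nearest)
    binary_volume(g > 0.5, out_spacing, vol$origin_mm)
  else
    voxel_volume(g, out_spacing, vol$origin_mm)
}

#' Median-filter background subtraction
#'
#' High-frequency denoised stack (low-radius 3D median) minus the
#' low-frequency background (large-radius 2D median chained over all three
#' slice orientations), clipped at zero. Removes both impulse noise and
#' slowly varying background such as beam hardening.
#'
#' @param vol a [voxel_volume()].
#' @param small_radius_px radius of the 3D median (2-10 px typical).
#' @param large_radius_px radius of the 2D background medians (10-40 px
#'   typical; must exceed `small_radius_px` and be large relative to the
#'   trabecular thickness).
#' @return a [voxel_volume()] of non-negative values.
#' @export
background_subtract <- function(vol, small_radius_px = 2,
                                large_radius_px = 12) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (small_radius_px >= large_radius_px)
    stop("small_radius_px must be < large_radius_px")
  if (2 * large_radius_px + 1 > max(dim(vol$grid)))
    stop("background median radius exceeds the volume extent")
  hi <- cpp_median_filter(vol$grid, as.integer(small_radius_px), 0L)
  lo <- vol$grid
  for (ax in 1:3)
    lo <- cpp_median_filter(lo, as.integer(large_radius_px), ax)
  g <- pmax(hi - lo, 0)
  dim(g) <- dim(vol$grid)
  voxel_volume(g, vol$spacing_mm, vol$origin_mm)
}

#' Protocol parameter specification
#'
#' @param protocol protocol id, 1-4.
#' @param window_radius_px,contrast_threshold Bernsen parameters
#'   (protocols 1-3).
#' @param resample a [resample_spec()] (protocols 2-3; NULL if the input is
#'   already isotropic).
#' @param median3d_radius_px denoising median radius (protocol 3).
#' @param small_median_radius_px,large_median_radius_px background
#'   subtraction radii (protocol 4).
#' @param mean3d_radius_px final mean-filter radius (protocol 4).
#' @param global_threshold high-pass grey threshold after background
#'   subtraction and smoothing (protocol 4); on the near-zero background of
#'   subtracted stacks a small value suffices, scaled to the expected bone
#'   grey value.
#' @return object of class `protocol_spec`.
#' @export
protocol_spec <- function(protocol, window_radius_px = 5,
                          contrast_threshold = 30, resample = NULL,
                          median3d_radius_px = 2,
                          small_median_radius_px = 2,
                          large_median_radius_px = 12,
                          mean3d_radius_px = 2, global_threshold = 2) {
  if (!protocol %in% 1:4)
    stop("protocol must be 1-4 (protocol 5 is qualitative-only)")
  stopifnot(window_radius_px >= 1, contrast_threshold >= 0,
            global_threshold >= 0)
  structure(list(protocol = protocol, window_radius_px = window_radius_px,
                 contrast_threshold = contrast_threshold,
                 resample = resample,
                 median3d_radius_px = median3d_radius_px,
                 small_median_radius_px = small_median_radius_px,
                 large_median_radius_px = large_median_radius_px,
                 mean3d_radius_px = mean3d_radius_px,
                 global_threshold = global_threshold),
            class = "protocol_spec")
}

#' Run a segmentation protocol
#'
#' Executes the stage sequence of the chosen protocol (see [segmentation])
#' and finishes with [remove_floating()].
#'
#' @param vol a [voxel_volume()].
#' @param spec a [protocol_spec()].
#' @param mask optional [binary_volume()]; voxels outside it are forced to
#'   background before component cleaning.
#' @return a [binary_volume()].
#' @export
run_protocol <- function(vol, spec, mask = NULL) {
  stopifnot(inherits(spec, "protocol_spec"))
  p <- spec$protocol
  if (p == 2 && !is.null(spec$resample))
    vol <- resample_isotropic(vol, spec$resample)
  if (p == 3) {
    if (!is.null(spec$resample) && abs(spec$resample$f - 1) > 1e-12) {
      # in-plane-only resampling to isotropic voxels at the slice thickness
      f <- spec$resample$f
      factor <- c(1, 1 / f, 1 / f)
      d <- dim(vol$grid)
      out_dim <- as.integer(pmax(1, round((d - 1) * factor) + 1))
      g <- cpp_resample(vol$grid, out_dim, factor, FALSE)
      vol <- voxel_volume(g, rep(spec$resample$slice_thickness_mm, 3),
                          vol$origin_mm)
    }
    g <- cpp_median_filter(vol$grid, as.integer(spec$median3d_radius_px), 0L)
    vol <- voxel_volume(g, vol$spacing_mm, vol$origin_mm)
  }
  if (p %in% 1:3) {
    seg <- bernsen_threshold(vol, spec$window_radius_px,
                             spec$contrast_threshold)
  } else {
    bs <- background_subtract(vol, spec$small_median_radius_px,
                              spec$large_median_radius_px)
    sm <- cpp_mean_filter(bs$grid, as.integer(spec$mean3d_radius_px))
    seg <- binary_volume(sm > spec$global_threshold,
                         vol$spacing_mm, vol$origin_mm)
  }
  if (!is.null(mask)) seg$grid <- seg$grid & mask$grid
  if (!any(seg$grid)) return(seg)      # nothing segmented: empty, no cleaning
  remove_floating(seg)
}
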