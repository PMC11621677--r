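#' Re-project depth pixels into 3D camera coordinates
#'
#' Pinhole back-projection: a pixel at (row = v, col = u) with depth d
#' maps to X = (u - cx) d / fx, Y = (v - cy) d / fy, Z = d. Pixels with
#' invalid (zero) depth are skipped. The camera frame serves as the world
#' frame: container volume is rigid-motion invariant, so with a single
#' uncalibrated wearable camera the choice is immaterial.
#'
#' @param depth A \linkS4class{DepthFrame}.
#' @param pixel_subset Optional integer matrix of 0-based (row, col)
#'   pixels to re-project; default all pixels.
#' @return Numeric matrix with columns X, Y, Z in metres.
#' @export
reproject <- function(depth, pixel_subset = NULL) {
  k <- frameIntrinsics(depth)
  dm <- depthMatrix(depth)
  if (is.null(pixel_subset)) {
    idx <- which(dm > 0, arr.ind = TRUE)
    v <- idx[, 1] - 1L; u <- idx[, 2] - 1L
  } else {
    v <- pixel_subset[, 1]; u <- pixel_subset[, 2]
    if (any(v < 0) || any(v >= k@height) || any(u < 0) || any(u >= k@width))
      stop("pixel subset outside image bounds")
    keep <- dm[cbind(v + 1L, u + 1L)] > 0
    v <- v[keep]; u <- u[keep]
  }
  if (!length(v)) stop("no valid depth pixels to re-project")
  d <- dm[cbind(v + 1L, u + 1L)]
  cbind(X = (u - k@cx) * d / k@fx, Y = (v - k@cy) * d / k@fy, Z = d)
}

#' Forward-project 3D points to pixel coordinates
#'
#' The inverse of \code{\link{reproject}}; mainly useful for building
#' synthetic scenes and for verifying the back-projection.
#'
#' @param points Matrix with columns X, Y, Z (metres), Z > 0.
#' @param intrinsics A \linkS4class{CameraIntrinsics}.
#' @return Data frame with (possibly fractional) \code{row}, \code{col}
#'   and \code{depth}.
#' @export
forwardProject <- function(points, intrinsics) {
  stopifnot(all(points[, 3] > 0))
  data.frame(
    row = points[, 2] * intrinsics@fy / points[, 3] + intrinsics@cy,
    col = points[, 1] * intrinsics@fx / points[, 3] + intrinsics@cx,
    depth = points[, 3])
}

#' Convex-hull volume of a point cloud
#'
#' Volume of the 3D convex hull (the smallest convex set containing all
#' points), in cm^3. Duplicate points are removed before hull
#' construction; the hull is exact for clouds up to about 1e5 points.
#'
#' @param cloud Numeric matrix with columns X, Y, Z in metres; at least 4
#'   non-coplanar points.
#' @return Volume in cm^3.
#' @export
hullVolume <- function(cloud) {
  cloud <- unique(cloud)
  if (!is.matrix(cloud) || ncol(cloud) != 3L)
    stop("cloud must be an n x 3 matrix")
  if (nrow(cloud) < 4L)
    stop("degenerate geometry: need at least 4 distinct points")
  .hull_volume_cpp(cloud) * 1e6
}

#' Container volume from a depth frame and container mask
#'
#' Re-projects the container's mask pixels to a point cloud and returns
#' the convex-hull volume. All valid-depth mask pixels are used.
#'
#' @param depth A \linkS4class{DepthFrame}.
#' @param container_mask An \linkS4class{InstanceMask} of the container.
#' @return Raw volume in cm^3.
#' @export
containerVolume <- function(depth, container_mask) {
  tryCatch(
    hullVolume(reproject(depth, maskPixels(container_mask))),
    error = function(e)
      stop("frame ", depth@frameId, ": ", conditionMessage(e),
           call. = FALSE))
}

#' Average volume over frames
#'
#' Averaging the per-frame volume estimates of the same container reduces
#' the variance of the final estimate.
#'
#' @param estimates Numeric vector of raw volumes (cm^3).
#' @return Arithmetic mean.
#' @export
averageVolume <- function(estimates) {
  if (!length(estimates)) stop("no volume estimates to average")
  mean(estimates)
}

#' Bin a raw volume into the categorical VC feature
#'
#' Rounds to the nearest positive multiple of 200 cm^3 (a coarse
#' tiny/small/medium/large container-size indication). Ties at odd
#' multiples of 100 round up, and inputs below 100 take the floor
#' category of 200 so no zero-volume category exists.
#'
#' @param raw_cm3 Raw volume(s) in cm^3, >= 0.
#' @return Categorical volume(s): positive multiples of 200.
#' @examples
#' categorizeVolume(c(240, 375, 300))  # 200 400 400
#' @export
categorizeVolume <- function(raw_cm3) {
  if (any(raw_cm3 < 0)) stop("volume must be non-negative")
  pmax(200, 200 * floor(raw_cm3 / 200 + 0.5))
}
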