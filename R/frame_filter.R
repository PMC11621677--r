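#' Edge-region configuration for frame filtering
#'
#' Frames whose container mask substantially overlaps a band along the
#' image border are treated as showing an incomplete (clipped) container.
#' The band width is \code{band_fraction * min(width, height)} pixels
#' (rounded), making the rule resolution-independent across typical
#' wearable-camera formats (640x480, 1280x720).
#'
#' @param band_fraction Border band width as a fraction of the shorter
#'   image side; in (0, 0.5).
#' @param overlap_threshold Maximum tolerated fraction of container-mask
#'   pixels inside the band; in [0, 1).
#' @return Config list used by \code{\link{classifyFrame}}.
#' @export
edgeRegionConfig <- function(band_fraction = 0.02, overlap_threshold = 0.01) {
  if (!(band_fraction > 0 && band_fraction < 0.5))
    stop("band_fraction must lie in (0, 0.5)")
  if (!(overlap_threshold >= 0 && overlap_threshold < 1))
    stop("overlap_threshold must lie in [0, 1)")
  structure(list(band_fraction = band_fraction,
                 overlap_threshold = overlap_threshold),
            class = "EdgeRegionConfig")
}

#' Fraction of a mask inside the image-border band
#'
#' @param mask An \linkS4class{InstanceMask}.
#' @param image_size \code{c(width, height)} in pixels.
#' @param band_fraction Band width as a fraction of the shorter side.
#' @return Fraction of mask pixels within \code{band_width} of any image
#'   border, in [0, 1]. A degenerate band (width rounds to 0) returns 0
#'   with a warning.
#' @export
overlapFraction <- function(mask, image_size, band_fraction) {
  w <- image_size[1]; h <- image_size[2]
  bw <- round(band_fraction * min(w, h))
  if (bw == 0) {
    warning("edge band width rounds to 0 pixels; overlap is 0 by convention")
    return(0)
  }
  p <- maskPixels(mask)
  inband <- p[, "row"] < bw | p[, "row"] >= h - bw |
            p[, "col"] < bw | p[, "col"] >= w - bw
  mean(inband)
}

#' Classify a frame by container completeness
#'
#' \code{without_container} when no container instance is present;
#' \code{incomplete_container} when any container instance has more than
#' \code{overlap_threshold} of its pixels inside the border band (a
#' complete container never hugs the image edge, so sustained border
#' contact signals clipping); otherwise \code{with_container}. Portion
#' features are only meaningful on \code{with_container} frames.
#'
#' @param frame_masks List of \linkS4class{InstanceMask} belonging to one
#'   frame.
#' @param image_size \code{c(width, height)} in pixels.
#' @param config An \code{\link{edgeRegionConfig}}.
#' @return One of \code{"with_container"}, \code{"incomplete_container"},
#'   \code{"without_container"}.
#' @export
classifyFrame <- function(frame_masks, image_size,
                          config = edgeRegionConfig()) {
  stopifnot(inherits(config, "EdgeRegionConfig"))
  w <- image_size[1]; h <- image_size[2]
  for (m in frame_masks) {
    p <- maskPixels(m)
    if (any(p[, "row"] >= h) || any(p[, "col"] >= w))
      stop("mask '", maskCategory(m), "' in frame ", maskFrameId(m),
           " has pixels outside the ", w, "x", h, " image")
  }
  containers <- Filter(function(m) maskCategory(m) == "container",
                       frame_masks)
  if (!length(containers)) return("without_container")
  fr <- vapply(containers, overlapFraction, numeric(1),
               image_size = image_size,
               band_fraction = config$band_fraction)
  if (any(fr > config$overlap_threshold)) "incomplete_container"
  else "with_container"
}
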