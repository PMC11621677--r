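#' Camera intrinsic parameters
#'
#' Pinhole-camera intrinsics used to re-project depth pixels into 3D camera
#' coordinates. Focal lengths and the principal point are in pixels.
#'
#' @slot fx,fy Focal lengths in pixels (> 0).
#' @slot cx,cy Principal point in pixels; must lie inside the image.
#' @slot width,height Image size in pixels.
#' @export
setClass("CameraIntrinsics",
  representation(fx = "numeric", fy = "numeric", cx = "numeric",
                 cy = "numeric", width = "integer", height = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@fx <= 0 || object@fy <= 0)
      msg <- c(msg, "focal lengths fx, fy must be positive")
    if (object@width < 1L || object@height < 1L)
      msg <- c(msg, "image size must be at least 1x1")
    if (object@cx < 0 || object@cx >= object@width)
      msg <- c(msg, "cx must lie in [0, width)")
    if (object@cy < 0 || object@cy >= object@height)
      msg <- c(msg, "cy must lie in [0, height)")
    if (length(msg)) msg else TRUE
  })

#' Construct camera intrinsics
#'
#' @param fx,fy Focal lengths in pixels.
#' @param cx,cy Principal point in pixels.
#' @param width,height Image size in pixels.
#' @return A \linkS4class{CameraIntrinsics} object.
#' @examples
#' cameraIntrinsics(600, 600, 320, 240, 640, 480)
#' @export
cameraIntrinsics <- function(fx, fy, cx, cy, width, height) {
  new("CameraIntrinsics", fx = as.numeric(fx), fy = as.numeric(fy),
      cx = as.numeric(cx), cy = as.numeric(cy),
      width = as.integer(width), height = as.integer(height))
}

#' One labelled instance mask
#'
#' A binary pixel region for one food item or container instance in one
#' frame. Pixel coordinates are 0-based (row, col) with pixel centres at
#' integer coordinates.
#'
#' @slot frameId Frame identifier.
#' @slot category Food category (one of the fixed label set) or
#'   \code{"container"}.
#' @slot instanceId Instance identifier, unique within the frame.
#' @slot pixels Integer matrix with two columns (row, col).
#' @export
setClass("InstanceMask",
  representation(frameId = "character", category = "character",
                 instanceId = "character", pixels = "matrix"),
  validity = function(object) {
    msg <- character()
    p <- object@pixels
    if (!is.numeric(p) || ncol(p) != 2L)
      msg <- c(msg, "pixels must be a numeric matrix with columns (row, col)")
    else {
      if (nrow(p) == 0L) msg <- c(msg, "mask has no pixels")
      else if (any(p < 0) || any(p != floor(p)))
        msg <- c(msg, "pixel coordinates must be non-negative integers")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct an instance mask
#'
#' @param frame_id Frame identifier.
#' @param category Category label; matched case-insensitively after
#'   trimming against the accepted label set when used downstream.
#' @param pixels Two-column matrix of 0-based (row, col) pixel coordinates.
#' @param instance_id Instance identifier.
#' @return An \linkS4class{InstanceMask}.
#' @export
instanceMask <- function(frame_id, category, pixels, instance_id = "1") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  colnames(pixels) <- c("row", "col")
  new("InstanceMask", frameId = as.character(frame_id),
      category = normalizeCategory(category),
      instanceId = as.character(instance_id), pixels = pixels)
}

#' @describeIn instanceMask Category label of a mask.
#' @param x An \code{InstanceMask}.
#' @export
maskCategory <- function(x) x@category

#' @describeIn instanceMask Pixel coordinate matrix of a mask.
#' @export
maskPixels <- function(x) x@pixels

#' @describeIn instanceMask Frame identifier of a mask.
#' @export
maskFrameId <- function(x) x@frameId

#' Per-frame metric depth
#'
#' Per-pixel depth in metres; 0 marks invalid pixels (depth-camera
#' convention), which never enter re-projection.
#'
#' @slot frameId Frame identifier.
#' @slot depth Numeric matrix (height x width) of depth in metres.
#' @slot intrinsics A \linkS4class{CameraIntrinsics}.
#' @export
setClass("DepthFrame",
  representation(frameId = "character", depth = "matrix",
                 intrinsics = "CameraIntrinsics"),
  validity = function(object) {
    msg <- character()
    if (any(object@depth < 0)) msg <- c(msg, "depth must be >= 0 everywhere")
    if (nrow(object@depth) != object@intrinsics@height ||
        ncol(object@depth) != object@intrinsics@width)
      msg <- c(msg, "depth dimensions must equal intrinsics height x width")
    if (length(msg)) msg else TRUE
  })

#' Construct a depth frame
#'
#' @param frame_id Frame identifier.
#' @param depth Numeric matrix of depth in metres, 0 = invalid.
#' @param intrinsics A \linkS4class{CameraIntrinsics} matching the matrix
#'   dimensions.
#' @return A \linkS4class{DepthFrame}.
#' @export
depthFrame <- function(frame_id, depth, intrinsics) {
  new("DepthFrame", frameId = as.character(frame_id),
      depth = depth, intrinsics = intrinsics)
}

#' @describeIn depthFrame Depth matrix in metres.
#' @param x A \code{DepthFrame}.
#' @export
depthMatrix <- function(x) x@depth

#' @describeIn depthFrame Camera intrinsics of the frame.
#' @export
frameIntrinsics <- function(x) x@intrinsics

#' Eating-episode manifest
#'
#' Links the frames of one eating episode and designates the two time
#' frames (start and end) from which consumed portion size is computed.
#'
#' @slot episodeId Episode identifier.
#' @slot frameIds Ordered frame identifiers.
#' @slot startFrameId,endFrameId The two designated frames; must be members
#'   of \code{frameIds}.
#' @slot deviceTag Free-text device tag.
#' @slot groundTruth Optional named numeric: consumed weight in grams per
#'   food category.
#' @export
setClass("EpisodeManifest",
  representation(episodeId = "character", frameIds = "character",
                 startFrameId = "character", endFrameId = "character",
                 deviceTag = "character", groundTruth = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@startFrameId %in% object@frameIds))
      msg <- c(msg, "start frame id must be one of the episode frames")
    if (!(object@endFrameId %in% object@frameIds))
      msg <- c(msg, "end frame id must be one of the episode frames")
    if (length(object@groundTruth) && any(object@groundTruth < 0))
      msg <- c(msg, "ground-truth weights must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct an episode manifest
#'
#' @param episode_id Episode identifier.
#' @param frame_ids Ordered character vector of frame identifiers.
#' @param start_frame_id,end_frame_id Designated start/end frames.
#' @param device_tag Free-text device description.
#' @param ground_truth Optional named numeric vector of consumed weights
#'   (grams) per food category.
#' @return An \linkS4class{EpisodeManifest}.
#' @export
episodeManifest <- function(episode_id, frame_ids, start_frame_id,
                            end_frame_id, device_tag = "",
                            ground_truth = numeric()) {
  new("EpisodeManifest", episodeId = as.character(episode_id),
      frameIds = as.character(frame_ids),
      startFrameId = as.character(start_frame_id),
      endFrameId = as.character(end_frame_id),
      deviceTag = as.character(device_tag),
      groundTruth = ground_truth)
}

#' One food item's portion-size feature vector
#'
#' The six handcrafted features for one food item in one frame: food-type
#' one-hot (FT), food region ratio (FRR), categorical container volume
#' (VC, cm^3), container pixel count (NP), plate aspect ratio (PAR) and
#' area-weight ratio (AWR, g/cm^2).
#'
#' @slot category Food category.
#' @slot ft 15-element one-hot vector over the fixed food labels.
#' @slot frr Food region ratio (>= 0).
#' @slot vc Categorical container volume in cm^3 (positive multiple of 200).
#' @slot np Container pixel count (>= 1).
#' @slot par Plate aspect ratio (>= 1).
#' @slot awr Area-weight ratio in g/cm^2 (> 0).
#' @export
setClass("FeatureVector",
  representation(category = "character", ft = "numeric", frr = "numeric",
                 vc = "numeric", np = "numeric", par = "numeric",
                 awr = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@ft) != 15L || sum(object@ft == 1) != 1L ||
        sum(object@ft == 0) != 14L)
      msg <- c(msg, "ft must be a 15-element one-hot vector")
    if (object@frr < 0) msg <- c(msg, "frr must be >= 0")
    if (object@np < 1) msg <- c(msg, "np must be >= 1")
    if (object@par < 1 - 1e-9) msg <- c(msg, "par must be >= 1")
    if (object@awr <= 0) msg <- c(msg, "awr must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a feature vector
#'
#' @param category Food category.
#' @param ft One-hot food-type vector (see \code{\link{oneHot}}).
#' @param frr,vc,np,par,awr The scalar features.
#' @return A \linkS4class{FeatureVector}.
#' @export
featureVector <- function(category, ft, frr, vc, np, par, awr) {
  new("FeatureVector", category = normalizeCategory(category),
      ft = as.numeric(ft), frr = as.numeric(frr), vc = as.numeric(vc),
      np = as.numeric(np), par = as.numeric(par), awr = as.numeric(awr))
}

#' Fitted portion-size regression model
#'
#' @slot kind One of \code{"rf"}, \code{"et"}, \code{"gb"},
#'   \code{"ensemble"}.
#' @slot featureOrder Frozen feature column order (length 20).
#' @slot seed Integer seed all randomness was derived from.
#' @slot hyperparameters Named list of the frozen hyperparameters.
#' @slot fit Internal list of fitted component models.
#' @export
setClass("PortionModel",
  representation(kind = "character", featureOrder = "character",
                 seed = "integer", hyperparameters = "list", fit = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("rf", "et", "gb", "ensemble"))
      msg <- c(msg, "kind must be one of rf, et, gb, ensemble")
    if (length(object@featureOrder) != 20L)
      msg <- c(msg, "featureOrder must have length 20")
    if (length(msg)) msg else TRUE
  })

#' Cross-validation report
#'
#' @slot predictions Per-item data frame: item id, episode, category, fold,
#'   true and predicted weight (grams).
#' @slot metrics Named list of pooled summary metrics with 95\% CIs.
#' @slot kind Regressor kind used.
#' @slot folds Number of folds.
#' @export
setClass("CvReport",
  representation(predictions = "data.frame", metrics = "list",
                 kind = "character", folds = "integer"),
  validity = function(object) {
    tab <- table(object@predictions$item_id)
    if (any(tab != 1L)) "every item must appear in exactly one test fold"
    else TRUE
  })

#' @describeIn CvReport-class Per-item predictions of a CV report.
#' @param x A \code{CvReport}.
#' @export
cvPredictions <- function(x) x@predictions

#' @describeIn CvReport-class Pooled summary metrics of a CV report.
#' @export
cvMetrics <- function(x) x@metrics

setMethod("show", "CameraIntrinsics", function(object) {
  cat(sprintf("CameraIntrinsics %dx%d  fx=%.1f fy=%.1f cx=%.1f cy=%.1f\n",
              object@width, object@height, object@fx, object@fy,
              object@cx, object@cy))
})

setMethod("show", "InstanceMask", function(object) {
  cat(sprintf("InstanceMask '%s' frame=%s instance=%s  %d pixels\n",
              object@category, object@frameId, object@instanceId,
              nrow(object@pixels)))
})

setMethod("show", "DepthFrame", function(object) {
  d <- object@depth[object@depth > 0]
  cat(sprintf("DepthFrame %s  %dx%d  valid=%d  depth range [%.3f, %.3f] m\n",
              object@frameId, ncol(object@depth), nrow(object@depth),
              length(d), if (length(d)) min(d) else NA,
              if (length(d)) max(d) else NA))
})

setMethod("show", "EpisodeManifest", function(object) {
  cat(sprintf("EpisodeManifest %s  %d frames  start=%s end=%s\n",
              object@episodeId, length(object@frameIds),
              object@startFrameId, object@endFrameId))
})

setMethod("show", "FeatureVector", function(object) {
  cat(sprintf(
    "FeatureVector '%s'  frr=%.3f vc=%g np=%d par=%.3f awr=%.2f\n",
    object@category, object@frr, object@vc, as.integer(object@np),
    object@par, object@awr))
})

setMethod("show", "PortionModel", function(object) {
  cat(sprintf("PortionModel kind='%s' seed=%d  %d features\n",
              object@kind, object@seed, length(object@featureOrder)))
})

setMethod("show", "CvReport", function(object) {
  m <- object@metrics
  cat(sprintf(
    "CvReport kind='%s' k=%d  n=%d\n  MAE %.1f g  accuracy %.3f  MAPE %.1f%%\n",
    object@kind, object@folds, nrow(object@predictions),
    m$mae, m$accuracy, m$mape))
})
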