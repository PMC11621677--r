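#' Rasterise a polygon to pixel coordinates
#'
#' Even-odd rasterisation with pixel centres at integer (row, col)
#' coordinates: a pixel belongs to the region when its centre lies strictly
#' inside the polygon (even-odd rule) or on its boundary. Polygon vertices
#' are in image coordinates (x = col, y = row).
#'
#' @param xy Two-column matrix of polygon vertices (x, y), or a flat
#'   numeric vector \code{c(x1, y1, x2, y2, ...)} as used by COCO.
#' @param width,height Image size; pixels outside the image are dropped.
#' @param boundary Include pixels whose centre lies exactly on the polygon
#'   boundary. Needed for annotation formats with integer vertices; safe
#'   to disable for polygons in general position.
#' @return Integer matrix of 0-based (row, col) pixel coordinates.
#' @export
rasterizePolygon <- function(xy, width, height, boundary = TRUE) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2, byrow = TRUE)
  px <- xy[, 1]; py <- xy[, 2]
  n <- length(px)
  cmin <- max(0L, floor(min(px))); cmax <- min(width - 1L, ceiling(max(px)))
  rmin <- max(0L, floor(min(py))); rmax <- min(height - 1L, ceiling(max(py)))
  if (cmin > cmax || rmin > rmax)
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  .raster_polygon_cpp(px, py, cmin, cmax, rmin, rmax, boundary)
}

# Column-major uncompressed RLE (counts start with zeros), as in COCO
# "segmentation": {"counts": [...], "size": [h, w]}.
rleDecode <- function(counts, height, width) {
  counts <- as.numeric(counts)
  if (sum(counts) != height * width)
    stop("RLE counts do not cover the image (", sum(counts), " vs ",
         height * width, " pixels)")
  v <- rep(rep(c(0L, 1L), length.out = length(counts)), counts)
  idx <- which(v == 1L) - 1L          # 0-based linear, column-major
  cbind(row = idx %% height, col = idx %/% height)
}

rleEncode <- function(pixels, height, width) {
  v <- integer(height * width)
  v[pixels[, "col"] * height + pixels[, "row"] + 1L] <- 1L
  r <- rle(v)
  if (r$values[1] == 1L) list(counts = c(0L, r$lengths), size = c(height, width))
  else list(counts = r$lengths, size = c(height, width))
}

.checkCategory <- function(category, labels, where = "") {
  cat <- normalizeCategory(category)
  ok <- c(labels, "container")
  if (!cat %in% ok)
    stop("unknown category '", category, "'", where,
         "; accepted labels: ", paste(ok, collapse = ", "))
  cat
}

#' Read instance annotations
#'
#' Reads per-frame instance masks either from a COCO-style instance
#' annotation JSON (polygon or uncompressed RLE segmentations) or from a
#' directory of per-instance binary PNG masks with a sidecar
#' \code{labels.csv} (columns \code{file}, \code{frame_id},
#' \code{category}, \code{instance_id}). Every instance is decoded to an
#' explicit pixel set and its category validated against the configured
#' label set.
#'
#' @param path JSON file or mask directory.
#' @param labels Accepted food labels; \code{"container"} is always
#'   accepted in addition.
#' @return Named list (by frame id) of lists of
#'   \linkS4class{InstanceMask}; frame image sizes are attached as the
#'   \code{"image_sizes"} attribute (named list of \code{c(width,
#'   height)}).
#' @export
readAnnotations <- function(path, labels = foodLabels()) {
  labels <- normalizeCategory(labels)
  if (dir.exists(path)) return(.readAnnotationsPngDir(path, labels))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  imgs <- doc$images
  img_by_id <- list()
  for (im in imgs) img_by_id[[as.character(im$id)]] <- im
  cat_by_id <- list()
  for (ct in doc$categories) cat_by_id[[as.character(ct$id)]] <- ct$name
  out <- list()
  sizes <- list()
  for (im in imgs) {
    fid <- if (!is.null(im$file_name)) sub("\\.[^.]*$", "", im$file_name)
           else as.character(im$id)
    out[[fid]] <- list()
    sizes[[fid]] <- c(width = im$width, height = im$height)
  }
  for (an in doc$annotations) {
    im <- img_by_id[[as.character(an$image_id)]]
    if (is.null(im)) stop("annotation ", an$id, " references unknown image ",
                          an$image_id)
    fid <- if (!is.null(im$file_name)) sub("\\.[^.]*$", "", im$file_name)
           else as.character(im$id)
    category <- .checkCategory(cat_by_id[[as.character(an$category_id)]],
                               labels,
                               paste0(" (annotation ", an$id, ")"))
    seg <- an$segmentation
    if (!is.null(seg$counts)) {
      pix <- rleDecode(unlist(seg$counts), im$height, im$width)
    } else {
      polys <- lapply(seg, function(p)
        rasterizePolygon(unlist(p), im$width, im$height))
      pix <- unique(do.call(rbind, polys))
    }
    if (nrow(pix) == 0L)
      stop("empty mask for annotation ", an$id, " in frame ", fid)
    out[[fid]] <- c(out[[fid]],
                    instanceMask(fid, category, pix,
                                 instance_id = as.character(an$id)))
  }
  attr(out, "image_sizes") <- sizes
  out
}

.readAnnotationsPngDir <- function(path, labels) {
  lab <- read.csv(file.path(path, "labels.csv"), stringsAsFactors = FALSE)
  out <- list()
  sizes <- list()
  for (i in seq_len(nrow(lab))) {
    img <- png::readPNG(file.path(path, lab$file[i]))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    pix <- which(img > 0.5, arr.ind = TRUE) - 1L
    colnames(pix) <- c("row", "col")
    fid <- as.character(lab$frame_id[i])
    category <- .checkCategory(lab$category[i], labels,
                               paste0(" (", lab$file[i], ")"))
    if (nrow(pix) == 0L) stop("empty mask in ", lab$file[i], " frame ", fid)
    out[[fid]] <- c(out[[fid]],
                    instanceMask(fid, category, pix,
                                 as.character(lab$instance_id[i])))
    sizes[[fid]] <- c(width = ncol(img), height = nrow(img))
  }
  attr(out, "image_sizes") <- sizes
  out
}

#' Write instance annotations as COCO-style JSON
#'
#' Masks are stored as uncompressed column-major RLE. The inverse of
#' \code{\link{readAnnotations}} for in-memory masks.
#'
#' @param frames Named list (by frame id) of lists of
#'   \linkS4class{InstanceMask}.
#' @param image_sizes Named list of \code{c(width, height)} per frame id.
#' @param path Output JSON path.
#' @export
writeAnnotations <- function(frames, image_sizes, path) {
  cats <- c(foodLabels(), "container")
  categories <- lapply(seq_along(cats), function(i)
    list(id = i, name = cats[i]))
  images <- list(); annotations <- list(); aid <- 0L
  for (i in seq_along(frames)) {
    fid <- names(frames)[i]
    sz <- image_sizes[[fid]]
    images[[i]] <- list(id = i, file_name = paste0(fid, ".png"),
                        width = unname(sz["width"]),
                        height = unname(sz["height"]))
    for (m in frames[[fid]]) {
      aid <- aid + 1L
      annotations[[aid]] <- list(
        id = aid, image_id = i,
        category_id = match(maskCategory(m), cats),
        segmentation = rleEncode(maskPixels(m), sz["height"], sz["width"]))
    }
  }
  jsonlite::write_json(
    list(images = images, annotations = annotations,
         categories = categories),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a 16-bit PNG depth map
#'
#' @param path 16-bit single-channel PNG; stored integers times
#'   \code{scale_mm_per_unit} give millimetres. Stored zeros are invalid
#'   pixels and never enter re-projection.
#' @param intrinsics \linkS4class{CameraIntrinsics}; image size must match.
#' @param scale_mm_per_unit Millimetres per stored unit.
#' @param frame_id Frame identifier for the result.
#' @return A \linkS4class{DepthFrame} with depth in metres.
#' @export
readDepth <- function(path, intrinsics, scale_mm_per_unit = 1,
                      frame_id = sub("\\.[^.]*$", "", basename(path))) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) stop("depth PNG must be single-channel")
  units <- round(img * 65535)
  if (ncol(units) != intrinsics@width || nrow(units) != intrinsics@height)
    stop("depth image size ", ncol(units), "x", nrow(units),
         " does not match intrinsics ", intrinsics@width, "x",
         intrinsics@height)
  depthFrame(frame_id, units * scale_mm_per_unit / 1000, intrinsics)
}

#' Write a depth frame as 16-bit PNG
#'
#' @param frame A \linkS4class{DepthFrame}.
#' @param path Output path.
#' @param scale_mm_per_unit Millimetres per stored unit.
#' @export
writeDepth <- function(frame, path, scale_mm_per_unit = 1) {
  units <- round(depthMatrix(frame) * 1000 / scale_mm_per_unit)
  if (any(units > 65535))
    stop("depth exceeds the 16-bit range at the given scale")
  writePng16(units, path)
  invisible(path)
}

#' Read/write camera intrinsics JSON
#'
#' The JSON holds \code{fx, fy, cx, cy, width, height}.
#'
#' @param path JSON path.
#' @return \code{readIntrinsics} returns a \linkS4class{CameraIntrinsics}.
#' @export
readIntrinsics <- function(path) {
  k <- jsonlite::fromJSON(path)
  cameraIntrinsics(k$fx, k$fy, k$cx, k$cy, k$width, k$height)
}

#' @rdname readIntrinsics
#' @param k A \linkS4class{CameraIntrinsics}.
#' @export
writeIntrinsics <- function(k, path) {
  jsonlite::write_json(
    list(fx = k@fx, fy = k@fy, cx = k@cx, cy = k@cy,
         width = k@width, height = k@height),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read/write an episode manifest JSON
#'
#' @param path JSON path.
#' @return \code{readManifest} returns an \linkS4class{EpisodeManifest}.
#' @export
readManifest <- function(path) {
  m <- jsonlite::fromJSON(path)
  gt <- numeric()
  if (!is.null(m$ground_truth) && length(m$ground_truth))
    gt <- unlist(m$ground_truth)
  episodeManifest(m$episode_id, m$frame_ids, m$start_frame_id,
                  m$end_frame_id, device_tag = m$device_tag %||% "",
                  ground_truth = gt)
}

#' @rdname readManifest
#' @param manifest An \linkS4class{EpisodeManifest}.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(
    list(episode_id = manifest@episodeId,
         frame_ids = as.list(manifest@frameIds),
         start_frame_id = manifest@startFrameId,
         end_frame_id = manifest@endFrameId,
         device_tag = manifest@deviceTag,
         ground_truth = as.list(manifest@groundTruth)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a feature table CSV
#'
#' Deterministic column order: \code{episode_id, frame_id, category,
#' ft_0..ft_14, frr, vc, np, par, awr, weight_g}. Missing feature columns
#' are an error naming the offending record; a missing \code{weight_g} is
#' allowed (written as NA) since weights only exist for annotated training
#' data.
#'
#' @param records Data frame carrying the columns above (any order).
#' @param path Output CSV path.
#' @export
writeFeatureTable <- function(records, path) {
  cols <- featureTableColumns()
  if (!nrow(records)) {
    empty <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    write.csv(empty, path, row.names = FALSE)
    return(invisible(path))
  }
  if (!"weight_g" %in% names(records)) records$weight_g <- NA_real_
  need <- setdiff(cols, "weight_g")
  for (cn in need)
    if (!cn %in% names(records))
      stop("record is missing feature column '", cn, "'")
  feat <- setdiff(cols, c("episode_id", "frame_id", "category", "weight_g"))
  bad <- which(!stats::complete.cases(records[feat]))
  if (length(bad))
    stop("record ", bad[1], " (frame ", records$frame_id[bad[1]],
         ", category ", records$category[bad[1]], ") has missing features")
  write.csv(records[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @return \code{readFeatureTable} returns the records data frame in the
#'   canonical column order.
#' @export
readFeatureTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(featureTableColumns(), names(df))
  if (length(miss))
    stop("feature table is missing columns: ", paste(miss, collapse = ", "))
  df[featureTableColumns()]
}

#' Read/write an AWR calibration table
#'
#' CSV columns: \code{category, awr_g_per_cm2}. Returned as a named
#' numeric vector keyed by canonical category.
#'
#' @param path CSV path.
#' @export
readAwrTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  v <- df$awr_g_per_cm2
  names(v) <- normalizeCategory(df$category)
  if (any(v <= 0)) stop("AWR values must be positive")
  v
}

#' @rdname readAwrTable
#' @param table Named numeric vector of AWR values (g/cm^2).
#' @export
writeAwrTable <- function(table, path) {
  write.csv(data.frame(category = names(table),
                       awr_g_per_cm2 = unname(table)),
            path, row.names = FALSE)
  invisible(path)
}

#' Read/write ground-truth consumed weights
#'
#' Weighed-food-record CSV with columns \code{episode_id, category,
#' weight_g}.
#'
#' @param path CSV path.
#' @export
readWeights <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$category <- normalizeCategory(df$category)
  if (any(df$weight_g < 0)) stop("weights must be >= 0")
  df
}

#' @rdname readWeights
#' @param weights Data frame with \code{episode_id, category, weight_g}.
#' @export
writeWeights <- function(weights, path) {
  write.csv(weights[c("episode_id", "category", "weight_g")], path,
            row.names = FALSE)
  invisible(path)
}
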