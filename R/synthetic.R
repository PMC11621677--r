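# Synthetic eating scenes with exact ground truth: elliptical container
# masks under projective foreshortening, star-convex food blobs packed at
# target area fractions, plane-plus-depression depth maps with analytic
# hull volume, and weights tied to visible area through the AWR table.

#' Default AWR calibration table
#'
#' Area-weight ratios (g/cm^2) for the 15 food labels. Beef stew (2.3),
#' yam (3.5) and avocado (2.0) are the published calibration examples;
#' the remaining values are fixed plausible densities in the same range.
#'
#' @return Named numeric vector over \code{\link{foodLabels}}.
#' @export
defaultAwrTable <- function() {
  c("avocado" = 2.0, "banku" = 2.8, "beef stew" = 2.3, "chapati" = 1.5,
    "chicken drumstick" = 2.6, "onions" = 1.8,
    "onions & tomato salad" = 1.6, "rice dish" = 2.4,
    "roasted beef" = 2.2, "salted fish" = 2.1, "spinach stew" = 1.9,
    "tilapia fish" = 2.5, "tomato soup" = 2.9, "ugali" = 3.0,
    "yam" = 3.5)
}

#' Synthetic scene configuration
#'
#' Describes one synthetic eating scene. A circular plate of radius
#' \code{plate_radius_m} viewed at tilt theta projects to an ellipse whose
#' minor/major axis ratio is cos(theta) (foreshortening model), so the
#' ground-truth plate aspect ratio is 1/cos(theta). The depth map is a
#' fronto-parallel table plane at \code{distance_m} with a spherical-cap
#' depression of depth \code{plate_depth_m} spanning the container mask;
#' its convex-hull volume is analytic. Food weights follow
#' weight = AWR x visible area (cm^2) + Normal(0, weight_noise_g).
#'
#' @param width,height Image size in pixels.
#' @param fx,fy,cx,cy Camera intrinsics (defaults: 600 px focal length,
#'   centred principal point).
#' @param tilt_deg Camera tilt in degrees, 0 <= theta < 75.
#' @param distance_m Camera-to-table distance in metres.
#' @param plate_radius_m Physical plate radius in metres.
#' @param plate_depth_m Depression depth of the container in metres.
#' @param plate_center_px Optional \code{c(col, row)} plate centre;
#'   default the principal point.
#' @param food_layout Named numeric of target area fractions of the plate
#'   per food category; fractions >= 0 summing to <= 0.95.
#' @param awr_table Named AWR vector.
#' @param mask_jitter_px Boundary jitter of the container mask (px).
#' @param depth_noise_m Depth noise SD (m).
#' @param weight_noise_g Weight noise SD (g).
#' @return Validated config list of class \code{SceneConfig}.
#' @export
sceneConfig <- function(width = 640, height = 480, fx = 600, fy = 600,
                        cx = width / 2, cy = height / 2, tilt_deg = 0,
                        distance_m = 0.5, plate_radius_m = 0.10,
                        plate_depth_m = 0.03, plate_center_px = NULL,
                        food_layout = c("rice dish" = 0.25),
                        awr_table = defaultAwrTable(),
                        mask_jitter_px = 0, depth_noise_m = 0,
                        weight_noise_g = 0) {
  if (any(food_layout < 0) || sum(food_layout) > 0.95)
    stop("food area fractions must be >= 0 and sum to <= 0.95")
  if (tilt_deg < 0 || tilt_deg >= 75)
    stop("tilt must lie in [0, 75) degrees")
  if (distance_m <= 0) stop("distance must be positive")
  names(food_layout) <- normalizeCategory(names(food_layout))
  structure(list(width = width, height = height, fx = fx, fy = fy,
                 cx = cx, cy = cy, tilt_deg = tilt_deg,
                 distance_m = distance_m, plate_radius_m = plate_radius_m,
                 plate_depth_m = plate_depth_m,
                 plate_center_px = plate_center_px,
                 food_layout = food_layout, awr_table = awr_table,
                 mask_jitter_px = mask_jitter_px,
                 depth_noise_m = depth_noise_m,
                 weight_noise_g = weight_noise_g),
            class = "SceneConfig")
}

sceneIntrinsics <- function(config) {
  cameraIntrinsics(config$fx, config$fy, config$cx, config$cy,
                   config$width, config$height)
}

# Ellipse mask pixels, optionally with smooth radial boundary jitter.
.rasterEllipse <- function(x0, y0, a, b, width, height, jitter_px = 0) {
  cmin <- max(0L, floor(x0 - a - jitter_px * 3))
  cmax <- min(width - 1L, ceiling(x0 + a + jitter_px * 3))
  rmin <- max(0L, floor(y0 - b - jitter_px * 3))
  rmax <- min(height - 1L, ceiling(y0 + b + jitter_px * 3))
  if (cmin > cmax || rmin > rmax)
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  g <- expand.grid(col = cmin:cmax, row = rmin:rmax)
  u <- (g$col - x0) / a; v <- (g$row - y0) / b
  t <- sqrt(u^2 + v^2)
  if (jitter_px > 0) {
    phase <- runif(3, 0, 2 * pi)
    amp <- rnorm(3, 0, jitter_px / sqrt(3))
    phi <- atan2(v, u)
    j <- amp[1] * cos(2 * phi + phase[1]) + amp[2] * cos(3 * phi + phase[2]) +
      amp[3] * cos(5 * phi + phase[3])
    t <- t - j / sqrt(a * b)
  }
  keep <- t <= 1
  cbind(row = as.integer(g$row[keep]), col = as.integer(g$col[keep]))
}

# Star-convex polygon with unit mean radius; returns (x, y) vertices and
# its shoelace area.
.starPolygon <- function(n_vertices = 24, irregularity = 0.25) {
  phi <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  amp <- rnorm(3, 0, irregularity / sqrt(3))
  phase <- runif(3, 0, 2 * pi)
  r <- 1 + amp[1] * cos(2 * phi + phase[1]) +
    amp[2] * cos(3 * phi + phase[2]) + amp[3] * cos(4 * phi + phase[3])
  r <- pmin(pmax(r, 0.4), 1.6)
  x <- r * cos(phi); y <- r * sin(phi)
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  list(x = x, y = y, area = area)
}

# Shared renderer: given plate geometry and food blob polygons, produce
# masks, optional depth and the exact truth record.
.renderScene <- function(config, blobs, frame_id, render_depth = TRUE) {
  w <- config$width; h <- config$height
  ct <- cos(config$tilt_deg * pi / 180)
  a <- config$plate_radius_m * config$fx / config$distance_m
  b <- a * ct
  ctr <- config$plate_center_px %||% c(config$cx, config$cy)
  x0 <- ctr[1]; y0 <- ctr[2]
  plate_pix <- .rasterEllipse(x0, y0, a, b, w, h, config$mask_jitter_px)
  if (!nrow(plate_pix)) stop("container projects outside the image")
  masks <- list(instanceMask(frame_id, "container", plate_pix, "plate"))
  occupied <- matrix(FALSE, h, w)

  food_px <- list()  # per-category pixel counts
  for (nm in names(blobs)) {
    bl <- blobs[[nm]]
    if (is.null(bl)) next  # fully consumed
    vx <- x0 + bl$cx + bl$scale * bl$poly$x
    vy <- y0 + bl$cy + bl$scale * ct * bl$poly$y
    pix <- rasterizePolygon(cbind(vx, vy), w, h, boundary = FALSE)
    if (nrow(pix)) {
      ov <- occupied[cbind(pix[, "row"] + 1L, pix[, "col"] + 1L)]
      pix <- pix[!ov, , drop = FALSE]
    }
    if (!nrow(pix)) next
    occupied[cbind(pix[, "row"] + 1L, pix[, "col"] + 1L)] <- TRUE
    food_px[[bl$category]] <- (food_px[[bl$category]] %||% 0) + nrow(pix)
    masks <- c(masks, instanceMask(frame_id, bl$category, pix, nm))
  }

  px_area_cm2 <- config$distance_m^2 / (config$fx * config$fy) * 1e4
  R <- config$plate_radius_m; hd <- config$plate_depth_m
  # container (top-down) depression volume, and the foreshortened volume
  # the depth pipeline measures in THIS frame
  container_cm3 <- pi * hd * (3 * R^2 + hd^2) / 6 * 1e6
  vol_cm3 <- ct * container_cm3

  depth <- NULL
  if (render_depth) {
    dm <- matrix(config$distance_m, h, w)
    rho <- (R^2 + hd^2) / (2 * hd)
    uu <- (plate_pix[, "col"] - x0) / a
    vv <- (plate_pix[, "row"] - y0) / b
    t2 <- pmin(uu^2 + vv^2, 1)
    delta <- sqrt(rho^2 - t2 * R^2) - (rho - hd)
    dm[cbind(plate_pix[, "row"] + 1L, plate_pix[, "col"] + 1L)] <-
      config$distance_m + delta
    if (config$depth_noise_m > 0)
      dm <- pmax(dm + rnorm(length(dm), 0, config$depth_noise_m), 0.05)
    depth <- depthFrame(frame_id, dm, sceneIntrinsics(config))
  }

  food_truth <- if (length(food_px)) {
    npx <- unlist(food_px)
    data.frame(
      category = names(food_px),
      n_px = npx,
      frr = npx / nrow(plate_pix),
      area_cm2 = npx * px_area_cm2,
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(category = character(), n_px = numeric(),
               frr = numeric(), area_cm2 = numeric())
  }
  food_truth$weight_g <- pmax(
    0,
    food_truth$area_cm2 *
      vapply(food_truth$category, awrLookup, numeric(1),
             table = config$awr_table) +
      if (config$weight_noise_g > 0 && nrow(food_truth))
        rnorm(nrow(food_truth), 0, config$weight_noise_g) else 0)

  list(masks = masks, depth = depth,
       truth = list(container_px = nrow(plate_pix), par = 1 / ct,
                    volume_cm3 = vol_cm3,
                    container_volume_cm3 = container_cm3,
                    vc = categorizeVolume(container_cm3),
                    px_area_cm2 = px_area_cm2, foods = food_truth))
}

# Pack food blobs inside the plate ellipse by rejection sampling with an
# exact pixel-overlap test, capped at 10 000 attempts per category.
# Centres are proposed on unoccupied plate pixels; categories are placed
# largest-first; when a single blob of the target area will not fit, the
# area is split across several smaller instances of the same category
# (FRR sums instances, so the truth is unchanged).
.packBlobs <- function(config, plate_pix) {
  plate_px_count <- nrow(plate_pix)
  ct <- cos(config$tilt_deg * pi / 180)
  a <- config$plate_radius_m * config$fx / config$distance_m
  b <- a * ct
  ctr <- config$plate_center_px %||% c(config$cx, config$cy)
  x0 <- ctr[1]; y0 <- ctr[2]
  occupied <- matrix(FALSE, config$height, config$width)
  blobs <- list()
  layout <- config$food_layout[order(-config$food_layout)]
  for (nm in names(layout)) {
    frac <- layout[[nm]]
    if (frac == 0) next
    target_px <- frac * plate_px_count
    # greedy placement: try one blob of the full remaining area; after
    # sustained failure halve the piece size and keep what is placed
    remaining <- target_px
    piece_px <- target_px
    attempts <- 0L
    consecutive_fail <- 0L
    n_placed <- 0L
    while (remaining > max(1, 0.005 * target_px)) {
      if (attempts >= 10000L)
        stop("cannot pack food layout: area fraction ", frac, " for '",
             nm, "' unachievable")
      attempts <- attempts + 1L
      this_px <- min(piece_px, remaining)
      poly <- .starPolygon()
      scale <- sqrt(this_px / (poly$area * ct))
      ci <- plate_pix[sample.int(plate_px_count, 1), ]
      ok <- !occupied[ci[["row"]] + 1L, ci[["col"]] + 1L]
      if (ok) {
        cx <- ci[["col"]] - x0; cy <- ci[["row"]] - y0
        # vertex containment: polygon inside the ellipse implies every
        # rasterised blob pixel lies on a plate pixel (same centre rule)
        vx <- (cx + scale * poly$x) / a
        vy <- (cy + scale * ct * poly$y) / b
        ok <- !any(vx^2 + vy^2 > 1)
      }
      if (ok) {
        pix <- rasterizePolygon(cbind(x0 + cx + scale * poly$x,
                                      y0 + cy + scale * ct * poly$y),
                                config$width, config$height,
                                boundary = FALSE)
        ok <- nrow(pix) > 0 &&
          !any(occupied[cbind(pix[, "row"] + 1L, pix[, "col"] + 1L)])
      }
      if (!ok) {
        consecutive_fail <- consecutive_fail + 1L
        if (consecutive_fail >= 600L) {
          piece_px <- piece_px / 2
          consecutive_fail <- 0L
          if (piece_px < 0.02 * target_px)
            stop("cannot pack food layout: area fraction ", frac,
                 " for '", nm, "' unachievable")
        }
        next
      }
      occupied[cbind(pix[, "row"] + 1L, pix[, "col"] + 1L)] <- TRUE
      n_placed <- n_placed + 1L
      blobs[[paste0(nm, if (n_placed > 1L) paste0("#", n_placed) else "")]] <-
        list(category = nm, poly = poly, scale = scale, cx = cx, cy = cy)
      remaining <- remaining - this_px
      consecutive_fail <- 0L
    }
  }
  blobs
}

#' Generate one synthetic frame
#'
#' Renders the container mask, food masks at the configured area
#' fractions, and (optionally) the depth map, and returns the exact truth
#' record alongside.
#'
#' @param config A \code{\link{sceneConfig}}.
#' @param seed Integer seed; the frame is fully reproducible from it.
#' @param frame_id Frame identifier.
#' @param render_depth Render the depth map (skippable for speed when
#'   only masks are needed).
#' @return List with \code{masks} (list of \linkS4class{InstanceMask};
#'   container first), \code{depth} (a \linkS4class{DepthFrame} or NULL),
#'   and \code{truth} (container pixel count, true PAR, analytic
#'   container volume and VC, per-food pixel counts, areas in cm^2 and
#'   weights in g).
#' @export
generateFrame <- function(config, seed = 1, frame_id = "frame_1",
                          render_depth = TRUE) {
  .withSeed(seed, {
    probe <- .rasterEllipse(
      (config$plate_center_px %||% c(config$cx, config$cy))[1],
      (config$plate_center_px %||% c(config$cx, config$cy))[2],
      config$plate_radius_m * config$fx / config$distance_m,
      config$plate_radius_m * config$fx / config$distance_m *
        cos(config$tilt_deg * pi / 180),
      config$width, config$height)
    blobs <- .packBlobs(config, probe)
    .renderScene(config, blobs, frame_id, render_depth)
  })
}

#' Generate a synthetic eating episode
#'
#' Renders a start frame and an end frame in which each food blob is
#' shrunk about its centroid to (1 - consumed fraction) of its initial
#' area (a fraction of 1 removes the food entirely), and records the true
#' initial, final and consumed weight per category.
#'
#' @param config A \code{\link{sceneConfig}}.
#' @param consumption Named numeric in [0, 1]: consumed area fraction per
#'   food category (defaults to the full layout at 0.5 each when
#'   unnamed scalar given).
#' @param seed Integer seed.
#' @param episode_id Episode identifier.
#' @param render_depth Render depth maps.
#' @return List with \code{start}, \code{end} (as
#'   \code{\link{generateFrame}} results), \code{manifest}
#'   (an \linkS4class{EpisodeManifest} whose ground truth is the consumed
#'   weight), and \code{truth} (per-category initial/final/consumed g).
#' @export
generateEpisode <- function(config, consumption, seed = 1,
                            episode_id = "ep_1", render_depth = TRUE) {
  if (any(consumption < 0) || any(consumption > 1))
    stop("consumption fractions must lie in [0, 1]")
  names(consumption) <- normalizeCategory(names(consumption))
  if (!all(names(consumption) %in% names(config$food_layout)))
    stop("consumption names must match the food layout")
  sid <- paste0(episode_id, "_start"); eid <- paste0(episode_id, "_end")
  .withSeed(seed, {
    probe <- .rasterEllipse(
      (config$plate_center_px %||% c(config$cx, config$cy))[1],
      (config$plate_center_px %||% c(config$cx, config$cy))[2],
      config$plate_radius_m * config$fx / config$distance_m,
      config$plate_radius_m * config$fx / config$distance_m *
        cos(config$tilt_deg * pi / 180),
      config$width, config$height)
    blobs <- .packBlobs(config, probe)
    start <- .renderScene(config, blobs, sid, render_depth)
    end_blobs <- blobs
    for (nm in names(end_blobs)) {
      cfrac <- consumption[[end_blobs[[nm]]$category]] %||% 0
      if (cfrac >= 1) end_blobs[nm] <- list(NULL)
      else end_blobs[[nm]]$scale <- end_blobs[[nm]]$scale * sqrt(1 - cfrac)
    }
    end <- .renderScene(config, end_blobs, eid, render_depth)

    tr0 <- start$truth$foods
    tr1 <- end$truth$foods
    final <- tr1$weight_g[match(tr0$category, tr1$category)]
    final[is.na(final)] <- 0
    final <- pmin(final, tr0$weight_g)
    truth <- data.frame(category = tr0$category,
                        initial_g = tr0$weight_g, final_g = final,
                        consumed_g = tr0$weight_g - final,
                        stringsAsFactors = FALSE)
    gt <- setNames(truth$consumed_g, truth$category)
    manifest <- episodeManifest(episode_id, c(sid, eid), sid, eid,
                                device_tag = "synthetic",
                                ground_truth = gt)
    list(start = start, end = end, manifest = manifest, truth = truth,
         volume_cm3 = start$truth$volume_cm3, vc = start$truth$vc)
  })
}

.sampleSceneConfig <- function(ranges, awr_table) {
  n_foods <- sample(ranges$foods_per_episode, 1)
  cats <- sample(foodLabels(), n_foods)
  fracs <- runif(n_foods, ranges$frac_range[1], ranges$frac_range[2])
  if (sum(fracs) > 0.6) fracs <- fracs * 0.6 / sum(fracs)
  container <- ranges$containers[[sample(length(ranges$containers), 1)]]
  sceneConfig(
    width = ranges$width, height = ranges$height,
    fx = ranges$fx, fy = ranges$fy,
    tilt_deg = runif(1, ranges$tilt_range[1], ranges$tilt_range[2]),
    distance_m = runif(1, ranges$distance_range[1],
                       ranges$distance_range[2]),
    plate_radius_m = container[["radius"]],
    plate_depth_m = container[["depth"]],
    food_layout = setNames(fracs, cats), awr_table = awr_table,
    mask_jitter_px = ranges$mask_jitter_px,
    depth_noise_m = ranges$depth_noise_m,
    weight_noise_g = ranges$weight_noise_g)
}

#' Default parameter ranges for synthetic studies
#'
#' Scene parameters are drawn uniformly from these ranges: tilt 0-60
#' degrees (wearable cameras see plates well off the vertical), distance
#' 0.4-0.7 m (eye- or chest-level camera to table), one of three
#' geometrically similar container types (radius 0.08/0.10/0.12 m with
#' depression depth 0.3 radius; volumes of roughly 250-850 cm^3 -- a
#' study uses a small set of known containers, which is what makes the
#' container-volume feature informative and the plate pixel count a
#' distance proxy), 1-3 foods per episode at area fractions 0.08-0.30,
#' and consumed fractions 0.3-1. Noise defaults are 0 so that generator
#' truth is exact up to rasterisation.
#'
#' @param ... Overrides of individual entries.
#' @return Named list of ranges.
#' @export
studyRanges <- function(...) {
  r <- list(width = 640, height = 480, fx = 600, fy = 600,
            tilt_range = c(0, 60), distance_range = c(0.4, 0.7),
            containers = list(c(radius = 0.08, depth = 0.024),
                              c(radius = 0.10, depth = 0.030),
                              c(radius = 0.12, depth = 0.036)),
            foods_per_episode = 1:3, frac_range = c(0.08, 0.30),
            consumption_range = c(0.3, 1), mask_jitter_px = 0,
            depth_noise_m = 0, weight_noise_g = 0)
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(r)))
  r[names(dots)] <- dots   # whole-entry replacement, no recursive merge
  r
}

#' Generate a synthetic study on disk
#'
#' Writes a full synthetic dataset in every external format the pipeline
#' reads: COCO-style annotations, 16-bit PNG depth maps, intrinsics JSON,
#' per-episode manifests, the AWR table and weighed-food-record ground
#' truth. Byte-identical for the same seed.
#'
#' @param n_episodes Number of episodes (>= 1).
#' @param out_dir Output directory (created).
#' @param seed Integer seed.
#' @param ranges Parameter ranges, see \code{\link{studyRanges}}.
#' @param awr_table AWR table used for weights.
#' @return Invisibly, the list of episode truth tables.
#' @export
generateStudy <- function(n_episodes, out_dir, seed = 1,
                          ranges = studyRanges(),
                          awr_table = defaultAwrTable()) {
  stopifnot(n_episodes >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "depth"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "manifests"), showWarnings = FALSE)
  frames <- list(); sizes <- list(); truths <- list()
  wfr <- list()
  intr <- NULL
  .withSeed(seed, {
    for (i in seq_len(n_episodes)) {
      cfg <- .sampleSceneConfig(ranges, awr_table)
      cats <- names(cfg$food_layout)
      cons <- setNames(runif(length(cats), ranges$consumption_range[1],
                             ranges$consumption_range[2]), cats)
      ep_id <- sprintf("ep_%03d", i)
      ep <- generateEpisode(cfg, cons, seed = sample.int(1e6, 1),
                            episode_id = ep_id)
      for (fr in list(ep$start, ep$end)) {
        fid <- maskFrameId(fr$masks[[1]])
        frames[[fid]] <- fr$masks
        sizes[[fid]] <- c(width = cfg$width, height = cfg$height)
        writeDepth(fr$depth, file.path(out_dir, "depth",
                                       paste0(fid, ".png")))
        intr <- frameIntrinsics(fr$depth)
      }
      writeManifest(ep$manifest,
                    file.path(out_dir, "manifests", paste0(ep_id, ".json")))
      truths[[ep_id]] <- ep$truth
      wfr[[ep_id]] <- data.frame(episode_id = ep_id,
                                 category = ep$truth$category,
                                 weight_g = ep$truth$consumed_g)
    }
  })
  writeAnnotations(frames, sizes, file.path(out_dir, "annotations.json"))
  writeIntrinsics(intr, file.path(out_dir, "intrinsics.json"))
  writeAwrTable(awr_table, file.path(out_dir, "awr.csv"))
  writeWeights(do.call(rbind, wfr), file.path(out_dir, "wfr.csv"))
  invisible(truths)
}

#' Generate an in-memory feature study
#'
#' Renders frames through the real mask pipeline (rasterised container
#' and food blobs, features assembled by \code{\link{assembleFeatures}})
#' and returns a weight-annotated feature table for model experiments.
#' The categorical container volume comes from the analytic scene truth;
#' depth rendering is skipped for speed.
#'
#' @param n_items Number of food items (feature records) to produce.
#' @param seed Integer seed.
#' @param ranges Parameter ranges, see \code{\link{studyRanges}}.
#' @param awr_table AWR table.
#' @return Feature-table data frame with \code{weight_g} filled and
#'   \code{item_id} set; one row per food item.
#' @export
generateFeatureStudy <- function(n_items, seed = 1, ranges = studyRanges(),
                                 awr_table = defaultAwrTable()) {
  out <- list()
  got <- 0L; i <- 0L
  .withSeed(seed, {
    while (got < n_items) {
      i <- i + 1L
      cfg <- .sampleSceneConfig(ranges, awr_table)
      fid <- sprintf("frame_%04d", i)
      fr <- tryCatch(
        .renderScene(cfg, .packBlobs(
          cfg, .rasterEllipse(cfg$cx, cfg$cy,
                              cfg$plate_radius_m * cfg$fx / cfg$distance_m,
                              cfg$plate_radius_m * cfg$fx / cfg$distance_m *
                                cos(cfg$tilt_deg * pi / 180),
                              cfg$width, cfg$height)),
          fid, render_depth = FALSE),
        error = function(e) NULL)
      if (is.null(fr) || !nrow(fr$truth$foods)) next
      fv <- assembleFeatures(fr$masks, vc = fr$truth$vc, awr_table)
      tab <- featureTable(fv, episode_id = fid, frame_id = fid,
                          weights = setNames(fr$truth$foods$weight_g,
                                             fr$truth$foods$category))
      out[[length(out) + 1L]] <- tab
      got <- got + nrow(tab)
    }
  })
  df <- do.call(rbind, out)
  df <- df[seq_len(n_items), , drop = FALSE]
  df$item_id <- as.character(seq_len(n_items))
  rownames(df) <- NULL
  df
}
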