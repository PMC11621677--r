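#' One-hot food-type encoding (FT)
#'
#' Encodes a food category as a 15-element one-hot vector over the frozen
#' alphabetical label order (see \code{\link{foodLabels}}).
#'
#' @param category A food category label.
#' @return Numeric vector of length 15 with a single 1.
#' @export
oneHot <- function(category) {
  cat <- normalizeCategory(category)
  if (cat == "container")
    stop("'container' is not a food type; one-hot encoding applies to the ",
         "15 food labels only")
  i <- match(cat, foodLabels())
  if (is.na(i))
    stop("unknown food category '", category, "'; accepted labels: ",
         paste(foodLabels(), collapse = ", "))
  v <- numeric(15)
  v[i] <- 1
  v
}

#' Food region ratio (FRR)
#'
#' Ratio of a food item's pixel count to the container's pixel count,
#' N_F / N_P. Multiple instances of the same food in a frame are summed
#' into one ratio.
#'
#' @param food_masks List of \linkS4class{InstanceMask} for one food
#'   category in one frame (possibly empty).
#' @param container_mask The container \linkS4class{InstanceMask}.
#' @return FRR, a dimensionless ratio >= 0.
#' @export
foodRegionRatio <- function(food_masks, container_mask) {
  if (is(food_masks, "InstanceMask")) food_masks <- list(food_masks)
  np <- pixelCount(container_mask)
  if (np == 0L) stop("container mask is empty")
  if (!length(food_masks)) return(0)
  sum(vapply(food_masks, pixelCount, numeric(1))) / np
}

#' Container pixel count (NP)
#'
#' Number of pixels in a mask; with a fixed container, a rough proxy for
#' camera-to-container distance.
#'
#' @param mask An \linkS4class{InstanceMask}.
#' @return Pixel count.
#' @export
pixelCount <- function(mask) nrow(maskPixels(mask))

#' Plate aspect ratio (PAR)
#'
#' Ratio of the two singular values of the centred (row, col) mask
#' coordinates: sigma_1 / sigma_2. A top-down circular plate gives 1; a
#' tilted view foreshortens the plate into an ellipse and raises the
#' ratio, so PAR indicates the camera viewing angle independently of dish
#' size. All filled mask pixels are used (robust to boundary noise).
#'
#' @param container_mask An \linkS4class{InstanceMask}.
#' @return PAR >= 1.
#' @export
plateAspectRatio <- function(container_mask) {
  p <- maskPixels(container_mask)
  x <- sweep(p, 2, colMeans(p))
  sv <- svd(x, nu = 0, nv = 0)$d
  if (sv[2] <= 1e-9 * sv[1])
    stop("degenerate mask: pixel coordinates are collinear")
  sv[1] / sv[2]
}

#' Look up a food's area-weight ratio (AWR)
#'
#' @param category Food category.
#' @param table Named numeric vector of AWR values in g/cm^2 (see
#'   \code{\link{readAwrTable}}).
#' @return AWR in g/cm^2.
#' @export
awrLookup <- function(category, table) {
  cat <- normalizeCategory(category)
  v <- unname(table[match(cat, names(table))])
  if (is.na(v))
    stop("no AWR value for category '", category, "'")
  v
}

#' Calibrate an AWR value by regression
#'
#' Least-squares slope of weight on visible surface area through the
#' origin, sum(a w) / sum(a^2) — the grams-per-cm^2 interpretation of AWR
#' forces a zero intercept.
#'
#' @param areas_cm2 Mean surface areas (cm^2), > 0.
#' @param weights_g Matching weights (g).
#' @return AWR in g/cm^2.
#' @examples
#' calibrateAwr(c(10, 20), c(23, 46))  # 2.3
#' @export
calibrateAwr <- function(areas_cm2, weights_g) {
  if (length(areas_cm2) != length(weights_g))
    stop("areas and weights must have equal length")
  if (length(areas_cm2) < 2)
    stop("insufficient data: need at least 2 paired observations")
  if (all(areas_cm2 == 0)) stop("all areas are zero")
  sum(areas_cm2 * weights_g) / sum(areas_cm2^2)
}

#' Assemble per-food feature vectors for one frame
#'
#' For a frame classified \code{with_container}, computes one
#' \linkS4class{FeatureVector} per distinct food category present. All
#' vectors share the frame's NP, PAR and VC; FRR, FT and AWR are
#' food-specific. When several containers are present the largest by
#' pixel count is the reference plate (a warning is issued); episodes use
#' a single container per estimate.
#'
#' @param frame_masks List of \linkS4class{InstanceMask} for one frame
#'   (foods and container(s)).
#' @param vc Categorical container volume in cm^3 (see
#'   \code{\link{categorizeVolume}}).
#' @param awr_table Named numeric vector of AWR values.
#' @return Named list of \linkS4class{FeatureVector}, one per food
#'   category, in alphabetical category order. Empty when no food lies in
#'   the frame.
#' @export
assembleFeatures <- function(frame_masks, vc, awr_table) {
  containers <- Filter(function(m) maskCategory(m) == "container",
                       frame_masks)
  if (!length(containers))
    stop("frame without container: portion features are undefined")
  if (length(containers) > 1L) {
    warning("multiple containers in frame; using the largest as the ",
            "reference plate")
    containers <- containers[order(-vapply(containers, pixelCount,
                                           numeric(1)))]
  }
  plate <- containers[[1]]
  np <- pixelCount(plate)
  par <- plateAspectRatio(plate)
  foods <- Filter(function(m) maskCategory(m) != "container", frame_masks)
  if (!length(foods)) return(list())
  cats <- sort(unique(vapply(foods, maskCategory, character(1))))
  out <- lapply(cats, function(cat) {
    inst <- Filter(function(m) maskCategory(m) == cat, foods)
    featureVector(cat, oneHot(cat),
                  frr = foodRegionRatio(inst, plate), vc = vc, np = np,
                  par = par, awr = awrLookup(cat, awr_table))
  })
  names(out) <- cats
  out
}

#' Convert feature vectors to a feature-table row set
#'
#' @param features List of \linkS4class{FeatureVector} (e.g. from
#'   \code{\link{assembleFeatures}}).
#' @param episode_id,frame_id Identifiers stamped on each row.
#' @param weights Optional named numeric of ground-truth weights (grams)
#'   per category.
#' @return Data frame in the canonical feature-table column order.
#' @export
featureTable <- function(features, episode_id = "", frame_id = "",
                         weights = NULL) {
  cols <- featureTableColumns()
  if (!length(features)) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    df$episode_id <- character(0); df$frame_id <- character(0)
    df$category <- character(0)
    return(df[cols])
  }
  rows <- lapply(features, function(f) {
    w <- if (!is.null(weights) && f@category %in% names(weights))
      unname(weights[[f@category]]) else NA_real_
    c(list(episode_id = episode_id, frame_id = frame_id,
           category = f@category),
      setNames(as.list(f@ft), paste0("ft_", 0:14)),
      list(frr = f@frr, vc = f@vc, np = f@np, par = f@par, awr = f@awr,
           weight_g = w))
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df[cols]
}
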