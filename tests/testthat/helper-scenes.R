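# Shared fixtures, all built in code.

tinyIntrinsics <- function(w = 40, h = 30, f = 50) {
  cameraIntrinsics(f, f, w / 2, h / 2, w, h)
}

# Filled disc mask (0-based integer pixel centres).
discMask <- function(cx, cy, r, frame_id = "f1", category = "container",
                     instance_id = "1") {
  g <- expand.grid(col = floor(cx - r):ceiling(cx + r),
                   row = floor(cy - r):ceiling(cy + r))
  keep <- (g$col - cx)^2 + (g$row - cy)^2 <= r^2 &
    g$col >= 0 & g$row >= 0
  instanceMask(frame_id, category,
               cbind(row = g$row[keep], col = g$col[keep]), instance_id)
}

# Filled axis-aligned ellipse, optionally rotated by `angle` radians.
ellipseMask <- function(cx, cy, a, b, angle = 0, frame_id = "f1",
                        category = "container") {
  m <- ceiling(max(a, b)) + 1L
  g <- expand.grid(col = -m:m, row = -m:m)
  x <- g$col * cos(angle) + g$row * sin(angle)
  y <- -g$col * sin(angle) + g$row * cos(angle)
  keep <- (x / a)^2 + (y / b)^2 <= 1
  px <- cbind(row = g$row[keep] + round(cy), col = g$col[keep] + round(cx))
  px <- px[px[, 1] >= 0 & px[, 2] >= 0, , drop = FALSE]
  instanceMask(frame_id, category, px)
}

rectMask <- function(r0, c0, nr, nc, frame_id = "f1",
                     category = "container", instance_id = "1") {
  g <- expand.grid(row = r0:(r0 + nr - 1), col = c0:(c0 + nc - 1))
  instanceMask(frame_id, category, cbind(row = g$row, col = g$col),
               instance_id)
}

# A small weight-annotated feature table with a known linear structure,
# for exercising the model plumbing quickly.
toyPairs <- function(n = 30, seed = 1, weight = NULL) {
  set.seed(seed)
  cats <- sample(foodLabels(), n, replace = TRUE)
  ft <- t(vapply(cats, oneHot, numeric(15)))
  colnames(ft) <- paste0("ft_", 0:14)
  df <- data.frame(episode_id = paste0("ep", rep(1:5, length.out = n)),
                   frame_id = paste0("fr", seq_len(n)), category = cats,
                   stringsAsFactors = FALSE)
  df <- cbind(df, ft)
  df$frr <- runif(n, 0.05, 0.4)
  df$vc <- sample(c(200, 400, 600), n, replace = TRUE)
  df$np <- round(runif(n, 2e4, 6e4))
  df$par <- runif(n, 1, 2)
  df$awr <- vapply(cats, awrLookup, numeric(1), table = defaultAwrTable())
  df$weight_g <- if (is.null(weight))
    df$awr * df$frr * df$vc / 4 + rnorm(n, 0, 2) else weight
  df$item_id <- as.character(seq_len(n))
  df
}

# Memoised 300-item noiseless feature study shared by the acceptance
# blocks (generation is the expensive step).
.study_cache <- new.env(parent = emptyenv())
acceptanceStudy <- function() {
  if (is.null(.study_cache$df))
    .study_cache$df <- generateFeatureStudy(300, seed = 2024)
  .study_cache$df
}

# Zero out all feature columns except `keep` (a constant column is never
# split on, so this trains the model on the kept features only).
restrictFeatures <- function(df, keep) {
  drop <- setdiff(featureOrder(), keep)
  df[drop] <- 0
  df
}
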