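# Portion-size regression: single regressors (RF / ET / GB) and the
# stacking ensemble (RF + ET bases, MLP meta-learner), with volume-weight
# augmentation and the two cross-validation protocols.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# MLP wrapper: standardises inputs and target (grams are O(100) while
# Glorot-initialised weights expect unit-scale activations), then trains
# the compiled Adam MLP.
.fitMlp <- function(X, y, hidden, max_iter, tol, seed, lr = 1e-3,
                    alpha = 1e-4) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  ymu <- mean(y); ysd <- stats::sd(y)
  if (ysd == 0 || !is.finite(ysd)) ysd <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  fit <- .mlp_fit_cpp(Xs, (y - ymu) / ysd, as.integer(hidden),
                      as.integer(max_iter), tol, lr, as.integer(seed),
                      alpha)
  structure(list(fit = fit, mu = mu, sd = sdv, ymu = ymu, ysd = ysd),
            class = "dv_mlp")
}

.predictMlp <- function(m, X) {
  Xs <- sweep(sweep(as.matrix(X), 2, m$mu), 2, m$sd, "/")
  as.numeric(.mlp_predict_cpp(m$fit, Xs)) * m$ysd + m$ymu
}

.defaultHyperparameters <- function(kind) {
  base <- list(rf_trees = 10L, et_trees = 10L, gb_trees = 20L,
               gb_eta = 0.1, gb_depth = 3L,
               mlp_hidden = c(250L, 250L, 250L, 250L, 125L, 50L),
               mlp_max_iter = 10000L, mlp_tol = 1e-6, stacking_cv = 5L)
  base
}

.designMatrix <- function(features, feature_order = featureOrder()) {
  if (is(features, "FeatureVector")) features <- list(features)
  if (is.list(features) && !is.data.frame(features) &&
      all(vapply(features, is, logical(1), "FeatureVector")))
    features <- featureTable(features)
  if (is.data.frame(features)) {
    miss <- setdiff(feature_order, names(features))
    if (length(miss))
      stop("feature columns missing: ", paste(miss, collapse = ", "))
    X <- as.matrix(features[feature_order])
  } else {
    X <- as.matrix(features)
    if (is.null(colnames(X)) || !identical(colnames(X), feature_order))
      stop("feature matrix columns must match the model's feature order")
  }
  storage.mode(X) <- "double"
  X
}

.fitBase <- function(what, X, y, hp, seed) {
  switch(what,
    rf = .withSeed(seed,
      randomForest::randomForest(x = X, y = y, ntree = hp$rf_trees,
                                 mtry = ncol(X), nodesize = 1)),
    et = ranger::ranger(x = as.data.frame(X), y = y,
                        num.trees = hp$et_trees, mtry = ncol(X),
                        splitrule = "extratrees", num.random.splits = 1,
                        replace = FALSE, sample.fraction = 1,
                        min.node.size = 1, seed = seed, num.threads = 1),
    gb = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      xgboost::xgb.train(
        params = list(objective = "reg:squarederror", eta = hp$gb_eta,
                      max_depth = hp$gb_depth, nthread = 1,
                      base_score = mean(y)),
        data = dtrain, nrounds = hp$gb_trees, verbose = 0)
    },
    stop("unknown base regressor '", what, "'"))
}

.predictBase <- function(what, fit, X) {
  switch(what,
    rf = as.numeric(predict(fit, X)),
    et = as.numeric(predict(fit, data = as.data.frame(X),
                            num.threads = 1)$predictions),
    gb = as.numeric(predict(fit, xgboost::xgb.DMatrix(X))))
}

#' Train a portion-size regressor
#'
#' Fits one of the frozen portion-size models on weight-annotated feature
#' records: random forest (10 trees), extra trees (10 trees), gradient
#' boosting (20 rounds), or the stacking ensemble that combines RF and ET
#' base regressors with a multi-layer perceptron meta-learner (hidden
#' layers 250-250-250-250-125-50, ReLU, Adam, up to 10k epochs,
#' tolerance 1e-6). Meta-features are produced by internal 5-fold
#' cross-validation of the bases, then the bases are refit on all data.
#' All randomness derives from \code{seed}; identical data and seed give
#' bitwise-identical predictions.
#'
#' @param pairs Data frame of training records carrying the 20 feature
#'   columns (see \code{\link{featureOrder}}) and \code{weight_g}.
#' @param kind \code{"ensemble"}, \code{"rf"}, \code{"et"} or \code{"gb"}.
#' @param seed Integer seed.
#' @param config Named list overriding individual hyperparameters.
#' @return A \linkS4class{PortionModel}.
#' @export
trainPortionModel <- function(pairs, kind = c("ensemble", "rf", "et", "gb"),
                              seed = 1, config = list()) {
  kind <- match.arg(kind)
  hp <- utils::modifyList(.defaultHyperparameters(kind), config)
  X <- .designMatrix(pairs)
  if (!"weight_g" %in% names(pairs) || anyNA(pairs$weight_g))
    stop("training requires a complete weight_g column")
  y <- as.numeric(pairs$weight_g)
  if (any(y < 0)) stop("training weights must be >= 0")
  if (nrow(X) < 10L) stop("too few training pairs (need >= 10)")
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite feature value in record ", bad[1, 1], ", column '",
         colnames(X)[bad[1, 2]], "'")
  seed <- as.integer(seed)

  fit <- if (kind == "ensemble") {
    n <- nrow(X)
    cv <- min(hp$stacking_cv, n)
    fold <- .withSeed(seed, sample(rep_len(seq_len(cv), n)))
    Z <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("rf", "et")))
    for (f in seq_len(cv)) {
      tr <- fold != f
      for (b in c("rf", "et")) {
        bf <- .fitBase(b, X[tr, , drop = FALSE], y[tr], hp,
                       seed + f)
        Z[!tr, b] <- .predictBase(b, bf, X[!tr, , drop = FALSE])
      }
    }
    meta <- .fitMlp(Z, y, hp$mlp_hidden, hp$mlp_max_iter, hp$mlp_tol, seed)
    list(rf = .fitBase("rf", X, y, hp, seed),
         et = .fitBase("et", X, y, hp, seed),
         meta = meta)
  } else {
    list(single = .fitBase(kind, X, y, hp, seed))
  }
  new("PortionModel", kind = kind, featureOrder = featureOrder(),
      seed = seed, hyperparameters = hp, fit = fit)
}

#' Predict food weight in grams
#'
#' Applies a fitted \linkS4class{PortionModel}. Raw negative outputs are
#' physically impossible and are clipped to 0 g with a warning.
#'
#' @param object A \linkS4class{PortionModel}.
#' @param newdata Feature records: a data frame with the model's feature
#'   columns, a matrix in the model's column order, or (a list of)
#'   \linkS4class{FeatureVector}.
#' @param ... Ignored.
#' @return Numeric vector of non-negative weights (g).
#' @export
setMethod("predict", "PortionModel", function(object, newdata, ...) {
  X <- .designMatrix(newdata, object@featureOrder)
  p <- if (object@kind == "ensemble") {
    Z <- cbind(rf = .predictBase("rf", object@fit$rf, X),
               et = .predictBase("et", object@fit$et, X))
    .predictMlp(object@fit$meta, Z)
  } else {
    .predictBase(object@kind, object@fit$single, X)
  }
  if (any(p < 0)) {
    warning(sum(p < 0), " negative prediction(s) clipped to 0 g")
    p <- pmax(0, p)
  }
  p
})

#' Volume-weight augmentation
#'
#' Exploits the linear physical relationship between a container's inner
#' volume and the weight of the food it holds: scaling the container by a
#' factor s scales both the categorical volume feature and the target
#' weight by s, leaving all other features unchanged. Returns only the
#' new records (originals are untouched), flagged \code{augmented} and
#' carrying \code{source_item_id} so cross-validation can keep a test
#' item's augmented derivatives out of its training folds.
#'
#' @param pairs Data frame of training records (feature columns plus
#'   \code{weight_g}; an \code{item_id} column is added from the row
#'   index when absent).
#' @param scale_factors Positive numeric scale factors.
#' @return Data frame of augmented records,
#'   \code{nrow(pairs) * length(scale_factors)} rows.
#' @export
augmentVolumeScaling <- function(pairs, scale_factors) {
  if (any(scale_factors <= 0)) stop("scale factors must be positive")
  if (!"item_id" %in% names(pairs))
    pairs$item_id <- as.character(seq_len(nrow(pairs)))
  out <- lapply(seq_along(scale_factors), function(i) {
    s <- scale_factors[i]
    a <- pairs
    a$vc <- categorizeVolume(s * a$vc)
    a$weight_g <- s * a$weight_g
    a$augmented <- TRUE
    a$source_item_id <- a$item_id
    a$item_id <- paste0(a$item_id, "_aug", i)
    a
  })
  do.call(rbind, out)
}

#' Consumed portion from start and end frames
#'
#' Consumed portion size is the net difference between the predicted food
#' weight at the designated start and end frames of an eating episode.
#' Per category: max(0, start - end); a category present at start but
#' undetected at the end is counted as fully consumed; a category absent
#' at start is excluded with a warning.
#'
#' @param model A \linkS4class{PortionModel}.
#' @param start_features,end_features Feature records for the start/end
#'   frame (data frame with a \code{category} column, or (list of)
#'   \linkS4class{FeatureVector}).
#' @return Named numeric vector of consumed grams per category.
#' @export
consumedPortion <- function(model, start_features, end_features) {
  asdf <- function(x) {
    if (is(x, "FeatureVector")) x <- list(x)
    if (is.list(x) && !is.data.frame(x)) x <- featureTable(x)
    x
  }
  start_features <- asdf(start_features)
  end_features <- asdf(end_features)
  if (is.null(start_features) || !nrow(start_features))
    stop("missing start frame features")
  ps <- predict(model, start_features)
  names(ps) <- start_features$category
  pe <- numeric(0)
  if (!is.null(end_features) && nrow(end_features)) {
    pe <- predict(model, end_features)
    names(pe) <- end_features$category
  }
  extra <- setdiff(names(pe), names(ps))
  if (length(extra))
    warning("categories absent at start excluded: ",
            paste(extra, collapse = ", "))
  out <- vapply(names(ps), function(cat) {
    e <- if (cat %in% names(pe)) pe[[cat]] else 0
    d <- ps[[cat]] - e
    if (d < 0) {
      warning("end-frame prediction exceeds start for '", cat,
              "'; consumed clipped to 0 g")
      d <- 0
    }
    d
  }, numeric(1))
  out
}

.cvMetrics <- function(y, p, epsilon) {
  abs_err <- abs(y - p)
  ape <- abs(y - p) / abs(y) * 100
  list(mae = mae(y, p),
       mae_ci = confidenceInterval(abs_err),
       accuracy = toleranceAccuracy(y, p, epsilon),
       accuracy_ci = confidenceInterval(as.numeric(abs_err < epsilon)),
       mape = mape(y, p),
       mape_ci = confidenceInterval(ape),
       epsilon = epsilon, n = length(y))
}

.runFolds <- function(pairs, fold, kind, seed, config, augment_scales,
                      epsilon, k) {
  if (!"item_id" %in% names(pairs))
    pairs$item_id <- as.character(seq_len(nrow(pairs)))
  if (!"episode_id" %in% names(pairs)) pairs$episode_id <- ""
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    test <- pairs[fold == f, , drop = FALSE]
    train <- pairs[fold != f, , drop = FALSE]
    if (!is.null(augment_scales)) {
      aug <- augmentVolumeScaling(train, augment_scales)
      # leakage guard: no derivative of a test item may enter training
      stopifnot(!any(aug$source_item_id %in% test$item_id))
      if (!"augmented" %in% names(train)) train$augmented <- FALSE
      train$source_item_id <- NA_character_
      train <- rbind(train, aug[names(train)])
    }
    model <- trainPortionModel(train, kind, seed = seed + f,
                               config = config)
    p <- suppressWarnings(predict(model, test))
    preds[[f]] <- data.frame(item_id = test$item_id,
                             episode_id = test$episode_id,
                             category = test$category %||% "",
                             fold = f, y_true = test$weight_g,
                             y_pred = p, stringsAsFactors = FALSE)
  }
  preds <- do.call(rbind, preds)
  new("CvReport", predictions = preds,
      metrics = .cvMetrics(preds$y_true, preds$y_pred, epsilon),
      kind = kind, folds = as.integer(k))
}

#' k-fold cross-validation of a portion model
#'
#' Shuffled fold assignment derived from \code{seed}; every item is
#' tested exactly once. When \code{augment_scales} is given, volume-weight
#' augmentation is applied to the training folds only, and the absence of
#' any test item's augmented derivative from training is asserted, not
#' assumed.
#'
#' @param pairs Training records (feature columns, \code{weight_g},
#'   optional \code{item_id}, \code{episode_id}, \code{category}).
#' @param k Number of folds (2..n).
#' @param seed Integer seed.
#' @param kind Regressor kind, as in \code{\link{trainPortionModel}}.
#' @param config Hyperparameter overrides.
#' @param augment_scales Optional positive scale factors for training-fold
#'   augmentation.
#' @param epsilon Tolerance (g) for the accuracy metric.
#' @return A \linkS4class{CvReport}.
#' @export
kfoldEvaluate <- function(pairs, k = 15, seed = 1,
                          kind = c("ensemble", "rf", "et", "gb"),
                          config = list(), augment_scales = NULL,
                          epsilon = 60) {
  kind <- match.arg(kind)
  n <- nrow(pairs)
  if (k < 2 || k > n) stop("k must lie in [2, n]; got k=", k, ", n=", n)
  fold <- .withSeed(seed, sample(rep_len(seq_len(k), n)))
  .runFolds(pairs, fold, kind, as.integer(seed), config, augment_scales,
            epsilon, k)
}

#' Leave-one-episode-out cross-validation
#'
#' One fold per eating episode, so training and test items never come
#' from the same video. Adds per-episode MAPE to the report metrics.
#'
#' @inheritParams kfoldEvaluate
#' @return A \linkS4class{CvReport}.
#' @export
leaveOneEpisodeOut <- function(pairs, seed = 1,
                               kind = c("ensemble", "rf", "et", "gb"),
                               config = list(), augment_scales = NULL,
                               epsilon = 60) {
  kind <- match.arg(kind)
  if (!"episode_id" %in% names(pairs))
    stop("pairs must carry an episode_id column")
  eps_ids <- unique(pairs$episode_id)
  if (length(eps_ids) < 2) stop("need at least 2 episodes")
  fold <- match(pairs$episode_id, eps_ids)
  rep <- .runFolds(pairs, fold, kind, as.integer(seed), config,
                   augment_scales, epsilon, length(eps_ids))
  per <- vapply(split(rep@predictions, rep@predictions$episode_id),
                function(d) mape(d$y_true, d$y_pred), numeric(1))
  rep@metrics$per_episode_mape <- per
  rep
}
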