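#' Tolerance accuracy
#'
#' Fraction of predictions whose absolute error is strictly below the
#' tolerance epsilon: mean of 1(|y_i - yhat_i| < eps). Visual portion
#' estimation is inherently coarse, so a prediction within eps grams of
#' the weighed record counts as correct; the default tolerance is 60 g.
#'
#' @param y_true Ground-truth values (weighed food records).
#' @param y_pred Predicted values.
#' @param epsilon Tolerance, > 0; the inequality is strict.
#' @return Fraction in [0, 1].
#' @examples
#' toleranceAccuracy(c(0, 0, 0, 0), c(0, 59.9, 60, 61), 60)  # 0.5
#' @export
toleranceAccuracy <- function(y_true, y_pred, epsilon = 60) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!length(y_true)) stop("empty input")
  if (epsilon <= 0) stop("epsilon must be > 0")
  mean(abs(y_true - y_pred) < epsilon)
}

#' Mean absolute percentage error (MAPE)
#'
#' (1/M) sum |y_i - yhat_i| / |y_i| x 100, with y the ground truth
#' (weighed food record).
#'
#' @param y_true Ground-truth values; must all be non-zero.
#' @param y_pred Predicted values.
#' @return MAPE in percent.
#' @export
mape <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!length(y_true)) stop("empty input")
  z <- which(y_true == 0)
  if (length(z))
    stop("zero ground-truth value at item ", z[1],
         "; percentage error is undefined")
  mean(abs(y_true - y_pred) / abs(y_true)) * 100
}

#' Mean absolute error
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return Mean |y_i - yhat_i| (grams or cm^3, per caller).
#' @export
mae <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!length(y_true)) stop("empty input")
  mean(abs(y_true - y_pred))
}

#' Normal-approximation confidence interval of a mean
#'
#' mean +/- z * SD / sqrt(n); z = 1.96 at the default 95% level. Used to
#' report per-item error metrics with their sampling uncertainty.
#'
#' @param per_item_values Numeric vector, n >= 2.
#' @param level Confidence level.
#' @return Named vector \code{c(low, high)}.
#' @export
confidenceInterval <- function(per_item_values, level = 0.95) {
  n <- length(per_item_values)
  if (n < 2) stop("need at least 2 values for a confidence interval")
  z <- stats::qnorm((1 + level) / 2)
  m <- mean(per_item_values)
  half <- z * stats::sd(per_item_values) / sqrt(n)
  c(low = m - half, high = m + half)
}

#' Bland-Altman limits of agreement
#'
#' Agreement between two paired measurement (error) series: bias is the
#' mean difference and the limits of agreement are bias +/- 1.96 SD of
#' the differences; about 95% of paired differences are expected to fall
#' inside the band when differences are roughly normal.
#'
#' @param errors_a,errors_b Paired, equal-length numeric vectors.
#' @return Object of class \code{AgreementResult}: \code{bias},
#'   \code{loa_low}, \code{loa_high}, \code{sd_diff}, the paired
#'   \code{differences} and \code{means}.
#' @export
blandAltman <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b)) stop("length mismatch")
  d <- errors_a - errors_b
  s <- if (length(d) > 1) stats::sd(d) else 0
  structure(list(bias = mean(d), loa_low = mean(d) - 1.96 * s,
                 loa_high = mean(d) + 1.96 * s, sd_diff = s,
                 differences = d, means = (errors_a + errors_b) / 2),
            class = "AgreementResult")
}

#' @export
print.AgreementResult <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, LOA [%.3f, %.3f] (n=%d)\n",
              x$bias, x$loa_low, x$loa_high, length(x$differences)))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x An \code{AgreementResult}.
#' @return A ggplot object (requires ggplot2).
#' @export
blandAltmanPlot <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- data.frame(mean = x$means, difference = x$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = x$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(x$loa_low, x$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of paired errors",
                  y = "Difference between methods")
}

#' The six-feature grouping of the model columns
#'
#' Permutation importance is reported per handcrafted feature, so the 15
#' one-hot food-type columns are permuted jointly as one FT group.
#'
#' @return Named list mapping feature names to column names.
#' @export
featureGroups <- function() {
  list(ft = paste0("ft_", 0:14), frr = "frr", vc = "vc", np = "np",
       par = "par", awr = "awr")
}

.predictAny <- function(model, X) {
  if (is(model, "PortionModel")) suppressWarnings(predict(model, X))
  else if (is.function(model)) model(X)
  else stop("model must be a PortionModel or a prediction function")
}

#' Permutation feature importance (mean decrease accuracy)
#'
#' For each feature (group) k, the importance is
#' i_k = s - (1/M) sum_m s_{m,k}: the baseline score s minus the mean
#' score after randomly permuting the feature's column(s) across samples,
#' over M repetitions. Permuting a feature the model does not use leaves
#' the score unchanged (importance exactly 0); important features cause a
#' large score drop.
#'
#' @param model A fitted \linkS4class{PortionModel}, or a function
#'   mapping a feature table to predictions.
#' @param X Feature records (data frame).
#' @param y Ground-truth weights.
#' @param scorer Function \code{(model, X, y) -> score}; higher is
#'   better. Default: tolerance accuracy at 60 g.
#' @param M Number of permutation repetitions.
#' @param seed Integer seed for the permutations.
#' @param groups Named list of column groups to permute jointly; default
#'   \code{\link{featureGroups}} when the columns are present, else one
#'   group per column.
#' @return Object of class \code{ImportanceResult}: \code{importances}
#'   (named, i_k), \code{baseline} (s), \code{shuffled} (M x K matrix of
#'   s_{m,k}) and \code{M}.
#' @export
permutationImportance <- function(model, X, y, scorer = NULL, M = 20,
                                  seed = 1, groups = NULL) {
  if (M < 1) stop("M must be >= 1")
  if (is.null(scorer))
    scorer <- function(model, X, y)
      toleranceAccuracy(y, .predictAny(model, X), 60)
  if (is.null(groups)) {
    groups <- if (all(unlist(featureGroups()) %in% names(X)))
      featureGroups()
    else setNames(as.list(names(X)), names(X))
  }
  s <- scorer(model, X, y)
  if (!is.finite(s)) stop("scorer returned a non-finite baseline score")
  n <- nrow(X)
  shuffled <- matrix(NA_real_, M, length(groups),
                     dimnames = list(NULL, names(groups)))
  .withSeed(seed, {
    for (m in seq_len(M)) {
      for (k in seq_along(groups)) {
        idx <- sample.int(n)
        Xp <- X
        Xp[groups[[k]]] <- X[idx, groups[[k]], drop = FALSE]
        sk <- scorer(model, Xp, y)
        if (!is.finite(sk)) stop("scorer returned a non-finite score")
        shuffled[m, k] <- sk
      }
    }
  })
  structure(list(importances = s - colMeans(shuffled), baseline = s,
                 shuffled = shuffled, M = M),
            class = "ImportanceResult")
}

#' @export
print.ImportanceResult <- function(x, ...) {
  cat("Permutation importance (baseline score ",
      sprintf("%.4f", x$baseline), ", M=", x$M, "):\n", sep = "")
  imp <- sort(x$importances, decreasing = TRUE)
  for (k in names(imp)) cat(sprintf("  %-4s %.4f\n", k, imp[[k]]))
  invisible(x)
}
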