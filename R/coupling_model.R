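## Gaze -> posture predictive coupling: random-forest regression with
## repeated out-of-bag permutation importance, quartile-threshold feature
## selection, and leave-one-out prediction of the postural score.
##
## The importance of biomarker i is Imp_i = dbar_i / sigma_i, where d is the
## out-of-bag squared-error change after permuting biomarker i, taken over
## the trees that used i; sigma_i = 0 maps to Imp_i = 0. The procedure is
## run five times and a biomarker is selected when the lower quartile of its
## five Imp values exceeds the threshold (default 0.1).

#' Random-forest configuration
#'
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split; `NULL` means `ceiling(p / 3)`.
#' @param min_leaf Minimum observations per leaf (default 2).
#' @param seed Integer seed.
#' @return A `forest_config` list.
#' @export
forest_config <- function(n_trees = 500, mtry = NULL, min_leaf = 2,
                          seed = 1) {
  if (!is_count(n_trees) || !is_count(min_leaf))
    stopf("n_trees and min_leaf must be counts >= 1")
  if (!is.null(mtry) && !is_count(mtry)) stopf("mtry must be a count or NULL")
  structure(list(n_trees = n_trees, mtry = mtry, min_leaf = min_leaf,
                 seed = seed),
            class = "forest_config")
}

resolve_mtry <- function(cfg, p) {
  m <- cfg$mtry
  if (is.null(m)) m <- ceiling(p / 3)
  min(max(1L, as.integer(m)), p)
}

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X
}

#' Fit a regression random forest
#'
#' Bootstrap-resampled CART regression trees with `mtry` feature subsampling,
#' grown to `min_leaf`. Deterministic given `cfg$seed`.
#'
#' @param X Numeric matrix or data frame (subjects x features), no missing
#'   values.
#' @param y Numeric response.
#' @param cfg A [forest_config()].
#' @return An `rf_model` (opaque list of trees plus in-bag counts).
#' @export
rf_fit <- function(X, y, cfg = forest_config()) {
  X <- as_feature_matrix(X)
  if (anyNA(X) || anyNA(y)) stopf("missing values must be imputed upstream")
  if (nrow(X) != length(y)) stopf("nrow(X) must equal length(y)")
  set.seed(cfg$seed)
  fit <- cpp_rf_grow(X, as.numeric(y), cfg$n_trees,
                     resolve_mtry(cfg, ncol(X)), cfg$min_leaf)
  structure(c(fit, list(features = colnames(X), cfg = cfg)),
            class = "rf_model")
}

#' Predict from a fitted forest
#'
#' @param object An `rf_model`.
#' @param newdata Matrix or data frame with the training features.
#' @param ... Unused.
#' @return Numeric vector of predictions (mean over trees).
#' @export
predict.rf_model <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  X <- X[, object$features, drop = FALSE]
  cpp_rf_predict(object[c("trees", "inbag")], X)
}

#' Importance statistic from per-tree error changes
#'
#' `Imp = mean(d) / sd(d)`, with the convention that fewer than two values
#' or a zero standard deviation give 0.
#'
#' @param d Numeric vector of per-tree out-of-bag error changes.
#' @return Scalar importance.
#' @export
importance_from_d <- function(d) {
  if (length(d) < 2) return(0)
  s <- sd(d)
  if (!is.finite(s) || s == 0) return(0)
  mean(d) / s
}

#' Repeated out-of-bag permutation importance
#'
#' For each run: a bootstrap forest is grown; for every tree and every
#' feature that tree used, `d` is the tree's out-of-bag mean squared error
#' after permuting that feature minus its baseline; the run's importance of
#' feature i is `mean(d_i) / sd(d_i)` over trees that used i (0 when the SD
#' is 0). Runs use seeds `cfg$seed + 0 .. n_runs - 1`. A feature is selected
#' when the lower quartile (linear-interpolation quantile) of its per-run
#' importances exceeds `threshold`.
#'
#' @param X Feature matrix/data frame (no missing values; >= 5 subjects).
#' @param y Postural scores (must not be constant).
#' @param cfg A [forest_config()].
#' @param n_runs Number of repetitions (default 5).
#' @param threshold Selection threshold on the lower quartile (default 0.1).
#' @return An `importance_result`: list with `imp_runs` (features x runs
#'   matrix), `quartile25`, `selected` (logical), `threshold`, `seeds`.
#' @export
oob_permutation_importance <- function(X, y, cfg = forest_config(),
                                       n_runs = 5, threshold = 0.1) {
  X <- as_feature_matrix(X)
  if (nrow(X) < 5) stopf("need at least 5 subjects")
  if (anyNA(X) || anyNA(y)) stopf("missing values must be imputed upstream")
  if (length(unique(y)) < 2) stopf("degenerate target: y is constant")
  p <- ncol(X)
  seeds <- cfg$seed + seq_len(n_runs) - 1
  imp <- matrix(NA_real_, p, n_runs,
                dimnames = list(colnames(X), paste0("run", seq_len(n_runs))))
  for (r in seq_len(n_runs)) {
    set.seed(seeds[r])
    forest <- cpp_rf_grow(X, as.numeric(y), cfg$n_trees,
                          resolve_mtry(cfg, p), cfg$min_leaf)
    d_list <- cpp_rf_oob_permutation_d(forest, X, as.numeric(y))
    imp[, r] <- vapply(d_list, importance_from_d, 0.0)
  }
  q25 <- apply(imp, 1, quantile, probs = 0.25, type = 7, names = FALSE)
  structure(list(imp_runs = imp, quartile25 = q25,
                 selected = q25 > threshold, threshold = threshold,
                 seeds = seeds),
            class = "importance_result")
}

#' Select features by the quartile-threshold rule
#'
#' @param imp An `importance_result`.
#' @param threshold Strict lower bound on the lower quartile (default 0.1).
#' @return Character vector of selected feature names.
#' @export
select_features <- function(imp, threshold = 0.1) {
  stopifnot(inherits(imp, "importance_result"))
  q25 <- apply(imp$imp_runs, 1, quantile, probs = 0.25, type = 7,
               names = FALSE)
  rownames(imp$imp_runs)[q25 > threshold]
}

#' Prediction accuracy metrics (normalised RMSE)
#'
#' `rmse_norm` is the root-mean-square residual divided by the score range
#' (100); `rmse_norm_excl` recomputes it after removing the single largest
#' absolute residual (first index on ties).
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @param subject_id Optional identifiers.
#' @return List with `rmse_norm`, `rmse_norm_excl`, `excluded_subject`,
#'   `excluded_index`.
#' @export
prediction_metrics <- function(observed, predicted, subject_id = NULL) {
  stopifnot(length(observed) == length(predicted))
  res <- observed - predicted
  rmse_norm <- sqrt(mean(res^2)) / 100
  i_max <- which.max(abs(res))
  rmse_norm_excl <- if (length(res) > 1)
    sqrt(mean(res[-i_max]^2)) / 100 else rmse_norm
  list(rmse_norm = rmse_norm, rmse_norm_excl = rmse_norm_excl,
       excluded_subject = if (!is.null(subject_id)) subject_id[i_max]
                          else NA_character_,
       excluded_index = i_max)
}

#' Leave-one-out random-forest prediction of the postural score
#'
#' Each subject is predicted by a forest trained on the other N - 1 only
#' (fold seeds `cfg$seed + fold`). Predictions are clipped to `[0, 100]`
#' (any clipping is recorded in the result).
#'
#' @param X Feature matrix/data frame (>= 3 subjects, no missing values).
#' @param y Observed postural scores.
#' @param cfg A [forest_config()].
#' @param features Optional character subset of features to use.
#' @param subject_id Optional identifiers.
#' @return A `prediction_result`: list with `table` (subject_id, observed,
#'   predicted), `rmse_norm`, `rmse_norm_excl`, `excluded_subject`,
#'   `n_clipped`.
#' @export
loo_predict <- function(X, y, cfg = forest_config(), features = NULL,
                        subject_id = NULL) {
  X <- as_feature_matrix(X)
  n <- nrow(X)
  if (n < 3) stopf("need at least 3 subjects")
  if (anyNA(X) || anyNA(y)) stopf("missing values must be imputed upstream")
  if (!is.null(features)) {
    unknown <- setdiff(features, colnames(X))
    if (length(unknown) > 0)
      stopf("unknown feature(s): %s", paste(unknown, collapse = ", "))
    X <- X[, features, drop = FALSE]
  }
  if (is.null(subject_id)) subject_id <- as.character(seq_len(n))
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + i
    fit <- rf_fit(X[-i, , drop = FALSE], y[-i], fold_cfg)
    pred[i] <- predict(fit, X[i, , drop = FALSE])
  }
  n_clipped <- sum(pred < 0 | pred > 100)
  pred <- pmin(100, pmax(0, pred))
  m <- prediction_metrics(y, pred, subject_id)
  structure(list(table = data.frame(subject_id = subject_id, observed = y,
                                    predicted = pred,
                                    stringsAsFactors = FALSE),
                 rmse_norm = m$rmse_norm,
                 rmse_norm_excl = m$rmse_norm_excl,
                 excluded_subject = m$excluded_subject,
                 n_clipped = n_clipped),
            class = "prediction_result")
}
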