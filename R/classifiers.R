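#' Train the gradient-boosted tree classifier on temporal features
#'
#' A thin, seeded wrapper around xgboost with a logistic objective.
#' Defaults: 200 trees of depth 3 at learning rate 0.1, single-threaded so
#' training is deterministic given the seed.
#'
#' @param x numeric feature matrix (n x p), column names kept as the feature
#'   manifest.
#' @param y 0/1 labels.
#' @param nrounds,max_depth,eta boosting hyperparameters.
#' @param seed RNG seed.
#' @return List of class `gbt_fit`: `model`, `feature_names`.
#' @export
train_gbt <- function(x, y, nrounds = 200, max_depth = 3, eta = 0.1,
                      seed = 1) {
  if (length(unique(y)) < 2L)
    stop("need both classes to train a classifier")
  x <- as.matrix(x)
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  model <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0)
  structure(list(model = model, feature_names = colnames(x)),
            class = "gbt_fit")
}

#' Predict probabilities from a fitted GBT
#' @param fit a `gbt_fit`.
#' @param x feature matrix with the training columns.
#' @return Probabilities in (0, 1).
#' @export
predict_gbt <- function(fit, x) {
  x <- as.matrix(x)
  if (!is.null(fit$feature_names) && !is.null(colnames(x)))
    x <- x[, fit$feature_names, drop = FALSE]
  stats::predict(fit$model, xgboost::xgb.DMatrix(x, nthread = 1))
}

#' Train the stacked ensemble (RNN probability as a 96th feature)
#'
#' Within the training set, the RNN is fitted on internal grouped splits so
#' that every training scan receives an out-of-split connectivity
#' probability; that probability is appended to the 95 temporal features and
#' the GBT is fitted on the augmented table.  A final RNN fitted on the full
#' training set supplies the connectivity probability at prediction time
#' (RNN first, then GBT).
#'
#' @param x n x 95 temporal feature matrix.
#' @param sequences list of n connectivity-vector matrices, same order.
#' @param y 0/1 labels.
#' @param groups grouping factor (participant ids) for the internal split.
#' @param rnn_cfg an [rnn_config()].
#' @param inner_k internal folds for the out-of-split RNN probabilities.
#' @param nrounds,max_depth,eta GBT hyperparameters.
#' @param seed seed driving the internal split and both learners.
#' @return List of class `impairment_model`: `gbt`, `rnn`, `feature_names`,
#'   `train_keys`, `seed`.
#' @export
train_ensemble <- function(x, sequences, y, groups = NULL,
                           rnn_cfg = rnn_config(), inner_k = 3,
                           nrounds = 200, max_depth = 3, eta = 0.1,
                           seed = 1) {
  x <- as.matrix(x)
  if (length(sequences) != nrow(x))
    stop("missing connectivity sequences for scan(s): ",
         paste(utils::head(setdiff(rownames(x), names(sequences)), 5),
               collapse = ", "))
  if (is.null(groups)) groups <- rownames(x)
  if (is.null(groups)) groups <- as.character(seq_len(nrow(x)))
  folds <- stratified_repeated_kfold(seq_len(nrow(x)), y, k = inner_k,
                                     repeats = 1, seed = seed + 1L,
                                     groups = groups)[[1]]
  oof <- numeric(nrow(x))
  for (f in sort(unique(folds))) {
    tr <- which(folds != f); te <- which(folds == f)
    cfg <- rnn_cfg; cfg$seed <- seed + f
    fit_f <- train_rnn(sequences[tr], y[tr], cfg)
    oof[te] <- rnn_predict(fit_f, sequences[te])
  }
  cfg <- rnn_cfg; cfg$seed <- seed
  rnn_full <- train_rnn(sequences, y, cfg)
  x_aug <- cbind(x, rnn_prob = oof)
  gbt <- train_gbt(x_aug, y, nrounds, max_depth, eta, seed)
  structure(list(gbt = gbt, rnn = rnn_full,
                 feature_names = colnames(x_aug),
                 train_keys = rownames(x), seed = seed),
            class = "impairment_model")
}

#' Predict with the stacked ensemble
#' @param bundle an `impairment_model`.
#' @param x n x 95 feature matrix.
#' @param sequences list of n connectivity-vector matrices, same order.
#' @return Scan-level impairment probabilities.
#' @export
predict_ensemble <- function(bundle, x, sequences) {
  x <- as.matrix(x)
  if (length(sequences) != nrow(x))
    stop("each scan needs both a feature row and a connectivity sequence")
  p_rnn <- rnn_predict(bundle$rnn, sequences)
  predict_gbt(bundle$gbt, cbind(x, rnn_prob = p_rnn))
}

#' @export
print.impairment_model <- function(x, ...) {
  cat("<impairment_model> stacked RNN + GBT, ",
      length(x$feature_names), " predictors, trained on ",
      length(x$train_keys), " scans\n", sep = "")
  invisible(x)
}
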