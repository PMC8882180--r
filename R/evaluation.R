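#' Stratified, participant-grouped repeated k-fold assignments
#'
#' Per repeat, partitions the keys into k test folds, stratifying by class
#' so per-fold class counts differ from proportional by at most one group,
#' and keeping all keys of one group (participant) in the same fold so
#' within-subject signal can never leak across the split.
#'
#' @param keys identifiers to split (any vector).
#' @param labels 0/1 (or two-level) labels, one per key.
#' @param k number of folds.
#' @param repeats number of independent repeats.
#' @param seed RNG seed.
#' @param groups grouping factor (e.g. participant id); defaults to one
#'   group per key.  A group's stratum is its majority label.
#' @return List of length `repeats`; each element an integer fold id per key
#'   (named by key).
#' @export
stratified_repeated_kfold <- function(keys, labels, k = 5, repeats = 5,
                                      seed = 1, groups = NULL) {
  n <- length(keys)
  stopifnot(length(labels) == n)
  if (is.null(groups)) groups <- as.character(seq_len(n))
  groups <- as.character(groups)
  glab <- vapply(split(as.character(labels), groups), function(v)
    names(sort(table(v), decreasing = TRUE))[1], character(1))
  for (cl in unique(glab))
    if (sum(glab == cl) < k)
      stop("class ", cl, " has only ", sum(glab == cl),
           " group(s), fewer than k = ", k)
  set.seed(seed)
  out <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    gfold <- integer(length(glab)); names(gfold) <- names(glab)
    for (cl in unique(glab)) {
      g <- sample(names(glab)[glab == cl])
      gfold[g] <- rep_len(sample(k), length(g))
    }
    fold <- gfold[groups]
    names(fold) <- as.character(keys)
    out[[r]] <- fold
  }
  out
}

#' Confusion counts from binary predictions
#' @param pred predicted 0/1 labels.
#' @param truth true 0/1 labels.
#' @return List with tp, fp, tn, fn.
#' @export
confusion_counts <- function(pred, truth) {
  list(tp = sum(pred == 1 & truth == 1), fp = sum(pred == 1 & truth == 0),
       tn = sum(pred == 0 & truth == 0), fn = sum(pred == 0 & truth == 1))
}

#' Rank-statistic AUC with tie averaging
#'
#' The Mann-Whitney estimate: probability a random positive outranks a
#' random negative, ties counted half.  Invariant under strictly monotone
#' transforms of the scores.
#'
#' @param probs numeric scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`, or NA if a class is absent.
#' @export
auc_rank <- function(probs, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probs)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from confusion counts
#'
#' accuracy = (tp+tn)/n, PPV = tp/(tp+fp), FPR = fp/(fp+tn),
#' sensitivity = tp/(tp+fn), specificity = tn/(tn+fp); AUC from the rank
#' statistic when probabilities are supplied.  Metrics with a zero
#' denominator are returned as NA and listed in `undefined` rather than
#' failing silently.  On an all-negative set accuracy + FPR = 1 exactly.
#'
#' @param cc confusion counts (list with tp, fp, tn, fn).
#' @param probabilities optional scores for AUC.
#' @param labels 0/1 labels matching `probabilities`.
#' @return List of class `metrics`: accuracy, ppv, fpr, sensitivity,
#'   specificity, auc, n, undefined.
#' @export
compute_metrics <- function(cc, probabilities = NULL, labels = NULL) {
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(cc)))
  if (any(unlist(cc[c("tp", "fp", "tn", "fn")]) < 0))
    stop("confusion counts must be non-negative")
  n <- cc$tp + cc$fp + cc$tn + cc$fn
  if (n == 0) stop("empty confusion table")
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(accuracy = (cc$tp + cc$tn) / n,
              ppv = safe(cc$tp, cc$tp + cc$fp),
              fpr = safe(cc$fp, cc$fp + cc$tn),
              sensitivity = safe(cc$tp, cc$tp + cc$fn),
              specificity = safe(cc$tn, cc$tn + cc$fp),
              auc = if (!is.null(probabilities))
                auc_rank(probabilities, labels) else NA_real_,
              n = n)
  out$undefined <- names(out)[vapply(out, function(v)
    length(v) == 1 && is.na(v), logical(1))]
  class(out) <- "metrics"
  out
}

#' One-tailed exact binomial test against the null-information rate
#'
#' `p = P(X >= n_correct)` for `X ~ Binomial(n_total, nir)`: the probability
#' of doing at least this well by classifying at chance.
#'
#' @param n_correct correct classifications observed.
#' @param n_total classifications made.
#' @param nir null-information rate (majority-class proportion) in (0, 1).
#' @return One-tailed p-value.
#' @export
binomial_test_vs_nir <- function(n_correct, n_total, nir) {
  if (n_total < 1 || n_correct < 0 || n_correct > n_total)
    stop("need 0 <= n_correct <= n_total with n_total >= 1")
  if (nir <= 0 || nir >= 1) stop("nir must lie in (0, 1)")
  stats::pbinom(n_correct - 1, n_total, nir, lower.tail = FALSE)
}

#' Two-sample test of proportions (pooled z)
#'
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with the pooled proportion
#' `p = (x1 + x2)/(n1 + n2)`.
#'
#' @param x1,n1 successes and trials in sample 1.
#' @param x2,n2 successes and trials in sample 2.
#' @return List: z, p_one_sided (for p1 > p2), p_two_sided.
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop("successes must lie within [0, n]")
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z,
       p_one_sided = stats::pnorm(z, lower.tail = FALSE),
       p_two_sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Select the best cross-validated candidate
#'
#' Minimizes the mean over folds of FPR divided by the true negative rate
#' (which, since FPR/TNR = FPR/(1-FPR) is increasing in FPR, prefers the
#' lowest false-positive model).  Ties break toward higher pooled accuracy,
#' then lexicographically smaller candidate id.
#'
#' @param candidates list of candidates, each with `id`, `fold_fpr`,
#'   `fold_tnr` (per-fold vectors) and `accuracy`.
#' @return The selected candidate.
#' @export
select_model <- function(candidates) {
  if (length(candidates) == 0L) stop("no candidates")
  score <- vapply(candidates, function(cand) {
    ok <- cand$fold_tnr > 0
    if (!any(ok)) return(Inf)
    mean(cand$fold_fpr[ok] / cand$fold_tnr[ok])
  }, numeric(1))
  if (all(!is.finite(score))) stop("all candidates have zero TNR")
  acc <- vapply(candidates, function(cand) cand$accuracy, numeric(1))
  ids <- vapply(candidates, function(cand) as.character(cand$id),
                character(1))
  ord <- order(score, -acc, ids)
  candidates[[ord[1]]]
}

#' Cross-validate a classifier on a labeled cohort
#'
#' Repeated stratified participant-grouped k-fold: per fold, the requested
#' model is trained on the training portion only and scored on the held-out
#' fold; probabilities and confusion counts are pooled over folds
#' (micro-average) and per-fold metrics kept alongside.  NIR is the
#' majority-class proportion; the pooled accuracy is tested against it with
#' the one-tailed exact binomial test.
#'
#' @param x n x 95 feature matrix (rownames = scan keys).
#' @param sequences list of n connectivity-vector matrices (for rnn and
#'   ensemble models).
#' @param y 0/1 labels.
#' @param groups participant ids, one per row.
#' @param model `"ensemble"`, `"gbt"` or `"rnn"`.
#' @param k,repeats folds and repeats.
#' @param seed RNG seed.
#' @param threshold probability cut for the positive class.
#' @param rnn_cfg an [rnn_config()] for the connectivity learner.
#' @param nrounds,max_depth,eta GBT hyperparameters.
#' @return List of class `cv_result`: `probs`, `truth`, `fold_metrics`
#'   (per repeat x fold data.frame), `pooled` (metrics), `nir`,
#'   `binomial_p`, `folds`, `model`, `seed`.
#' @export
cross_validate <- function(x, sequences = NULL, y, groups,
                           model = c("ensemble", "gbt", "rnn"),
                           k = 5, repeats = 5, seed = 1, threshold = 0.5,
                           rnn_cfg = rnn_config(),
                           nrounds = 200, max_depth = 3, eta = 0.1) {
  model <- match.arg(model)
  x <- as.matrix(x)
  n <- nrow(x)
  folds <- stratified_repeated_kfold(seq_len(n), y, k, repeats, seed, groups)
  probs <- matrix(NA_real_, n, repeats)
  fold_rows <- list()
  pooled_cc <- list(tp = 0, fp = 0, tn = 0, fn = 0)
  for (r in seq_len(repeats)) {
    for (f in sort(unique(folds[[r]]))) {
      tr <- which(folds[[r]] != f); te <- which(folds[[r]] == f)
      p_te <- switch(model,
        gbt = {
          fit <- train_gbt(x[tr, , drop = FALSE], y[tr], nrounds,
                           max_depth, eta, seed + r * 100 + f)
          predict_gbt(fit, x[te, , drop = FALSE])
        },
        rnn = {
          cfg <- rnn_cfg; cfg$seed <- seed + r * 100 + f
          fit <- train_rnn(sequences[tr], y[tr], cfg)
          rnn_predict(fit, sequences[te])
        },
        ensemble = {
          fit <- train_ensemble(x[tr, , drop = FALSE], sequences[tr],
                                y[tr], groups[tr], rnn_cfg,
                                nrounds = nrounds, max_depth = max_depth,
                                eta = eta, seed = seed + r * 100 + f)
          predict_ensemble(fit, x[te, , drop = FALSE], sequences[te])
        })
      probs[te, r] <- p_te
      cc <- confusion_counts(as.integer(p_te >= threshold), y[te])
      for (nm in names(pooled_cc))
        pooled_cc[[nm]] <- pooled_cc[[nm]] + cc[[nm]]
      m <- compute_metrics(cc, p_te, y[te])
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        repeat_id = r, fold = f, tp = cc$tp, fp = cc$fp, tn = cc$tn,
        fn = cc$fn, accuracy = m$accuracy, fpr = m$fpr,
        tnr = m$specificity, auc = m$auc)
    }
  }
  fold_metrics <- do.call(rbind, fold_rows)
  mean_prob <- rowMeans(probs)
  pooled <- compute_metrics(pooled_cc, rep(as.vector(probs), 1),
                            rep(y, times = repeats))
  nir <- max(mean(y), 1 - mean(y))
  n_correct <- pooled_cc$tp + pooled_cc$tn
  structure(list(probs = probs, mean_prob = mean_prob, truth = y,
                 fold_metrics = fold_metrics, pooled = pooled, nir = nir,
                 n_correct = n_correct, n_total = n * repeats,
                 binomial_p = binomial_test_vs_nir(n_correct, n * repeats,
                                                   nir),
                 folds = folds, model = model, seed = seed,
                 threshold = threshold),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  p <- x$pooled
  cat(sprintf(paste0("<cv_result> %s: accuracy %.1f%%, PPV %.1f%%, FPR ",
                     "%.1f%%, AUC %.3f (NIR %.1f%%, binomial p = %.2g)\n"),
              x$model, 100 * p$accuracy, 100 * p$ppv, 100 * p$fpr, p$auc,
              100 * x$nir, x$binomial_p))
  invisible(x)
}

#' Evaluate a fitted model on a hold-out set
#'
#' Refuses to run when any hold-out participant appeared in training
#' (leakage guard), predicts each hold-out scan, and reports accuracy and
#' FPR; on an all-negative hold-out (the study's "not clearly impaired"
#' scans) accuracy + FPR = 1 by construction.
#'
#' @param bundle an `impairment_model`.
#' @param x hold-out feature matrix (rownames = scan keys).
#' @param sequences hold-out connectivity sequences.
#' @param y true 0/1 labels (all 0 for the not-clearly-impaired set).
#' @param groups participant ids of the hold-out scans; leakage is checked
#'   against the participant part of the training keys.
#' @param threshold probability cut.
#' @return A `metrics` object.
#' @export
evaluate_holdout <- function(bundle, x, sequences, y = rep(0L, nrow(x)),
                             groups = NULL, threshold = 0.5) {
  train_participants <- sub("/.*$", "", bundle$train_keys)
  hold_participants <- if (!is.null(groups)) as.character(groups)
    else sub("/.*$", "", rownames(x))
  overlap <- intersect(train_participants, hold_participants)
  if (length(overlap) > 0L)
    stop("leakage: participant(s) in both training and hold-out: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  p <- predict_ensemble(bundle, x, sequences)
  cc <- confusion_counts(as.integer(p >= threshold), y)
  compute_metrics(cc, p, y)
}
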