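test_that("stratified folds balance classes and partition the keys", {
  keys <- 1:100
  y <- rep(c(1, 0), each = 50)
  folds <- stratified_repeated_kfold(keys, y, k = 5, repeats = 3, seed = 2)
  for (f in folds) {
    expect_setequal(names(f), as.character(keys))
    for (k in 1:5) {
      expect_equal(sum(f == k & y == 1), 10)
      expect_equal(sum(f == k & y == 0), 10)
    }
  }

  # 37 positives / 63 negatives: positives per fold must be 7 or 8
  y2 <- c(rep(1, 37), rep(0, 63))
  f2 <- stratified_repeated_kfold(1:100, y2, k = 5, repeats = 1, seed = 3)[[1]]
  pos_per_fold <- sapply(1:5, function(k) sum(f2 == k & y2 == 1))
  expect_true(all(pos_per_fold %in% c(7, 8)))
  expect_equal(sum(pos_per_fold), 37)

  expect_error(stratified_repeated_kfold(1:10, c(1, rep(0, 9)), k = 5),
               "fewer than k")
})

test_that("participant grouping keeps all scans of a subject together", {
  groups <- rep(sprintf("P%02d", 1:20), each = 3)
  y <- rep(rep(c(1, 0), each = 10), each = 3)
  folds <- stratified_repeated_kfold(seq_along(groups), y, k = 5,
                                     repeats = 2, seed = 5, groups = groups)
  for (f in folds)
    for (g in unique(groups))
      expect_length(unique(f[groups == g]), 1L)
})

test_that("metrics match hand arithmetic and flag undefined ratios", {
  m <- compute_metrics(list(tp = 3, fp = 1, tn = 9, fn = 2))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$fpr, 0.1)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.9)

  perfect <- compute_metrics(list(tp = 5, fp = 0, tn = 5, fn = 0),
                             probabilities = c(rep(0.9, 5), rep(0.1, 5)),
                             labels = rep(c(1, 0), each = 5))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$fpr, 0)
  expect_equal(perfect$auc, 1)

  allneg <- compute_metrics(list(tp = 0, fp = 8, tn = 44, fn = 0))
  expect_equal(allneg$accuracy + allneg$fpr, 1)
  expect_true("ppv" %in% allneg$undefined || allneg$fpr > 0)
  nopos <- compute_metrics(list(tp = 0, fp = 0, tn = 10, fn = 0))
  expect_true(all(c("ppv", "sensitivity") %in% nopos$undefined))
  expect_error(compute_metrics(list(tp = 0, fp = 0, tn = 0, fn = 0)),
               "empty")
})

test_that("AUC is a tie-averaged rank statistic, monotone-invariant", {
  set.seed(71)
  p <- runif(40)
  y <- rbinom(40, 1, 0.5)
  a <- auc_rank(p, y)
  expect_equal(auc_rank(qlogis(p), y), a)
  expect_equal(auc_rank(p^3, y), a)
  skip_if_not_installed("pROC")
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                                 direction = "<"))))
})

test_that("model selection minimizes FPR/TNR with documented tie-breaks", {
  cand <- function(id, fpr, tnr, acc)
    list(id = id, fold_fpr = fpr, fold_tnr = tnr, accuracy = acc)
  sel <- select_model(list(cand("a", 0.2, 0.8, 0.7),
                           cand("b", 0.1, 0.9, 0.7)))
  expect_equal(sel$id, "b")
  sel2 <- select_model(list(cand("a", 0.2, 0.8, 0.7),
                            cand("b", 0.2, 0.8, 0.8)))
  expect_equal(sel2$id, "b")

  # FPR/TNR = FPR/(1-FPR) is increasing, so selection = argmin FPR
  set.seed(72)
  for (i in 1:100) {
    fprs <- runif(5, 0, 0.9)
    cands <- lapply(seq_along(fprs), function(j)
      cand(letters[j], fprs[j], 1 - fprs[j], 0.5))
    expect_equal(select_model(cands)$id, letters[which.min(fprs)])
  }
  expect_error(select_model(list(cand("a", 1, 0, 0.5))), "zero TNR")
})

test_that("the binomial NIR test is the exact upper tail", {
  expect_equal(binomial_test_vs_nir(10, 10, 0.5), 0.5^10)
  expect_gt(binomial_test_vs_nir(5, 10, 0.5), 0.4)
  # enumeration oracle for n <= 20
  set.seed(73)
  for (i in 1:20) {
    n <- sample(1:20, 1); x <- sample(0:n, 1); nir <- runif(1, 0.05, 0.95)
    oracle <- sum(sapply(x:n, function(k)
      choose(n, k) * nir^k * (1 - nir)^(n - k)))
    expect_equal(binomial_test_vs_nir(x, n, nir), oracle, tolerance = 1e-12)
  }
  expect_error(binomial_test_vs_nir(11, 10, 0.5), "n_correct")
  expect_error(binomial_test_vs_nir(5, 10, 1.2), "nir")
})

test_that("two-proportion z-test matches its definition and a resampling
          oracle", {
  same <- two_proportion_test(5, 20, 5, 20)
  expect_equal(same$z, 0)
  expect_equal(same$p_two_sided, 1)

  big <- two_proportion_test(36, 100, 10, 100)
  expect_lt(big$p_one_sided, 0.001)
  # agreement with the uncorrected chi-square test
  pt <- prop.test(c(36, 10), c(100, 100), correct = FALSE)
  expect_equal(big$z^2, unname(pt$statistic), tolerance = 1e-10)

  # permutation oracle on small counts
  set.seed(74)
  x <- c(rep(1, 9), rep(0, 11), rep(1, 3), rep(0, 17))
  grp <- rep(c(1, 2), each = 20)
  obs <- two_proportion_test(9, 20, 3, 20)
  perm <- replicate(4000, {
    g <- sample(grp)
    mean(x[g == 1]) - mean(x[g == 2])
  })
  p_perm <- mean(perm >= (9 / 20 - 3 / 20) - 1e-12)
  expect_lt(abs(obs$p_one_sided - p_perm), 0.03)
})

test_that("cross-validation pools counts consistently over folds", {
  set.seed(75)
  n <- 80
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  x[, 1] <- x[, 1] + rep(c(1.5, 0), each = n / 2)
  y <- rep(c(1, 0), each = n / 2)
  cv <- cross_validate(x, NULL, y, groups = as.character(1:n),
                       model = "gbt", k = 4, repeats = 2, seed = 6,
                       nrounds = 50)
  fm <- cv$fold_metrics
  expect_equal(sum(fm$tp + fm$tn + fm$fp + fm$fn), 2 * n)
  pooled_n <- cv$pooled$n
  expect_equal(pooled_n, 2 * n)
  expect_equal(cv$n_correct, sum(fm$tp + fm$tn))
  # fold test sets partition the data within each repeat
  for (f in cv$folds) expect_setequal(names(f), as.character(1:n))
})

test_that("the hold-out evaluator predicts and guards against leakage", {
  set.seed(76)
  n <- 40
  x <- matrix(rnorm(n * 95), n, 95,
              dimnames = list(paste0("P", 1:n, "/THC/2"),
                              feature_vector_names()))
  y <- rep(c(1, 0), each = n / 2)
  seqs <- lapply(seq_len(n), function(i)
    matrix(rnorm(6 * 12, ifelse(y[i] == 1, 1, -1)), 6, 12))
  bundle <- train_ensemble(x, seqs, y, rnn_cfg = tiny_rnn(input_dim = 12),
                           inner_k = 3, nrounds = 30, seed = 8)

  xh <- matrix(rnorm(10 * 95), 10, 95,
               dimnames = list(paste0("H", 1:10, "/THC/2"),
                               feature_vector_names()))
  seqh <- lapply(1:10, function(i) matrix(rnorm(6 * 12, -1), 6, 12))
  m <- evaluate_holdout(bundle, xh, seqh)
  expect_equal(m$accuracy + m$fpr, 1)

  # same participants in train and hold-out must trip the guard
  xh2 <- xh; rownames(xh2)[1] <- "P1/THC/3"
  expect_error(evaluate_holdout(bundle, xh2, seqh), "leakage")
})
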