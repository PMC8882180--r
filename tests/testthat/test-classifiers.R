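test_that("GBT separates separable features and is seed-deterministic", {
  set.seed(61)
  x <- rbind(matrix(rnorm(50 * 10, 2), 50, 10),
             matrix(rnorm(50 * 10, -2), 50, 10))
  colnames(x) <- paste0("f", 1:10)
  y <- rep(c(1, 0), each = 50)
  fit <- train_gbt(x, y, seed = 5)
  p <- predict_gbt(fit, x)
  expect_equal(as.integer(p >= 0.5), y)
  fit2 <- train_gbt(x, y, seed = 5)
  expect_equal(p, predict_gbt(fit2, x), tolerance = 1e-12)
  expect_error(train_gbt(x, rep(1, 100)), "both classes")
})

test_that("GBT on permuted labels sits at chance", {
  set.seed(62)
  x <- matrix(rnorm(120 * 10), 120, 10)
  colnames(x) <- paste0("f", 1:10)
  y <- sample(rep(c(0, 1), each = 60))
  cv <- cross_validate(x, NULL, y, groups = as.character(1:120),
                       model = "gbt", k = 5, repeats = 1, seed = 3,
                       nrounds = 50)
  # 95% binomial band around chance for n = 120
  expect_lt(abs(cv$pooled$accuracy - 0.5), 1.96 * sqrt(0.25 / 120) + 0.05)
})

test_that("RNN forward pass respects the probabilistic contract", {
  cfg <- rnn_config(input_dim = 6, encoder = c(5, 4), hidden = 3, seed = 2)
  params <- rnn_init(cfg)
  set.seed(3)
  seqs <- lapply(1:4, function(i) matrix(rnorm(5 * 6), 5, 6))
  fw <- rnn_forward(params, seqs)
  expect_true(all(fw$p_window > 0 & fw$p_window < 1))
  expect_true(all(fw$p_scan > 0 & fw$p_scan < 1))
  expect_equal(fw$p_scan, rowMeans(fw$p_window))

  # zero parameters give logistic(0) = 0.5 everywhere
  zero <- rapply(params, function(z) z * 0, how = "replace")
  fw0 <- rnn_forward(zero, seqs)
  expect_true(all(fw0$p_window == 0.5))

  bad <- list(matrix(rnorm(10), 5, 2))
  expect_error(rnn_forward(params, bad), "expects")
})

test_that("analytic RNN gradients match central finite differences", {
  cfg <- rnn_config(input_dim = 5, encoder = c(4, 3), hidden = 3, seed = 3)
  params <- rnn_init(cfg)
  set.seed(9)
  seqs <- list(matrix(rnorm(10), 2, 5), matrix(rnorm(10), 2, 5))
  y <- c(0, 1)
  lg <- nirsimpair:::rnn_loss_grad(params, seqs, y)
  theta <- nirsimpair:::rnn_flatten(params)
  g <- nirsimpair:::rnn_flatten(lg$grads)
  idx <- seq_along(theta)
  num <- vapply(idx, function(i) {
    e <- 1e-6
    tp <- theta; tp[i] <- tp[i] + e
    tm <- theta; tm[i] <- tm[i] - e
    (nirsimpair:::rnn_loss_grad(
       nirsimpair:::rnn_unflatten(tp, params), seqs, y)$loss -
     nirsimpair:::rnn_loss_grad(
       nirsimpair:::rnn_unflatten(tm, params), seqs, y)$loss) / (2 * e)
  }, numeric(1))
  expect_lt(max(abs(num - g) / pmax(1e-6, abs(num) + abs(g))), 1e-5)
})

test_that("RNN training learns separable sequences and is deterministic", {
  set.seed(64)
  mk <- function(mu, n) lapply(seq_len(n),
                               function(i) matrix(rnorm(8 * 12, mu), 8, 12))
  seqs <- c(mk(0.5, 60), mk(-0.5, 60))
  y <- rep(c(1, 0), each = 60)
  tr <- c(1:40, 61:100); te <- setdiff(1:120, tr)
  cfg <- tiny_rnn(input_dim = 12, seed = 5)
  fit <- train_rnn(seqs[tr], y[tr], cfg)
  expect_gt(auc_rank(rnn_predict(fit, seqs[te]), y[te]), 0.9)
  fit2 <- train_rnn(seqs[tr], y[tr], cfg)
  expect_equal(tail(fit$loss_curve, 1), tail(fit2$loss_curve, 1))
  expect_lt(tail(fit$loss_curve, 1), fit$loss_curve[1])
  expect_error(train_rnn(seqs, rep(0, 120), cfg), "both classes")
})

test_that("RNN on permuted labels stays near chance", {
  set.seed(65)
  seqs <- lapply(1:60, function(i) matrix(rnorm(8 * 12), 8, 12))
  y <- sample(rep(c(0, 1), each = 30))
  tr <- 1:40; te <- 41:60
  fit <- train_rnn(seqs[tr], y[tr], tiny_rnn(input_dim = 12, seed = 6))
  auc <- auc_rank(rnn_predict(fit, seqs[te]), y[te])
  # 95% permutation band around 0.5 for 10 vs 10 is roughly +/- 0.37
  expect_gt(auc, 0.13)
  expect_lt(auc, 0.87)
})

test_that("the stacked ensemble augments features with the RNN probability", {
  set.seed(66)
  n <- 60
  x <- matrix(rnorm(n * 95), n, 95,
              dimnames = list(sprintf("s%02d/THC/2", 1:n),
                              feature_vector_names()))
  y <- rep(c(1, 0), each = n / 2)
  # class signal lives only in connectivity
  seqs <- lapply(seq_len(n), function(i)
    matrix(rnorm(8 * 12, ifelse(y[i] == 1, 0.6, -0.6)), 8, 12))
  bundle <- train_ensemble(x, seqs, y, rnn_cfg = tiny_rnn(input_dim = 12),
                           inner_k = 3, nrounds = 50, seed = 7)
  expect_length(bundle$feature_names, 96L)
  expect_equal(bundle$feature_names[96], "rnn_prob")

  set.seed(67)
  x_new <- matrix(rnorm(20 * 95), 20, 95,
                  dimnames = list(NULL, feature_vector_names()))
  y_new <- rep(c(1, 0), each = 10)
  seqs_new <- lapply(seq_len(20), function(i)
    matrix(rnorm(8 * 12, ifelse(y_new[i] == 1, 0.6, -0.6)), 8, 12))
  p_ens <- predict_ensemble(bundle, x_new, seqs_new)
  expect_gt(auc_rank(p_ens, y_new), 0.9)
  # feature-only GBT cannot see the connectivity signal
  gbt_only <- train_gbt(x, y, nrounds = 50, seed = 7)
  auc_gbt <- auc_rank(predict_gbt(gbt_only, x_new), y_new)
  expect_gt(auc_rank(p_ens, y_new), auc_gbt)

  expect_error(train_ensemble(x, seqs[1:10], y), "sequences")
})
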