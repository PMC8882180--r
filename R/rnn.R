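#' Configuration of the recurrent connectivity classifier
#'
#' A feed-forward encoder (tanh layers of 128, 64, 32 and 16 units) maps each
#' 190-value connectivity vector to a latent code; a 64-unit tanh recurrent
#' layer integrates the codes across windows; an affine map plus logistic
#' squashing yields a per-window impairment probability, aggregated (mean by
#' default) into the scan-level probability.  The stated "5 hidden layers,
#' 128/64/32/16 nodes" is read as 4 encoder layers plus the recurrent layer.
#'
#' @param input_dim length of each window vector (190 for 20 channels).
#' @param encoder encoder layer widths.
#' @param hidden recurrent state width.
#' @param epochs full-batch Adam epochs.
#' @param lr learning rate.
#' @param aggregate `"mean"`, `"last"` or `"max"` scan-level aggregation.
#' @param seed RNG seed for weight initialization.
#' @return List of class `rnn_config`.
#' @export
rnn_config <- function(input_dim = 190, encoder = c(128, 64, 32, 16),
                       hidden = 64, epochs = 80, lr = 0.01,
                       aggregate = "mean", seed = 1) {
  stopifnot(input_dim >= 1, all(encoder >= 1), hidden >= 1, epochs >= 1)
  aggregate <- match.arg(aggregate, c("mean", "last", "max"))
  structure(list(input_dim = input_dim, encoder = encoder, hidden = hidden,
                 epochs = epochs, lr = lr, aggregate = aggregate,
                 seed = seed), class = "rnn_config")
}

glorot <- function(nout, nin) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nout * nin, -lim, lim), nout, nin)
}

#' Initialize RNN parameters
#' @param config an [rnn_config()].
#' @param seed RNG seed (defaults to the config's).
#' @return Named list of weight matrices and bias vectors.
#' @export
rnn_init <- function(config, seed = config$seed) {
  set.seed(seed)
  sizes <- c(config$input_dim, config$encoder)
  enc <- lapply(seq_along(config$encoder), function(l)
    list(W = glorot(sizes[l + 1], sizes[l]), b = numeric(sizes[l + 1])))
  h <- config$hidden
  list(enc = enc,
       Wh = glorot(h, h) * 0.5, We = glorot(h, sizes[length(sizes)]),
       bh = numeric(h), w_out = stats::runif(h, -0.1, 0.1), c_out = 0)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# stack sequences (list of T x d matrices, equal T) scan-major into one
# (n*T) x d matrix; row of scan i, time t is (i-1)*T + t
stack_sequences <- function(sequences) {
  Ts <- vapply(sequences, nrow, integer(1))
  if (length(unique(Ts)) != 1L)
    stop("sequences must share the same number of windows (got lengths ",
         paste(unique(Ts), collapse = ", "), ")")
  list(M = do.call(rbind, sequences), T = Ts[1], n = length(sequences))
}

rnn_forward_stack <- function(params, M, n, T, aggregate = "mean",
                              keep_cache = FALSE) {
  Z <- M
  cache_Z <- list(M)
  for (l in seq_along(params$enc)) {
    Z <- tanh(sweep(Z %*% t(params$enc[[l]]$W), 2, params$enc[[l]]$b, "+"))
    cache_Z[[l + 1]] <- Z
  }
  h <- length(params$bh)
  H <- matrix(0, n, h)
  Hs <- vector("list", T)
  P <- matrix(0, n, T)
  for (t in seq_len(T)) {
    Et <- Z[(seq_len(n) - 1L) * T + t, , drop = FALSE]
    H <- tanh(sweep(H %*% t(params$Wh) + Et %*% t(params$We), 2,
                    params$bh, "+"))
    Hs[[t]] <- H
    P[, t] <- sigmoid(H %*% params$w_out + params$c_out)
  }
  p_scan <- switch(aggregate,
                   mean = rowMeans(P),
                   last = P[, T],
                   max = apply(P, 1, max))
  out <- list(p_window = P, p_scan = p_scan)
  if (keep_cache) out$cache <- list(Z = cache_Z, Hs = Hs)
  out
}

#' RNN forward pass
#'
#' Computes per-window and scan-level impairment probabilities for a list of
#' connectivity-vector sequences.  All outputs lie strictly in (0, 1).
#'
#' @param params parameter list from [rnn_init()] or [train_rnn()].
#' @param sequences list of T x input_dim matrices (rows =
#'   [vectorize_windows()] output).
#' @param aggregate scan-level aggregation rule.
#' @return List with `p_window` (n x T matrix) and `p_scan` (length n).
#' @export
rnn_forward <- function(params, sequences, aggregate = "mean") {
  if (is.matrix(sequences)) sequences <- list(sequences)
  din <- ncol(params$enc[[1]]$W)
  bad <- which(vapply(sequences, ncol, integer(1)) != din)
  if (length(bad) > 0L)
    stop("sequence ", bad[1], " has ", ncol(sequences[[bad[1]]]),
         " columns but encoder layer 1 expects ", din)
  Ts <- vapply(sequences, nrow, integer(1))
  p_scan <- numeric(length(sequences))
  p_window <- vector("list", length(sequences))
  for (T in unique(Ts)) {
    idx <- which(Ts == T)
    st <- stack_sequences(sequences[idx])
    fw <- rnn_forward_stack(params, st$M, st$n, T, aggregate)
    p_scan[idx] <- fw$p_scan
    for (j in seq_along(idx)) p_window[[idx[j]]] <- fw$p_window[j, ]
  }
  if (length(unique(Ts)) == 1L)
    p_window <- matrix(unlist(p_window), nrow = length(sequences),
                       byrow = TRUE)
  list(p_window = p_window, p_scan = p_scan)
}

# mean scan-level cross-entropy and analytic gradients (full batch);
# sequences must share T
rnn_loss_grad <- function(params, sequences, y, aggregate = "mean") {
  st <- stack_sequences(sequences)
  n <- st$n; T <- st$T
  fw <- rnn_forward_stack(params, st$M, n, T, aggregate, keep_cache = TRUE)
  p <- pmin(1 - 1e-12, pmax(1e-12, fw$p_scan))
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  P <- fw$p_window
  dpscan <- (p - y) / (p * (1 - p)) / n
  dP <- switch(aggregate,
               mean = matrix(dpscan / T, n, T),
               last = cbind(matrix(0, n, T - 1), dpscan),
               max = {
                 m <- matrix(0, n, T)
                 jmax <- max.col(P, ties.method = "first")
                 m[cbind(seq_len(n), jmax)] <- dpscan
                 m
               })
  da <- dP * P * (1 - P)                       # d loss / d logit
  Hs <- fw$cache$Hs
  h <- length(params$bh)
  gWh <- matrix(0, h, h); gWe <- matrix(0, h, ncol(params$We))
  gbh <- numeric(h); gw <- numeric(h); gc <- 0
  dE <- matrix(0, n * T, ncol(params$We))
  carry <- matrix(0, n, h)
  Zenc <- fw$cache$Z[[length(fw$cache$Z)]]
  for (t in rev(seq_len(T))) {
    Ht <- Hs[[t]]
    gw <- gw + drop(crossprod(Ht, da[, t]))
    gc <- gc + sum(da[, t])
    dH <- outer(da[, t], params$w_out) + carry
    G <- dH * (1 - Ht^2)
    Hprev <- if (t > 1) Hs[[t - 1]] else matrix(0, n, h)
    gWh <- gWh + crossprod(G, Hprev)
    Et <- Zenc[(seq_len(n) - 1L) * T + t, , drop = FALSE]
    gWe <- gWe + crossprod(G, Et)
    gbh <- gbh + colSums(G)
    dE[(seq_len(n) - 1L) * T + t, ] <- G %*% params$We
    carry <- G %*% params$Wh
  }
  genc <- vector("list", length(params$enc))
  dZ <- dE
  for (l in rev(seq_along(params$enc))) {
    Zl <- fw$cache$Z[[l + 1]]
    dpre <- dZ * (1 - Zl^2)
    genc[[l]] <- list(W = crossprod(dpre, fw$cache$Z[[l]]),
                      b = colSums(dpre))
    dZ <- dpre %*% params$enc[[l]]$W
  }
  list(loss = loss,
       grads = list(enc = genc, Wh = gWh, We = gWe, bh = gbh,
                    w_out = gw, c_out = gc))
}

# flatten/unflatten parameter lists for the optimizer and gradient checks
rnn_flatten <- function(params) {
  c(unlist(lapply(params$enc, function(l) c(l$W, l$b)), use.names = FALSE),
    params$Wh, params$We, params$bh, params$w_out, params$c_out)
}

rnn_unflatten <- function(theta, like) {
  pos <- 0L
  take <- function(k) {
    v <- theta[pos + seq_len(k)]; pos <<- pos + k; v
  }
  enc <- lapply(like$enc, function(l) {
    W <- matrix(take(length(l$W)), nrow(l$W), ncol(l$W))
    list(W = W, b = take(length(l$b)))
  })
  list(enc = enc,
       Wh = matrix(take(length(like$Wh)), nrow(like$Wh), ncol(like$Wh)),
       We = matrix(take(length(like$We)), nrow(like$We), ncol(like$We)),
       bh = take(length(like$bh)),
       w_out = take(length(like$w_out)), c_out = take(1))
}

#' Train the recurrent connectivity classifier
#'
#' Minimizes the mean scan-level cross-entropy with full-batch Adam from a
#' seeded initialization; fully deterministic given the seed.  The loss
#' curve is recorded.
#'
#' @param sequences list of T x input_dim window-vector matrices (equal T).
#' @param y 0/1 labels, one per sequence.
#' @param config an [rnn_config()].
#' @return List of class `rnn_fit`: `params`, `loss_curve`, `config`.
#' @export
train_rnn <- function(sequences, y, config = rnn_config()) {
  if (length(unique(y)) < 2L) stop("need both classes to train")
  if (length(sequences) != length(y)) stop("one label per sequence required")
  params <- rnn_init(config)
  theta <- rnn_flatten(params)
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_curve <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    params <- rnn_unflatten(theta, params)
    lg <- rnn_loss_grad(params, sequences, y, config$aggregate)
    if (!is.finite(lg$loss))
      stop("non-finite training loss at epoch ", ep,
           "; lower the learning rate")
    loss_curve[ep] <- lg$loss
    g <- rnn_flatten(lg$grads)
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^ep); vh <- v / (1 - b2^ep)
    theta <- theta - config$lr * mh / (sqrt(vh) + eps)
  }
  structure(list(params = rnn_unflatten(theta, params),
                 loss_curve = loss_curve, config = config),
            class = "rnn_fit")
}

#' Predict scan-level probabilities with a fitted RNN
#' @param fit an `rnn_fit`.
#' @param sequences list of window-vector matrices.
#' @return Numeric vector of scan probabilities in (0, 1).
#' @export
rnn_predict <- function(fit, sequences) {
  rnn_forward(fit$params, sequences, fit$config$aggregate)$p_scan
}
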