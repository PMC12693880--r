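sigmoid <- function(z) 1 / (1 + exp(-z))

#' Feedforward network architecture
#'
#' Fully connected architecture with logistic-sigmoid activation on every
#' hidden layer and on the output layer.  The reference depth for the
#' production soft sensor is 9 hidden layers; tests and examples use
#' shallower nets since depth is configuration, not a constant.
#'
#' @param n_inputs input dimension.
#' @param hidden_widths integer vector of hidden-layer widths (default nine
#'   hidden layers of width 8).
#' @param n_outputs output dimension (default 1).
#' @return object of class `fx_arch`.
#' @export
network_arch <- function(n_inputs, hidden_widths = rep(8L, 9), n_outputs = 1) {
  if (any(hidden_widths < 1) || n_inputs < 1 || n_outputs < 1)
    stop("all layer widths must be >= 1", call. = FALSE)
  structure(list(n_inputs = as.integer(n_inputs),
                 hidden_widths = as.integer(hidden_widths),
                 n_outputs = as.integer(n_outputs),
                 activation = "sigmoid"),
            class = "fx_arch")
}

layer_sizes <- function(arch) {
  c(arch$n_inputs, arch$hidden_widths, arch$n_outputs)
}

#' Initialise network parameters
#'
#' Weights and biases drawn i.i.d. uniform on `(-init_range, init_range)`;
#' the range is itself a tunable hyperparameter searched by the firefly
#' optimizer.
#'
#' @param arch an `fx_arch`.
#' @param init_range half-width of the uniform initialisation interval.
#' @param seed integer seed.
#' @return object of class `fx_net`: list with `weights` (per-layer
#'   out x in matrices), `biases` (per-layer vectors) and `arch`.
#' @export
init_network <- function(arch, init_range = 0.5, seed = 1L) {
  sz <- layer_sizes(arch)
  L <- length(sz) - 1L
  with_seed(seed, {
    W <- vector("list", L)
    b <- vector("list", L)
    for (l in seq_len(L)) {
      W[[l]] <- matrix(stats::runif(sz[l + 1] * sz[l], -init_range,
                                    init_range), sz[l + 1], sz[l])
      b[[l]] <- stats::runif(sz[l + 1], -init_range, init_range)
    }
    structure(list(weights = W, biases = b, arch = arch), class = "fx_net")
  })
}

n_layers <- function(params) length(params$weights)

#' Forward propagation
#'
#' Computes `a^(l) = sigmoid(W^(l) a^(l-1) + b^(l))` layer by layer and
#' returns the network output together with every cached activation (used
#' by backpropagation and by transfer-feature extraction).
#'
#' @param params an `fx_net`.
#' @param X input matrix (samples x n_inputs).
#' @return list with `prediction` (samples x n_outputs) and `activations`
#'   (list of per-layer matrices; element 1 is the input itself).
#' @export
forward <- function(params, X) {
  X <- as.matrix(X)
  if (ncol(X) != params$arch$n_inputs)
    stop("forward: X has wrong number of columns", call. = FALSE)
  L <- n_layers(params)
  A <- vector("list", L + 1L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% t(params$weights[[l]]) +
      matrix(params$biases[[l]], nrow(X), length(params$biases[[l]]),
             byrow = TRUE)
    A[[l + 1]] <- sigmoid(Z)
  }
  list(prediction = A[[L + 1L]], activations = A)
}

#' Training and reporting losses
#'
#' `mse_half_sum` is the half sum-of-squares training loss
#' `E = 1/2 * sum((y - yhat)^2)`; `mse_mean` is the mean squared error used
#' for reporting and fine-tuning.  Both are exposed because the two serve
#' different roles in the method.
#'
#' @param pred,truth equally shaped numeric matrices/vectors.
#' @return scalar loss.
#' @export
mse_half_sum <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth)))
    stop("mse_half_sum: shape mismatch", call. = FALSE)
  0.5 * sum((truth - pred)^2)
}

#' @rdname mse_half_sum
#' @export
mse_mean <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth)))
    stop("mse_mean: shape mismatch", call. = FALSE)
  mean((truth - pred)^2)
}

#' Backpropagation
#'
#' Reverse-mode gradients of the chosen loss through the sigmoid layers.
#' An additional upstream gradient can be injected at the activation of any
#' layer (`extra_grad` at `extra_layer`, counting the input as layer 0);
#' this is how the distribution-alignment (MMD) term contributes gradients
#' through a hidden feature layer during transfer.
#'
#' @param params an `fx_net`.
#' @param X input matrix.
#' @param Y target matrix (may be `NULL` when `loss = "none"`).
#' @param loss one of `"half_sum"` (E = 1/2 sum sq), `"mean"`
#'   (mean squared error) or `"none"` (only the injected gradient).
#' @param extra_grad optional matrix dL/da at layer `extra_layer`.
#' @param extra_layer activation index (0 = input) where `extra_grad`
#'   applies.
#' @return list with `dW`, `db` (same shapes as the parameters) and the
#'   forward `prediction`.
#' @export
backward <- function(params, X, Y = NULL, loss = c("half_sum", "mean", "none"),
                     extra_grad = NULL, extra_layer = NULL) {
  loss <- match.arg(loss)
  fw <- forward(params, X)
  A <- fw$activations
  L <- n_layers(params)
  n <- nrow(A[[1]])
  pred <- fw$prediction
  dA <- switch(loss,
    half_sum = pred - as.matrix(Y),
    mean = 2 * (pred - as.matrix(Y)) / length(pred),
    none = matrix(0, n, ncol(pred)))
  if (!is.null(extra_grad) && !is.null(extra_layer) && extra_layer == L)
    dA <- dA + extra_grad
  dW <- vector("list", L)
  db <- vector("list", L)
  for (l in L:1) {
    act <- A[[l + 1]]
    delta <- dA * act * (1 - act)       # sigmoid'(z) = a (1 - a)
    if (any(!is.finite(delta)))
      stop("backward: non-finite intermediate gradient", call. = FALSE)
    dW[[l]] <- t(delta) %*% A[[l]]
    db[[l]] <- colSums(delta)
    if (l > 1) {
      dA <- delta %*% params$weights[[l]]
      if (!is.null(extra_grad) && !is.null(extra_layer) &&
          extra_layer == l - 1L)
        dA <- dA + extra_grad
    }
  }
  list(dW = dW, db = db, prediction = pred)
}

#' One gradient-descent step with scalar or per-layer learning rates
#'
#' `w <- w - eta * dW`, `b <- b - eta * db` per layer.  A per-layer rate
#' vector implements layer freezing: layers with rate 0 are bit-identical
#' after the step.
#'
#' @param params an `fx_net`.
#' @param grads gradients from [backward()].
#' @param lr scalar learning rate or vector with one rate per layer.
#' @return updated `fx_net`.
#' @export
gd_step <- function(params, grads, lr) {
  L <- n_layers(params)
  if (any(lr < 0)) stop("learning rate must be >= 0", call. = FALSE)
  lr <- rep_len(lr, L)
  for (l in seq_len(L)) {
    if (lr[l] == 0) next               # frozen layer: leave bits untouched
    params$weights[[l]] <- params$weights[[l]] - lr[l] * grads$dW[[l]]
    params$biases[[l]] <- params$biases[[l]] - lr[l] * grads$db[[l]]
  }
  params
}

#' Train by full-batch gradient descent
#'
#' Plain full-batch descent on the half-sum-of-squares loss for a fixed
#' number of epochs; no momentum or adaptive step, matching the update rule
#' of the underlying method.  Targets are expected pre-scaled into the
#' sigmoid's range (see [fit_target_scaler()]).
#'
#' @param params an `fx_net`.
#' @param X,Y training inputs and (scaled) targets.
#' @param epochs number of full-batch epochs.
#' @param lr scalar or per-layer learning rate.
#' @param loss `"half_sum"` (default training loss) or `"mean"` (the
#'   fine-tuning/reporting form); the two differ only by a factor in the
#'   gradient scale.
#' @return list with updated `params` and numeric `loss_history`
#'   (loss after each epoch, in the chosen form).
#' @export
train_network <- function(params, X, Y, epochs, lr,
                          loss = c("half_sum", "mean")) {
  loss <- match.arg(loss)
  if (nrow(as.matrix(X)) == 0) stop("train_network: empty data", call. = FALSE)
  loss_fun <- if (loss == "half_sum") mse_half_sum else mse_mean
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    g <- backward(params, X, Y, loss = loss)
    params <- gd_step(params, g, lr)
    l <- loss_fun(forward(params, X)$prediction, Y)
    if (!is.finite(l))
      stop(sprintf("training diverged at epoch %d (non-finite loss)", ep),
           call. = FALSE)
    history[ep] <- l
  }
  list(params = params, loss_history = history)
}

#' Min-max target scaler into the sigmoid's working range
#'
#' Because the output layer is a sigmoid, unbounded physical targets are
#' mapped linearly into the margin-padded interval `[0.05, 0.95]` fitted on
#' training data only; predictions are inverse-transformed for reporting in
#' physical units.
#'
#' @param Y target matrix/vector (training data only).
#' @param lo,hi padded interval bounds.
#' @return object of class `fx_target_scaler`.
#' @export
fit_target_scaler <- function(Y, lo = 0.05, hi = 0.95) {
  Y <- as.matrix(Y)
  mn <- apply(Y, 2, min)
  mx <- apply(Y, 2, max)
  rg <- mx - mn
  rg[rg == 0] <- 1                      # constant target -> midpoint
  structure(list(min = mn, range = rg, lo = lo, hi = hi),
            class = "fx_target_scaler")
}

#' @rdname fit_target_scaler
#' @param scaler a fitted `fx_target_scaler`.
#' @export
scale_targets <- function(scaler, Y) {
  Y <- as.matrix(Y)
  u <- sweep(sweep(Y, 2, scaler$min), 2, scaler$range, "/")
  scaler$lo + (scaler$hi - scaler$lo) * u
}

#' @rdname fit_target_scaler
#' @export
unscale_targets <- function(scaler, Y) {
  Y <- as.matrix(Y)
  u <- (Y - scaler$lo) / (scaler$hi - scaler$lo)
  sweep(sweep(u, 2, scaler$range, "*"), 2, scaler$min, "+")
}
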