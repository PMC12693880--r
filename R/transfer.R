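#' Transfer plan: layer freezing and fine-tuning settings
#'
#' @param frozen_depth number of layers, counted from the input side, held
#'   frozen (`NA` lets [sequential_unfreeze()] choose it).
#' @param lr_frozen learning rate applied to frozen layers (default 0, the
#'   reproducible limit of "extremely small").
#' @param lr_finetune learning rate for the fine-tuned layers (default
#'   1e-5, the reference fine-tuning rate).
#' @param epochs fine-tuning epochs (default 50).
#' @param mmd_weight non-negative coefficient of the distribution-alignment
#'   (MMD) term in the fine-tuning objective.
#' @param feature_layer activation index feeding the MMD (default: last
#'   hidden layer).
#' @param unfreeze_tol minimum relative validation improvement required to
#'   keep unfreezing further layers.
#' @return object of class `fx_transfer_plan`.
#' @export
transfer_plan <- function(frozen_depth = NA, lr_frozen = 0,
                          lr_finetune = 1e-5, epochs = 50, mmd_weight = 1.0,
                          feature_layer = NULL, unfreeze_tol = 1e-3) {
  if (lr_frozen > lr_finetune)
    stop("lr_frozen must not exceed lr_finetune", call. = FALSE)
  if (epochs < 0) stop("epochs must be >= 0", call. = FALSE)
  if (mmd_weight < 0) stop("mmd_weight must be >= 0", call. = FALSE)
  structure(list(frozen_depth = frozen_depth, lr_frozen = lr_frozen,
                 lr_finetune = lr_finetune, epochs = as.integer(epochs),
                 mmd_weight = mmd_weight, feature_layer = feature_layer,
                 unfreeze_tol = unfreeze_tol),
            class = "fx_transfer_plan")
}

#' Extract hidden-layer features
#'
#' Activations of the requested layer from a forward pass (layer 0 is the
#' input, layer `n_layers` the output), used as the feature space of the
#' MMD alignment.
#'
#' @param params an `fx_net`.
#' @param X input matrix.
#' @param layer activation index, `0..n_layers`.
#' @return feature matrix (samples x layer width).
#' @export
extract_features <- function(params, X, layer) {
  L <- n_layers(params)
  if (layer < 0 || layer > L) stop("invalid feature layer", call. = FALSE)
  forward(params, X)$activations[[layer + 1L]]
}

#' Maximum mean discrepancy (mean-embedding form)
#'
#' Squared Euclidean norm of the difference between the column means of two
#' feature sets: `||mean(Zs) - mean(Zt)||^2`.  Always non-negative, and zero
#' exactly when the feature means coincide.
#'
#' @param Zs,Zt feature matrices with equal column count.
#' @return scalar MMD value.
#' @examples
#' mmd(matrix(c(0, 2), 2), matrix(1, 1))  # means 1 vs 1 -> 0
#' @export
mmd <- function(Zs, Zt) {
  Zs <- as.matrix(Zs); Zt <- as.matrix(Zt)
  if (nrow(Zs) == 0 || nrow(Zt) == 0) stop("mmd: empty feature set",
                                           call. = FALSE)
  if (ncol(Zs) != ncol(Zt)) stop("mmd: feature dimensions differ",
                                 call. = FALSE)
  sum((colMeans(Zs) - colMeans(Zt))^2)
}

#' Per-layer learning rates from a freeze depth
#'
#' Layers `1..k` (input side) receive the frozen rate, layers `k+1..n` the
#' fine-tuning rate.
#'
#' @param n_layers total number of weight layers.
#' @param k frozen depth, `0 <= k <= n_layers`.
#' @param plan an `fx_transfer_plan`.
#' @return numeric vector of per-layer learning rates.
#' @export
freeze_plan <- function(n_layers, k, plan) {
  if (k < 0 || k > n_layers) stop("frozen depth k out of range", call. = FALSE)
  c(rep(plan$lr_frozen, k), rep(plan$lr_finetune, n_layers - k))
}

add_grads <- function(g1, g2) {
  list(dW = Map(`+`, g1$dW, g2$dW), db = Map(`+`, g1$db, g2$db))
}

#' Fine-tune a source model on target data with MMD alignment
#'
#' Full-batch descent on `L = mse_mean(target) + mmd_weight * MMD` where the
#' MMD compares hidden features of the source-domain inputs and the target
#' inputs at `plan$feature_layer`, both flowing through the adapting
#' network.  Per-layer learning rates come from [freeze_plan()], so layers
#' below the frozen depth stay bit-identical when `lr_frozen = 0`.
#'
#' @param params pre-trained `fx_net` (the matched sub-domain model).
#' @param source_X scaled source-domain inputs (feature reference set).
#' @param target_X,target_Y scaled labelled target data.
#' @param plan an `fx_transfer_plan`; `frozen_depth` must be set.
#' @return list with adapted `params` and `history` (data frame with one
#'   row per epoch, including epoch 0: `epoch`, `mse`, `mmd`).
#' @export
fine_tune <- function(params, source_X, target_X, target_Y, plan) {
  L <- n_layers(params)
  k <- plan$frozen_depth
  if (is.na(k)) stop("fine_tune needs plan$frozen_depth; use ",
                     "sequential_unfreeze() to choose it", call. = FALSE)
  lr <- freeze_plan(L, k, plan)
  flayer <- plan$feature_layer %||% (L - 1L)
  nS <- nrow(as.matrix(source_X))
  nT <- nrow(as.matrix(target_X))
  snap <- function(p) {
    Zs <- extract_features(p, source_X, flayer)
    Zt <- extract_features(p, target_X, flayer)
    c(mse = mse_mean(forward(p, target_X)$prediction, target_Y),
      mmd = mmd(Zs, Zt))
  }
  hist <- matrix(NA_real_, plan$epochs + 1L, 2,
                 dimnames = list(NULL, c("mse", "mmd")))
  hist[1, ] <- snap(params)
  for (ep in seq_len(plan$epochs)) {
    g <- backward(params, target_X, target_Y, loss = "mean")
    if (plan$mmd_weight > 0) {
      diff <- colMeans(extract_features(params, source_X, flayer)) -
        colMeans(extract_features(params, target_X, flayer))
      w <- plan$mmd_weight
      gS <- backward(params, source_X, loss = "none",
                     extra_grad = matrix(2 * w * diff / nS, nS,
                                         length(diff), byrow = TRUE),
                     extra_layer = flayer)
      gT <- backward(params, target_X, loss = "none",
                     extra_grad = matrix(-2 * w * diff / nT, nT,
                                         length(diff), byrow = TRUE),
                     extra_layer = flayer)
      g <- add_grads(g, add_grads(gS, gT))
    }
    params <- gd_step(params, g, lr)
    s <- snap(params)
    if (any(!is.finite(s)))
      stop(sprintf("fine-tuning diverged at epoch %d", ep), call. = FALSE)
    hist[ep + 1L, ] <- s
  }
  list(params = params,
       history = data.frame(epoch = 0:plan$epochs, hist))
}

#' Sequential layer-by-layer unfreezing with a validation stopping rule
#'
#' Starts from a fully locked network and unfreezes one layer at a time
#' from the output side toward the input, fine-tuning at each stage and
#' evaluating on a seeded held-out split of the target data.  Unfreezing
#' stops as soon as an additional layer fails to improve validation MSE by
#' at least `plan$unfreeze_tol` (relative).  The same threshold governs
#' which stage is kept: a stage only replaces the incumbent parameters if
#' it beats their validation MSE by more than the threshold, so
#' noise-level fluctuations on small validation sets never switch models
#' and the locked source model is returned unchanged when no stage
#' meaningfully helps.
#'
#' @param params pre-trained `fx_net`.
#' @param source_X scaled source-domain inputs.
#' @param target_X,target_Y scaled labelled target data.
#' @param plan an `fx_transfer_plan`.
#' @param seed seed for the train/validation split.
#' @param val_frac validation fraction (default 0.2).
#' @return list with `params` (best-validation), `k_final` (frozen depth of
#'   the last stage run) and `report` (data frame: stage, frozen depth,
#'   validation MSE).
#' @export
sequential_unfreeze <- function(params, source_X, target_X, target_Y, plan,
                                seed = 1L, val_frac = 0.2) {
  target_X <- as.matrix(target_X); target_Y <- as.matrix(target_Y)
  n <- nrow(target_X)
  n_val <- round(val_frac * n)
  if (n_val < 1 || n - n_val < 1)
    stop("too few target samples to split into train and validation",
         call. = FALSE)
  idx_val <- with_seed(derive_seed(seed, 31), sample.int(n, n_val))
  Xtr <- target_X[-idx_val, , drop = FALSE]
  Ytr <- target_Y[-idx_val, , drop = FALSE]
  Xva <- target_X[idx_val, , drop = FALSE]
  Yva <- target_Y[idx_val, , drop = FALSE]
  L <- n_layers(params)
  val_mse <- function(p) mse_mean(forward(p, Xva)$prediction, Yva)

  best_p <- params
  best_v <- val_mse(params)             # stage 0: all layers locked
  report <- data.frame(stage = 0L, frozen_depth = L, val_mse = best_v)
  prev_v <- best_v
  k_final <- L
  cur <- params
  for (k in seq(L - 1L, 0L)) {
    stage_plan <- plan
    stage_plan$frozen_depth <- k
    ft <- fine_tune(cur, source_X, Xtr, Ytr, stage_plan)
    v <- val_mse(ft$params)
    report <- rbind(report,
                    data.frame(stage = L - k, frozen_depth = k, val_mse = v))
    k_final <- k
    ## only a beyond-threshold boost counts as an improvement worth keeping
    if ((best_v - v) > plan$unfreeze_tol * max(best_v, .Machine$double.eps)) {
      best_v <- v
      best_p <- ft$params
    }
    rel_impr <- (prev_v - v) / max(prev_v, .Machine$double.eps)
    cur <- ft$params
    if (rel_impr < plan$unfreeze_tol) break
    prev_v <- v
  }
  list(params = best_p, k_final = k_final, report = report)
}
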