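#' Root mean squared error
#' @param pred,truth equal-length numeric vectors.
#' @return scalar RMSE.
#' @export
rmse <- function(pred, truth) {
  if (!length(truth) || length(pred) != length(truth))
    stop("rmse: inputs must be equal-length and nonempty", call. = FALSE)
  sqrt(mean((pred - truth)^2))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with the total sum of squares taken about
#' the mean of the observed values.
#'
#' @param pred,truth equal-length numeric vectors; `truth` must not be
#'   constant.
#' @return scalar R-squared (<= 1; can be negative for bad predictions).
#' @export
r2 <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("r2: inputs must be equal length", call. = FALSE)
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0)
    stop("r2 is undefined for constant observed values", call. = FALSE)
  1 - sum((pred - truth)^2) / ss_tot
}

#' Run configuration for the local transfer pipeline
#'
#' Collects the tunables of every stage: augmentation, PCA, clustering, the
#' firefly search, network depth, the transfer plan, the labelled target
#' fraction, and the matching granularity.
#'
#' @param points_per_gap interpolation points per gap for source batches.
#' @param cum_var cumulative explained-variance threshold of the PCA.
#' @param K cluster count, or `"auto"` for elbow selection.
#' @param k_max largest k scanned by the elbow curve.
#' @param n_hidden_layers depth of every sub-model.
#' @param n_fireflies,ifa_iter firefly population and iteration budget.
#' @param encoding hyperparameter search box ([hyperparam_encoding()]).
#' @param plan transfer plan ([transfer_plan()]).
#' @param labeled_frac fraction of the target batch (earliest samples)
#'   treated as labelled for fine-tuning; the remainder is the test set.
#' @param match `"per_sample"` routes every target sample to the sub-model
#'   of its nearest domain centroid; `"batch"` predicts all samples with
#'   the single domain closest in mean distance.  Transfer fine-tuning
#'   always adapts the batch-matched domain's model.
#' @param seed master seed; all stage seeds derive from it.
#' @return object of class `fx_run_config`.
#' @export
run_config <- function(points_per_gap = 2, cum_var = 0.99, K = "auto",
                       k_max = 10, n_hidden_layers = 2, n_fireflies = 6,
                       ifa_iter = 4, encoding = hyperparam_encoding(),
                       plan = transfer_plan(), labeled_frac = 0.25,
                       match = c("per_sample", "batch"), seed = 1L) {
  match <- match.arg(match)
  if (labeled_frac <= 0 || labeled_frac >= 1)
    stop("labeled_frac must be in (0, 1)", call. = FALSE)
  structure(list(points_per_gap = points_per_gap, cum_var = cum_var, K = K,
                 k_max = k_max, n_hidden_layers = n_hidden_layers,
                 n_fireflies = n_fireflies, ifa_iter = ifa_iter,
                 encoding = encoding, plan = plan,
                 labeled_frac = labeled_frac, match = match,
                 seed = as.integer(seed)),
            class = "fx_run_config")
}

## Shared preprocessing: augment source batches, z-score, PCA-project.
## Target batches are never augmented (no leakage into test data).
prep_sources <- function(source_batches, cfg) {
  aug <- lapply(source_batches, augment_batch, points_per_gap =
                  cfg$points_per_gap)
  X <- do.call(rbind, lapply(aug, `[[`, "X_aux"))
  Y <- do.call(rbind, lapply(aug, `[[`, "Y_target"))
  phase <- unlist(lapply(aug, `[[`, "phase_label"))
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  pca <- fit_pca(Xs)
  k_pca <- select_components(pca, cfg$cum_var)
  Xp <- transform_pca(pca, Xs, k_pca)
  y_scaler <- fit_target_scaler(Y)
  list(X = Xp, Y = Y, Ys = scale_targets(y_scaler, Y), phase = phase,
       scaler = scaler, pca = pca, k_pca = k_pca, y_scaler = y_scaler)
}

project_target <- function(prep, batch) {
  transform_pca(prep$pca, apply_scaler(prep$scaler, batch$X_aux), prep$k_pca)
}

## Centre hyperparameters of the search box: the "untuned" reference
## network used by the plain-DNN baseline.
centre_hyperparams <- function(encoding) {
  decode_position(encoding, (encoding$lower + encoding$upper) / 2)
}

train_with_hp <- function(X, y, hp, n_hidden_layers, seed) {
  arch <- network_arch(ncol(X), rep(hp$width, n_hidden_layers), ncol(y))
  net <- init_network(arch, hp$init_range, seed = derive_seed(seed, 29))
  train_network(net, X, y, hp$epochs, hp$lr)$params
}

## Firefly-optimized training of one model on one data set.
tune_and_train <- function(X, y, cfg, seed, variant = "ifa") {
  obj <- make_dnn_objective(X, y, cfg$n_hidden_layers, cfg$encoding,
                            seed = seed)
  icfg <- ifa_config(n_fireflies = cfg$n_fireflies, max_iter = cfg$ifa_iter,
                     bounds = encoding_bounds(cfg$encoding), seed = seed,
                     variant = variant)
  opt <- ifa_optimize(obj, icfg)
  hp <- decode_position(cfg$encoding, opt$best_position)
  list(params = train_with_hp(X, y, hp, cfg$n_hidden_layers, seed),
       hyperparams = hp, search = opt)
}

## Predict scaled targets for projected samples with per-sample or batch
## routing; `nets_by_domain[[k]][[v]]` is the net of domain k, variable v.
route_predict <- function(Xp, route, nets_by_domain, n_var) {
  out <- matrix(NA_real_, nrow(Xp), n_var)
  for (k in sort(unique(route))) {
    idx <- which(route == k)
    for (v in seq_len(n_var))
      out[idx, v] <- forward(nets_by_domain[[k]][[v]],
                             Xp[idx, , drop = FALSE])$prediction[, 1]
  }
  out
}

#' Fit a local transfer soft sensor
#'
#' The end-to-end method: source batches are interpolation-augmented,
#' z-scored and PCA-reduced; the reduced source samples are partitioned
#' into phase-specific sub-source domains by K-means (cluster count by the
#' elbow criterion unless fixed); one firefly-optimized sigmoid network per
#' domain and per target variable is trained; the sub-domain whose centroid
#' is closest (mean Euclidean distance over the labelled target samples) is
#' adapted to the labelled early fraction of the target batch by
#' sequential layer unfreezing with MMD-regularised fine-tuning.
#' Predictions on the remaining target samples route each sample to its
#' nearest domain (the adapted model standing in for the matched domain),
#' or all to the matched model when `cfg$match = "batch"`.
#'
#' @param source_batches list of `ferm_batch` (historical source batches).
#' @param target_batch a `ferm_batch`; only its earliest
#'   `cfg$labeled_frac` samples are used as labelled data.
#' @param cfg a [run_config()].
#' @return object of class `ltss` with, among others, `domains`,
#'   `sub_models`, `matched_domain`, `models` (adapted per-variable nets of
#'   the matched domain), `predictions`, `metrics` (per-variable RMSE and
#'   R-squared on the held-out target samples) and the fitted
#'   preprocessing objects.
#' @examples
#' \donttest{
#' camp <- default_campaign(kinetics_config(seed = 7))
#' fit <- local_transfer_sensor(camp$source, camp$target,
#'                              run_config(seed = 7, n_fireflies = 4,
#'                                         ifa_iter = 2))
#' fit$metrics
#' }
#' @export
local_transfer_sensor <- function(source_batches, target_batch,
                                  cfg = run_config()) {
  if (!length(source_batches)) stop("need at least one source batch",
                                    call. = FALSE)
  prep <- prep_sources(source_batches, cfg)
  if (ncol(target_batch$X_aux) != length(prep$scaler$center))
    stop("target batch auxiliary schema does not match the source batches",
         call. = FALSE)

  ## Step 1: sub-source domain partitioning
  K <- if (identical(cfg$K, "auto")) {
    elbow_select(sse_curve(prep$X, cfg$k_max,
                           seed = derive_seed(cfg$seed, 2)))
  } else as.integer(cfg$K)
  km <- kmeans_fit(prep$X, K, seed = derive_seed(cfg$seed, 3))
  domains <- partition_domains(prep$X, prep$Ys, km)

  ## Step 2: firefly-optimized sub-model per domain and target variable
  n_var <- ncol(prep$Ys)
  sub_models <- lapply(domains, function(dom) {
    lapply(seq_len(n_var), function(v)
      tune_and_train(dom$samples_X,
                     dom$samples_y[, v, drop = FALSE], cfg,
                     seed = derive_seed(cfg$seed, 100 * dom$domain_id + v)))
  })

  ## Step 3: match target samples / batch to sub-source domains.  The
  ## transfer base domain is matched on the labelled window only (the data
  ## fine-tuning will see), by mean centroid distance.
  Xp_t <- project_target(prep, target_batch)
  n_t <- nrow(Xp_t)
  n_lab <- max(2L, round(cfg$labeled_frac * n_t))
  lab <- seq_len(n_lab)
  dist_mat <- vapply(domains, function(dom)
    sqrt(colSums((t(Xp_t) - dom$centroid)^2)), numeric(n_t))
  mean_dist <- colMeans(dist_mat[lab, , drop = FALSE])
  matched <- which.min(mean_dist)
  route <- if (cfg$match == "per_sample")
    max.col(-dist_mat, ties.method = "first") else
      rep(matched, nrow(Xp_t))

  ## Step 4: transfer fine-tuning of the matched domain's models on the
  ## labelled early target samples
  Ys_t <- scale_targets(prep$y_scaler, target_batch$Y_target)
  models <- vector("list", n_var)
  k_final <- integer(n_var)
  for (v in seq_len(n_var)) {
    tr <- sequential_unfreeze(sub_models[[matched]][[v]]$params,
                              domains[[matched]]$samples_X,
                              Xp_t[lab, , drop = FALSE],
                              Ys_t[lab, v, drop = FALSE],
                              cfg$plan, seed = derive_seed(cfg$seed, 7))
    models[[v]] <- tr$params
    k_final[v] <- tr$k_final
  }
  nets_by_domain <- lapply(seq_len(K), function(k) {
    if (k == matched) models else lapply(sub_models[[k]], `[[`, "params")
  })

  ## Step 5: prediction + metrics on the unlabelled target samples
  test <- setdiff(seq_len(n_t), lab)
  pred_scaled <- route_predict(Xp_t[test, , drop = FALSE], route[test],
                               nets_by_domain, n_var)
  pred <- unscale_targets(prep$y_scaler, pred_scaled)
  truth <- target_batch$Y_target[test, , drop = FALSE]
  colnames(pred) <- colnames(truth)
  metrics <- data.frame(
    variable = colnames(truth),
    rmse = vapply(seq_len(n_var), function(v) rmse(pred[, v], truth[, v]),
                  numeric(1)),
    r2 = vapply(seq_len(n_var), function(v) r2(pred[, v], truth[, v]),
                numeric(1)),
    row.names = NULL)

  structure(list(config = cfg, prep = prep, K = K, cluster = km,
                 domains = domains, sub_models = sub_models,
                 matched_domain = matched, mean_distances = mean_dist,
                 models = models, nets_by_domain = nets_by_domain,
                 frozen_depth = k_final,
                 labeled_index = lab, test_index = test,
                 predictions = pred, truth = truth, metrics = metrics,
                 target_id = target_batch$batch_id),
            class = "ltss")
}

#' Benchmark the model family on one campaign
#'
#' Trains and evaluates the four variants of the method on identical
#' preprocessing outputs, splits and seeds: a plain global network with
#' centre-of-the-box (untuned) hyperparameters (`DNN`), a global network
#' tuned by the classical firefly algorithm (`FA-DNN`), per-phase local
#' models tuned by the improved algorithm with centroid matching
#' (`K-IFA-DNN`), and the full method with transfer fine-tuning of the
#' batch-matched domain (`K-IFA-DNN-TL`).  All variants are scored on the
#' same held-out target samples; only the `-TL` variant sees the labelled
#' target fraction.
#'
#' @param source_batches,target_batch,cfg as in [local_transfer_sensor()].
#' @param models subset of
#'   `c("DNN", "FA-DNN", "K-IFA-DNN", "K-IFA-DNN-TL")`.
#' @return list of class `ltss_benchmark` with matrices `rmse`, `r2`
#'   (models x target variables, physical units) and `rmse_scaled`
#'   (models x variables on min-max scaled targets, comparable across
#'   variables).
#' @export
benchmark_models <- function(source_batches, target_batch,
                             cfg = run_config(),
                             models = c("DNN", "FA-DNN", "K-IFA-DNN",
                                        "K-IFA-DNN-TL")) {
  models <- match.arg(models, several.ok = TRUE)
  prep <- prep_sources(source_batches, cfg)
  Xp_t <- project_target(prep, target_batch)
  n_t <- nrow(Xp_t)
  n_lab <- max(2L, round(cfg$labeled_frac * n_t))
  lab <- seq_len(n_lab)
  test <- setdiff(seq_len(n_t), lab)
  truth <- target_batch$Y_target[test, , drop = FALSE]
  truth_s <- scale_targets(prep$y_scaler, target_batch$Y_target)[test, ,
                                                                 drop = FALSE]
  n_var <- ncol(prep$Ys)
  var_names <- colnames(prep$Y)

  ## local machinery shared bit-exactly by the K- variants
  need_local <- any(c("K-IFA-DNN", "K-IFA-DNN-TL") %in% models)
  if (need_local) {
    K <- if (identical(cfg$K, "auto")) {
      elbow_select(sse_curve(prep$X, cfg$k_max,
                             seed = derive_seed(cfg$seed, 2)))
    } else as.integer(cfg$K)
    km <- kmeans_fit(prep$X, K, seed = derive_seed(cfg$seed, 3))
    domains <- partition_domains(prep$X, prep$Ys, km)
    dist_mat <- vapply(domains, function(dom)
      sqrt(colSums((t(Xp_t) - dom$centroid)^2)), numeric(n_t))
    matched <- which.min(colMeans(dist_mat[lab, , drop = FALSE]))
    route <- if (cfg$match == "per_sample")
      max.col(-dist_mat, ties.method = "first") else
        rep(matched, n_t)
    sub_models <- lapply(domains, function(dom)
      lapply(seq_len(n_var), function(v)
        tune_and_train(dom$samples_X, dom$samples_y[, v, drop = FALSE], cfg,
                       seed = derive_seed(cfg$seed,
                                          100 * dom$domain_id + v))$params))
  }

  out_rmse <- out_r2 <- out_rmse_s <-
    matrix(NA_real_, length(models), n_var,
           dimnames = list(models, var_names))
  for (spec in models) {
    ps <- switch(spec,
      "DNN" = {
        hp <- centre_hyperparams(cfg$encoding)
        nets <- lapply(seq_len(n_var), function(v)
          train_with_hp(prep$X, prep$Ys[, v, drop = FALSE], hp,
                        cfg$n_hidden_layers,
                        seed = derive_seed(cfg$seed, 500 + v)))
        vapply(nets, function(m)
          forward(m, Xp_t[test, , drop = FALSE])$prediction[, 1],
          numeric(length(test)))
      },
      "FA-DNN" = {
        nets <- lapply(seq_len(n_var), function(v)
          tune_and_train(prep$X, prep$Ys[, v, drop = FALSE], cfg,
                         seed = derive_seed(cfg$seed, 600 + v),
                         variant = "fa")$params)
        vapply(nets, function(m)
          forward(m, Xp_t[test, , drop = FALSE])$prediction[, 1],
          numeric(length(test)))
      },
      "K-IFA-DNN" = route_predict(Xp_t[test, , drop = FALSE], route[test],
                                  sub_models, n_var),
      "K-IFA-DNN-TL" = {
        Ys_t <- scale_targets(prep$y_scaler, target_batch$Y_target)
        adapted <- lapply(seq_len(n_var), function(v)
          sequential_unfreeze(sub_models[[matched]][[v]],
                              domains[[matched]]$samples_X,
                              Xp_t[lab, , drop = FALSE],
                              Ys_t[lab, v, drop = FALSE],
                              cfg$plan,
                              seed = derive_seed(cfg$seed, 7))$params)
        nets_tl <- lapply(seq_along(sub_models), function(k)
          if (k == matched) adapted else sub_models[[k]])
        route_predict(Xp_t[test, , drop = FALSE], route[test],
                      nets_tl, n_var)
      })
    p <- unscale_targets(prep$y_scaler, ps)
    for (v in seq_len(n_var)) {
      out_rmse[spec, v] <- rmse(p[, v], truth[, v])
      out_r2[spec, v] <- r2(p[, v], truth[, v])
      out_rmse_s[spec, v] <- rmse(ps[, v], truth_s[, v])
    }
  }
  structure(list(rmse = out_rmse, r2 = out_r2, rmse_scaled = out_rmse_s,
                 seed = cfg$seed), class = "ltss_benchmark")
}

#' @export
print.ltss_benchmark <- function(x, ...) {
  cat("Benchmark on held-out target samples (RMSE, physical units):\n")
  print(round(x$rmse, 4))
  cat("\nR-squared:\n")
  print(round(x$r2, 4))
  invisible(x)
}
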