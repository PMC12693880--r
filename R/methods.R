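#' @export
print.ltss <- function(x, ...) {
  cat("Local transfer soft sensor\n")
  cat(sprintf("  sub-source domains : %d (sizes %s)\n", x$K,
              paste(vapply(x$domains, function(d) nrow(d$samples_X), 1L),
                    collapse = ", ")))
  cat(sprintf("  matched domain     : %d (mean centroid distances %s)\n",
              x$matched_domain,
              paste(signif(x$mean_distances, 3), collapse = ", ")))
  cat(sprintf("  frozen depth/var   : %s\n",
              paste(x$frozen_depth, collapse = ", ")))
  cat(sprintf("  target '%s': %d labelled + %d test samples\n",
              x$target_id, length(x$labeled_index), length(x$test_index)))
  cat("  held-out metrics:\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ltss <- function(object, ...) {
  structure(list(
    K = object$K,
    domain_sizes = vapply(object$domains, function(d) nrow(d$samples_X), 1L),
    pca_components = object$prep$k_pca,
    explained_variance = object$prep$pca$explained_variance_ratio,
    matched_domain = object$matched_domain,
    mean_distances = object$mean_distances,
    hyperparams = lapply(object$sub_models[[object$matched_domain]],
                         `[[`, "hyperparams"),
    frozen_depth = object$frozen_depth,
    metrics = object$metrics), class = "summary.ltss")
}

#' @export
print.summary.ltss <- function(x, ...) {
  cat(sprintf("Local transfer soft sensor: K = %d domains (sizes %s)\n",
              x$K, paste(x$domain_sizes, collapse = ", ")))
  cat(sprintf("PCA: %d components retained (cumulative variance %.3f)\n",
              x$pca_components,
              sum(x$explained_variance[seq_len(x$pca_components)])))
  cat(sprintf("Matched sub-source domain: %d\n", x$matched_domain))
  cat("Tuned hyperparameters of the matched domain's sub-models:\n")
  for (v in seq_along(x$hyperparams)) {
    hp <- x$hyperparams[[v]]
    cat(sprintf("  var %d: lr=%.2g width=%d init_range=%.2f epochs=%d\n",
                v, hp$lr, hp$width, hp$init_range, hp$epochs))
  }
  cat("Held-out target metrics:\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Predict soft-sensor targets for new auxiliary data
#'
#' Applies the fitted preprocessing (source scaler + PCA) and the adapted
#' per-variable networks to new auxiliary measurements, returning
#' predictions in physical units.
#'
#' @param object an `ltss` fit.
#' @param newdata a `ferm_batch` or a matrix of auxiliary variables with
#'   the training schema; defaults to the fit's held-out target samples.
#' @param ... unused.
#' @return matrix (samples x target variables).
#' @export
predict.ltss <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$predictions)
  X <- if (inherits(newdata, "ferm_batch")) newdata$X_aux else
    as.matrix(newdata)
  Xp <- transform_pca(object$prep$pca,
                      apply_scaler(object$prep$scaler, X),
                      object$prep$k_pca)
  route <- if (object$config$match == "per_sample") {
    apply(Xp, 1, function(x) match_domain(x, object$domains)$domain_id)
  } else rep(object$matched_domain, nrow(Xp))
  ps <- route_predict(Xp, route, object$nets_by_domain,
                      length(object$models))
  p <- unscale_targets(object$prep$y_scaler, ps)
  colnames(p) <- object$metrics$variable
  p
}

#' @export
fitted.ltss <- function(object, ...) object$predictions

#' @export
residuals.ltss <- function(object, ...) object$truth - object$predictions

#' @export
coef.ltss <- function(object, ...) {
  stats::setNames(lapply(object$models, function(m)
    list(weights = m$weights, biases = m$biases)),
    object$metrics$variable)
}

#' Plot predicted versus observed target trajectories
#'
#' One panel per target variable: observed held-out values and the adapted
#' model's predictions against sample index.
#'
#' @param x an `ltss` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ltss <- function(x, ...) {
  nv <- ncol(x$predictions)
  op <- graphics::par(mfrow = c(1, nv), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (v in seq_len(nv)) {
    graphics::matplot(cbind(x$truth[, v], x$predictions[, v]),
                      type = "l", lty = c(1, 2), col = c(1, 2),
                      xlab = "held-out sample", ylab = x$metrics$variable[v],
                      main = x$metrics$variable[v], ...)
    graphics::legend("topleft", c("observed", "predicted"),
                     lty = c(1, 2), col = c(1, 2), bty = "n", cex = 0.8)
  }
  invisible(x)
}
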