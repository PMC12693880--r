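#' Linear-interpolation data augmentation
#'
#' Inserts `points_per_gap` equally spaced points on the straight segment
#' between every pair of adjacent rows, per column, so a series of `n` rows
#' becomes `n + (n - 1) * points_per_gap` rows.  Original rows are preserved
#' unchanged at their ordered positions.  With the default 2 points per gap
#' a 61-sample batch grows to 181 samples.
#'
#' @param series numeric matrix (samples x features), rows time-ordered.
#' @param points_per_gap number of interpolated rows per gap (>= 1).
#' @return matrix with `n + (n - 1) * points_per_gap` rows.
#' @examples
#' interpolate_augment(rbind(c(0, 0), c(3, 3)), 2)
#' @export
interpolate_augment <- function(series, points_per_gap = 2) {
  series <- as.matrix(series)
  n <- nrow(series)
  if (n < 2) stop("series must have at least 2 rows", call. = FALSE)
  if (points_per_gap < 1) stop("points_per_gap must be >= 1", call. = FALSE)
  if (any(!is.finite(series))) stop("series contains non-finite values",
                                    call. = FALSE)
  g <- as.integer(points_per_gap)
  frac <- seq_len(g) / (g + 1)          # equal subdivision of each gap
  out <- matrix(NA_real_, n + (n - 1L) * g, ncol(series))
  colnames(out) <- colnames(series)
  step <- g + 1L
  out[seq(1L, nrow(out), by = step), ] <- series
  for (j in seq_len(g)) {
    y0 <- series[-n, , drop = FALSE]
    y1 <- series[-1, , drop = FALSE]
    out[seq(1L + j, nrow(out), by = step)[seq_len(n - 1L)], ] <-
      y0 + (y1 - y0) * frac[j]
  }
  out
}

#' Augment a whole batch
#'
#' Applies [interpolate_augment()] jointly to time, auxiliary and target
#' columns of a batch so auxiliary and target variables stay consistent;
#' interpolated samples inherit the phase label of their left neighbour.
#'
#' @param batch a `ferm_batch`.
#' @param points_per_gap interpolated rows per gap.
#' @return an augmented `ferm_batch`.
#' @export
augment_batch <- function(batch, points_per_gap = 2) {
  M <- cbind(time_h = batch$time_h, batch$X_aux, batch$Y_target)
  A <- interpolate_augment(M, points_per_gap)
  p <- ncol(batch$X_aux)
  lab <- NULL
  if (!is.null(batch$phase_label)) {
    idx <- rep(seq_along(batch$phase_label),
               c(rep(points_per_gap + 1L, length(batch$phase_label) - 1L), 1L))
    lab <- batch$phase_label[idx]
  }
  structure(list(batch_id = batch$batch_id,
                 time_h = A[, 1],
                 X_aux = A[, 1 + seq_len(p), drop = FALSE],
                 Y_target = A[, (2 + p):ncol(A), drop = FALSE],
                 phase_label = lab),
            class = "ferm_batch")
}

#' Z-score standardizer
#'
#' Per-feature centring and scaling fitted on source data and reused,
#' unchanged, on target data.  Constant features get unit scale so they map
#' to zero rather than NaN.
#'
#' @param X numeric matrix (samples x features).
#' @return object of class `fx_scaler` with `$center` and `$scale`.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  s <- apply(X, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  structure(list(center = colMeans(X), scale = s), class = "fx_scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted `fx_scaler`.
#' @export
apply_scaler <- function(scaler, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

#' Principal component analysis by covariance eigen-decomposition
#'
#' Centres the data, forms the (unbiased, n-1 divisor) covariance matrix and
#' eigen-decomposes it.  The model stores the mean vector, the eigenvector
#' loading matrix W (columns sorted by descending eigenvalue), the
#' eigenvalues and the per-component explained-variance ratios.
#'
#' @param X numeric matrix (samples x p), at least 2 rows.
#' @return object of class `fx_pca` with fields `mean_vector`, `components`,
#'   `eigenvalues`, `explained_variance_ratio`, `n_components_retained`.
#' @examples
#' m <- fit_pca(matrix(rnorm(80), 20))
#' m$explained_variance_ratio
#' @export
fit_pca <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("fit_pca needs at least 2 samples", call. = FALSE)
  if (any(!is.finite(X))) stop("fit_pca: X must be finite", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc) / (nrow(X) - 1)
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 0)              # clip tiny negative round-off
  tot <- sum(lam)
  evr <- if (tot > 0) lam / tot else rep(0, length(lam))
  structure(list(mean_vector = mu,
                 components = e$vectors,
                 eigenvalues = lam,
                 explained_variance_ratio = evr,
                 n_components_retained = sum(lam > 1e-12)),
            class = "fx_pca")
}

#' Project data onto the leading principal components
#'
#' @param model a fitted `fx_pca`.
#' @param X matrix with the same number of columns the model was fitted on.
#' @param k number of components (defaults to all).
#' @return matrix (samples x k) of scores `(X - mean) W[, 1:k]`.
#' @export
transform_pca <- function(model, X, k = length(model$eigenvalues)) {
  X <- as.matrix(X)
  p <- length(model$mean_vector)
  if (ncol(X) != p) stop("transform_pca: X has wrong number of columns",
                         call. = FALSE)
  if (k < 1 || k > p) stop("transform_pca: k out of range", call. = FALSE)
  sweep(X, 2, model$mean_vector) %*% model$components[, seq_len(k), drop = FALSE]
}

#' Choose the number of components by cumulative explained variance
#'
#' Returns the smallest k whose cumulative explained-variance ratio reaches
#' the threshold.
#'
#' @param model a fitted `fx_pca`.
#' @param cum_var_threshold fraction in (0, 1].
#' @return integer component count.
#' @export
select_components <- function(model, cum_var_threshold = 0.99) {
  if (cum_var_threshold <= 0 || cum_var_threshold > 1)
    stop("cum_var_threshold must be in (0, 1]", call. = FALSE)
  cum <- cumsum(model$explained_variance_ratio)
  ## threshold 1 with round-off: every nonzero component is needed
  k <- which(cum >= cum_var_threshold - 1e-12)[1]
  if (is.na(k)) k <- length(cum)
  as.integer(max(k, 1L))
}

#' @export
print.fx_pca <- function(x, ...) {
  cat(sprintf("<fx_pca: %d features, %d nonzero components>\n",
              length(x$mean_vector), x$n_components_retained))
  invisible(x)
}
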