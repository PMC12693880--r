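## squared Euclidean distances from every row of X to every row of C
sqdist_mat <- function(X, C) {
  xx <- rowSums(X^2)
  cc <- rowSums(C^2)
  outer(xx, cc, "+") - 2 * X %*% t(C)
}

## Greedy-spread ("k-means++"-style) seeding: random first centre, then
## each next centre drawn with probability proportional to the squared
## distance from its nearest chosen centre, so restarts explore distinct
## well-spread initialisations.
greedy_spread_init <- function(X, K) {
  n <- nrow(X)
  centres <- integer(K)
  centres[1] <- sample.int(n, 1)
  if (K > 1) {
    d2 <- sqdist_mat(X, X[centres[1], , drop = FALSE])[, 1]
    for (k in 2:K) {
      d2c <- pmax(d2, 0)
      centres[k] <- if (sum(d2c) > 0) {
        sample.int(n, 1, prob = d2c)
      } else sample.int(n, 1)
      d2 <- pmin(d2, sqdist_mat(X, X[centres[k], , drop = FALSE])[, 1])
    }
  }
  X[centres, , drop = FALSE]
}

lloyd_once <- function(X, K, max_iter, tol) {
  C <- greedy_spread_init(X, K)
  assign_prev <- integer(0)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    D2 <- sqdist_mat(X, C)
    a <- max.col(-D2, ties.method = "first")   # nearest centroid, lowest id
    wcss <- sum(D2[cbind(seq_len(nrow(X)), a)])
    trace <- c(trace, wcss)
    Cnew <- C
    for (k in seq_len(K)) {
      rows <- which(a == k)
      if (length(rows)) Cnew[k, ] <- colMeans(X[rows, , drop = FALSE])
    }
    shift <- sqrt(max(rowSums((Cnew - C)^2)))
    C <- Cnew
    if (identical(a, assign_prev) || shift < tol) break
    assign_prev <- a
  }
  ## final assignment/wcss against the converged centroids
  D2 <- sqdist_mat(X, C)
  a <- max.col(-D2, ties.method = "first")
  wcss <- sum(D2[cbind(seq_len(nrow(X)), a)])
  list(centroids = C, assignment = a, wcss = wcss, wcss_trace = trace)
}

#' K-means clustering with seeded greedy-spread initialization
#'
#' Lloyd's algorithm minimising the within-cluster sum of squares, started
#' from a greedy farthest-point seeding and restarted `n_init` times with
#' derived seeds; the best restart by WCSS is kept.  All tie-breaks
#' (nearest-centroid assignment, restarts with equal WCSS) resolve to the
#' lowest index, so results are fully deterministic for a fixed seed.
#'
#' @param X numeric matrix (samples x features).
#' @param K number of clusters, `1 <= K <= nrow(X)`.
#' @param seed integer seed.
#' @param n_init independent restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart.
#' @param tol centroid-shift convergence tolerance.
#' @return object of class `fx_kmeans`: `K`, `centroids` (K x p),
#'   `assignment`, `wcss`, `wcss_trace` (per-iteration WCSS of the winning
#'   restart), `seed`.
#' @examples
#' X <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 5), 10))
#' kmeans_fit(X, 2, seed = 1)$wcss
#' @export
kmeans_fit <- function(X, K, seed = 1L, n_init = 10, max_iter = 100,
                       tol = 1e-8) {
  X <- as.matrix(X)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (K > nrow(X)) stop("K cannot exceed the number of samples", call. = FALSE)
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- with_seed(derive_seed(seed, r), lloyd_once(X, K, max_iter, tol))
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  structure(list(K = as.integer(K), centroids = best$centroids,
                 assignment = best$assignment, wcss = best$wcss,
                 wcss_trace = best$wcss_trace, seed = as.integer(seed)),
            class = "fx_kmeans")
}

#' SSE (elbow) curve over candidate cluster counts
#'
#' Fits [kmeans_fit()] for every k in `1..k_max` and returns the within
#' -cluster sum of squares per k; with multiple restarts per fit the curve
#' is non-increasing in practice.
#'
#' @param X data matrix.
#' @param k_max largest cluster count (<= samples).
#' @param seed integer seed.
#' @param n_init restarts per fit.
#' @return numeric vector of length `k_max`, entry k = SSE of the k-cluster
#'   fit.
#' @export
sse_curve <- function(X, k_max = 10, seed = 1L, n_init = 10) {
  X <- as.matrix(X)
  if (k_max > nrow(X)) stop("k_max cannot exceed the number of samples",
                            call. = FALSE)
  vapply(seq_len(k_max), function(k)
    kmeans_fit(X, k, seed = derive_seed(seed, 1000 + k),
               n_init = n_init)$wcss,
    numeric(1))
}

#' Elbow selection by maximum discrete curvature
#'
#' Operationalises the elbow of an SSE-versus-k curve as the interior k
#' maximising the second forward difference `SSE(k-1) - 2 SSE(k) + SSE(k+1)`;
#' ties resolve to the smallest k.
#'
#' @param sse numeric vector of SSE values for k = 1, 2, ..., length >= 3.
#' @return the selected cluster count (integer).
#' @examples
#' elbow_select(c(100, 30, 28, 27))  # 2
#' @export
elbow_select <- function(sse) {
  if (length(sse) < 3) stop("elbow_select needs at least 3 SSE values",
                            call. = FALSE)
  interior <- 2:(length(sse) - 1)
  curv <- sse[interior - 1] - 2 * sse[interior] + sse[interior + 1]
  as.integer(interior[which.max(curv)])  # which.max ties -> smallest k
}

#' Partition clustered samples into sub-source domains
#'
#' Splits the data by the fitted cluster assignment into one sub-source
#' domain per cluster, each carrying its samples, targets and centroid.
#'
#' @param X matrix the cluster model was fitted on.
#' @param y target matrix/vector aligned with the rows of `X`.
#' @param model a fitted `fx_kmeans`.
#' @return list of `K` objects of class `fx_domain` with fields
#'   `domain_id`, `samples_X`, `samples_y`, `centroid`, `model_ref`.
#' @export
partition_domains <- function(X, y, model) {
  X <- as.matrix(X)
  y <- as.matrix(y)
  stopifnot(inherits(model, "fx_kmeans"), nrow(X) == length(model$assignment))
  lapply(seq_len(model$K), function(k) {
    rows <- which(model$assignment == k)
    if (!length(rows))
      stop(sprintf(paste("cluster %d is empty; re-fit the cluster model",
                         "with a different seed or smaller K"), k),
           call. = FALSE)
    structure(list(domain_id = k,
                   samples_X = X[rows, , drop = FALSE],
                   samples_y = y[rows, , drop = FALSE],
                   centroid = model$centroids[k, ],
                   model_ref = NULL),
              class = "fx_domain")
  })
}

#' Match a target sample to its closest sub-source domain
#'
#' Euclidean distance from the target point to each stored domain centroid;
#' the domain with the smallest distance wins, ties going to the lowest id.
#'
#' @param x_target numeric vector in the same (PCA) space as the centroids.
#' @param domains list of `fx_domain` from [partition_domains()].
#' @return list with `domain_id` and the vector of `distances`.
#' @export
match_domain <- function(x_target, domains) {
  d <- vapply(domains, function(dom) {
    if (length(dom$centroid) != length(x_target))
      stop("target sample dimension does not match the domain centroids",
           call. = FALSE)
    sqrt(sum((x_target - dom$centroid)^2))
  }, numeric(1))
  list(domain_id = which.min(d), distances = d)
}

#' @export
print.fx_kmeans <- function(x, ...) {
  cat(sprintf("<fx_kmeans: K=%d, wcss=%.4g, %d Lloyd iterations>\n",
              x$K, x$wcss, length(x$wcss_trace)))
  invisible(x)
}
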