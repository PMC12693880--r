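# Independent oracles and small fixtures shared across the test files.
# These deliberately avoid the package's own code paths.

# Brute-force optimal K-partition WCSS by enumerating all assignments.
brute_force_wcss <- function(X, K) {
  n <- nrow(X)
  best <- Inf
  grid <- do.call(expand.grid, rep(list(seq_len(K)), n))
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    if (length(unique(a)) < K) next
    w <- 0
    for (k in seq_len(K)) {
      rows <- X[a == k, , drop = FALSE]
      mu <- colMeans(rows)
      w <- w + sum(sweep(rows, 2, mu)^2)
    }
    best <- min(best, w)
  }
  best
}

# Central finite-difference gradient of an arbitrary scalar loss of the
# network parameters.
fd_gradients <- function(params, loss_fun, h = 1e-6) {
  L <- length(params$weights)
  dW <- vector("list", L); db <- vector("list", L)
  for (l in seq_len(L)) {
    dW[[l]] <- params$weights[[l]]
    for (i in seq_along(params$weights[[l]])) {
      p1 <- params; p1$weights[[l]][i] <- p1$weights[[l]][i] + h
      p2 <- params; p2$weights[[l]][i] <- p2$weights[[l]][i] - h
      dW[[l]][i] <- (loss_fun(p1) - loss_fun(p2)) / (2 * h)
    }
    db[[l]] <- params$biases[[l]]
    for (i in seq_along(params$biases[[l]])) {
      p1 <- params; p1$biases[[l]][i] <- p1$biases[[l]][i] + h
      p2 <- params; p2$biases[[l]][i] <- p2$biases[[l]][i] - h
      db[[l]][i] <- (loss_fun(p1) - loss_fun(p2)) / (2 * h)
    }
  }
  list(dW = dW, db = db)
}

max_rel_grad_err <- function(g, fd) {
  errs <- unlist(Map(function(a, b) abs(a - b) / pmax(abs(b), 1e-4),
                     c(g$dW, g$db), c(fd$dW, fd$db)))
  max(errs)
}

# Rand index between two labelings (agreement of co-membership pairs).
rand_index <- function(a, b) {
  n <- length(a)
  s <- 0
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    s <- s + sum((a[i] == a[j]) == (b[i] == b[j]))
  }
  s / choose(n, 2)
}

# Hill estimator of the tail exponent from the m largest order statistics.
hill_tail_exponent <- function(x, m) {
  x <- sort(abs(x), decreasing = TRUE)
  1 / mean(log(x[1:m] / x[m + 1]))
}

tiny_net <- function(widths = c(2, 3, 1), seed = 1, range = 0.8) {
  arch <- network_arch(widths[1], widths[-c(1, length(widths))],
                       widths[length(widths)])
  init_network(arch, range, seed = seed)
}

flatten_params <- function(p) unlist(c(p$weights, p$biases))
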