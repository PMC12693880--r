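#' Configuration of the (improved) firefly optimizer
#'
#' @param n_fireflies population size (>= 2; >= 3 when the perturbation
#'   operator is active).
#' @param max_iter iteration budget.
#' @param beta0 maximum attractiveness at distance 0.
#' @param gamma light absorption coefficient.
#' @param alpha random-walk step size, in (0, 1).
#' @param levy_lambda Levy tail index, in (0, 2).
#' @param bounds 2 x D matrix, first row lower and second row upper bounds.
#' @param seed integer seed.
#' @param plateau_patience iterations without sufficient improvement before
#'   early stop (`Inf` disables).
#' @param plateau_tol minimum absolute best-loss improvement counting as
#'   progress.
#' @param variant `"ifa"` (perturbation + crossover + Levy + greedy
#'   selection) or `"fa"` (plain attractiveness moves only).
#' @return object of class `fx_ifa_config`.
#' @export
ifa_config <- function(n_fireflies = 15, max_iter = 50, beta0 = 1.0,
                       gamma = 1.0, alpha = 0.2, levy_lambda = 1.5,
                       bounds, seed = 1L, plateau_patience = Inf,
                       plateau_tol = 0, variant = c("ifa", "fa")) {
  variant <- match.arg(variant)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (levy_lambda <= 0 || levy_lambda >= 2)
    stop("levy_lambda must be in (0, 2)", call. = FALSE)
  if (n_fireflies < 2) stop("need at least 2 fireflies", call. = FALSE)
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2 || any(bounds[1, ] >= bounds[2, ]))
    stop("bounds must be a 2 x D matrix with lower < upper", call. = FALSE)
  structure(list(n_fireflies = as.integer(n_fireflies),
                 max_iter = as.integer(max_iter), beta0 = beta0,
                 gamma = gamma, alpha = alpha, levy_lambda = levy_lambda,
                 bounds = bounds, seed = as.integer(seed),
                 plateau_patience = plateau_patience,
                 plateau_tol = plateau_tol, variant = variant),
            class = "fx_ifa_config")
}

#' Firefly brightness from a loss value
#'
#' `I = 1 / (1 + L)`, the reciprocal-style map from a non-negative loss to
#' a brightness in (0, 1]; a zero loss gives the maximum brightness 1.
#'
#' @param loss non-negative scalar loss.
#' @return brightness in (0, 1].
#' @export
brightness <- function(loss) {
  if (any(loss < 0)) stop("loss must be >= 0", call. = FALSE)
  1 / (1 + loss)
}

#' Attractiveness at distance r
#'
#' `beta(r) = beta0 * exp(-gamma r^2)`.
#'
#' @param r non-negative distance.
#' @param beta0 attractiveness at r = 0.
#' @param gamma absorption coefficient.
#' @return attractiveness value.
#' @export
attractiveness <- function(r, beta0 = 1, gamma = 1) beta0 * exp(-gamma * r^2)

#' Euclidean distance between two fireflies
#' @param xi,xj equal-length numeric position vectors.
#' @return scalar distance.
#' @export
firefly_distance <- function(xi, xj) {
  if (length(xi) != length(xj))
    stop("firefly positions must have equal dimension", call. = FALSE)
  sqrt(sum((xi - xj)^2))
}

clip_bounds <- function(x, bounds) pmin(pmax(x, bounds[1, ]), bounds[2, ])

#' Move a firefly toward a brighter one
#'
#' `x_i <- x_i + beta(r) (x_j - x_i) + alpha * eps`, with a fresh
#' `eps ~ U(0,1)` per dimension, clipped to the bounds.  The caller is
#' responsible for only moving toward brighter fireflies.
#'
#' @param xi,xj positions (xj the brighter one).
#' @param cfg an `fx_ifa_config`.
#' @return updated position vector.
#' @export
ff_move <- function(xi, xj, cfg) {
  r <- firefly_distance(xi, xj)
  beta <- attractiveness(r, cfg$beta0, cfg$gamma)
  eps <- stats::runif(length(xi))
  clip_bounds(xi + beta * (xj - xi) + cfg$alpha * eps, cfg$bounds)
}

#' Stochastic perturbation from two random population members
#'
#' `x_i <- x_i + delta (x_p - x_q)` with `delta ~ U(0,1)` and p, q, i all
#' distinct, drawn uniformly; clipped to bounds.
#'
#' @param xi_new position after the attractiveness move.
#' @param population matrix of positions (rows = fireflies).
#' @param i index of the firefly being perturbed.
#' @param cfg an `fx_ifa_config`.
#' @return perturbed position vector.
#' @export
ff_perturb <- function(xi_new, population, i, cfg) {
  n <- nrow(population)
  if (n < 3) stop("perturbation needs a population of at least 3",
                  call. = FALSE)
  pq <- sample(setdiff(seq_len(n), i), 2)
  delta <- stats::runif(1)
  clip_bounds(xi_new + delta * (population[pq[1], ] - population[pq[2], ]),
              cfg$bounds)
}

#' Fitness-proportional crossover probabilities
#'
#' `P_i = I_i / sum(I_k)` over the population.
#'
#' @param brightnesses vector of positive brightness values.
#' @return probability vector summing to 1.
#' @export
crossover_prob <- function(brightnesses) {
  if (!length(brightnesses)) stop("empty population", call. = FALSE)
  if (any(brightnesses <= 0)) stop("brightnesses must be > 0", call. = FALSE)
  brightnesses / sum(brightnesses)
}

#' Per-dimension crossover with the global best
#'
#' Each component is replaced by the global best's component with
#' probability `Pi`, otherwise kept.
#'
#' @param xi_pert perturbed position.
#' @param x_best global best position.
#' @param Pi crossover probability in `[0, 1]`.
#' @return recombined position vector.
#' @export
ff_crossover <- function(xi_pert, x_best, Pi) {
  if (Pi < 0 || Pi > 1) stop("Pi must be in [0, 1]", call. = FALSE)
  take <- stats::runif(length(xi_pert)) < Pi
  ifelse(take, x_best, xi_pert)
}

#' Mantegna Levy-flight step
#'
#' Draws a heavy-tailed step `s = u / |v|^(1/lambda)` with
#' `u ~ N(0, sigma_u^2)`, `v ~ N(0, 1)` and
#' `sigma_u = [Gamma(1+lambda) sin(pi lambda / 2) /
#'  (Gamma((1+lambda)/2) lambda 2^((lambda-1)/2))]^(1/lambda)`.
#'
#' @param lambda tail index in (0, 2).
#' @param n number of draws.
#' @return numeric vector of Levy steps.
#' @export
levy_step <- function(lambda = 1.5, n = 1) {
  if (lambda <= 0 || lambda >= 2) stop("lambda must be in (0, 2)",
                                       call. = FALSE)
  sigma_u <- (gamma(1 + lambda) * sin(pi * lambda / 2) /
                (gamma((1 + lambda) / 2) * lambda *
                   2^((lambda - 1) / 2)))^(1 / lambda)
  u <- stats::rnorm(n, 0, sigma_u)
  v <- stats::rnorm(n)
  u / abs(v)^(1 / lambda)
}

#' Improved firefly optimization
#'
#' Minimises `objective` over the box in `cfg$bounds` by the improved
#' firefly loop: attractiveness-driven moves toward every brighter
#' neighbour, stochastic perturbation, fitness-proportional crossover with
#' the global best, a Levy-flight jump (scaled by `alpha` to keep moves
#' bounded), and greedy selection — a candidate replaces its firefly only
#' if it improves the loss, so the best-ever loss is non-increasing.  With
#' `variant = "fa"` only the plain attractiveness moves are used (the
#' classical algorithm), with unconditional acceptance.
#'
#' @param objective function mapping a position vector to a finite
#'   non-negative loss.
#' @param cfg an `fx_ifa_config`.
#' @return list with `best_position`, `best_loss`, `history` (best-ever
#'   loss after each iteration) and `n_evals`.
#' @examples
#' cfg <- ifa_config(bounds = rbind(c(-5, -5), c(5, 5)), max_iter = 20,
#'                   seed = 7)
#' ifa_optimize(function(x) sum(x^2), cfg)$best_loss
#' @export
ifa_optimize <- function(objective, cfg) {
  D <- ncol(cfg$bounds)
  eval_obj <- function(x) {
    v <- objective(x)
    if (!is.finite(v))
      stop("objective returned a non-finite value at position (",
           paste(signif(x, 4), collapse = ", "), ")", call. = FALSE)
    v
  }
  with_seed(cfg$seed, {
    N <- cfg$n_fireflies
    pop <- matrix(stats::runif(N * D), N) *
      rep(cfg$bounds[2, ] - cfg$bounds[1, ], each = N) +
      rep(cfg$bounds[1, ], each = N)
    loss <- apply(pop, 1, eval_obj)
    n_evals <- N
    best_i <- which.min(loss)
    best_x <- pop[best_i, ]
    best_f <- loss[best_i]
    history <- numeric(0)
    stall <- 0
    for (t in seq_len(cfg$max_iter)) {
      I <- brightness(loss)
      P <- crossover_prob(I)
      for (i in seq_len(N)) {
        cand <- pop[i, ]
        for (j in seq_len(N)) {
          if (I[j] > I[i]) cand <- ff_move(cand, pop[j, ], cfg)
        }
        if (cfg$variant == "ifa") {
          cand <- ff_perturb(cand, pop, i, cfg)
          cand <- ff_crossover(cand, best_x, P[i])
          s <- levy_step(cfg$levy_lambda, D)
          sgn <- sign(stats::runif(D) - 0.5)
          cand <- clip_bounds(cand + cfg$alpha * s * sgn, cfg$bounds)
          f_cand <- eval_obj(cand)
          n_evals <- n_evals + 1
          if (f_cand < loss[i]) {       # greedy selection
            pop[i, ] <- cand
            loss[i] <- f_cand
          }
        } else {
          pop[i, ] <- cand
          loss[i] <- eval_obj(cand)
          n_evals <- n_evals + 1
        }
        if (loss[i] < best_f) {
          best_f <- loss[i]
          best_x <- pop[i, ]
        }
        I[i] <- brightness(loss[i])
      }
      improved <- length(history) == 0 ||
        (history[length(history)] - best_f) > cfg$plateau_tol
      history <- c(history, best_f)
      stall <- if (improved) 0 else stall + 1
      if (stall >= cfg$plateau_patience) break
    }
    list(best_position = best_x, best_loss = best_f, history = history,
         n_evals = n_evals)
  })
}

#' Hyperparameter encoding for the network search
#'
#' Ordered box dimensions the optimizer searches over: log10 learning rate,
#' hidden width (rounded to integer on decode), uniform weight-init range,
#' and training epochs per evaluation (rounded).
#'
#' @param log10_lr,width,init_range,epochs length-2 numeric ranges
#'   `c(lower, upper)` for each dimension.
#' @return object of class `fx_encoding` (data frame of dims + bounds).
#' @export
hyperparam_encoding <- function(log10_lr = c(-4, -1), width = c(3, 10),
                                init_range = c(0.2, 1.5),
                                epochs = c(100, 400)) {
  enc <- data.frame(
    name = c("log10_lr", "width", "init_range", "epochs"),
    lower = c(log10_lr[1], width[1], init_range[1], epochs[1]),
    upper = c(log10_lr[2], width[2], init_range[2], epochs[2]),
    integer = c(FALSE, TRUE, FALSE, TRUE))
  if (any(enc$lower >= enc$upper))
    stop("each encoding range needs lower < upper", call. = FALSE)
  class(enc) <- c("fx_encoding", "data.frame")
  enc
}

#' @rdname hyperparam_encoding
#' @param encoding an `fx_encoding`.
#' @param x position vector of length `nrow(encoding)`.
#' @return named list of decoded hyperparameters (`lr`, `width`,
#'   `init_range`, `epochs`).
#' @export
decode_position <- function(encoding, x) {
  stopifnot(length(x) == nrow(encoding))
  x <- pmin(pmax(x, encoding$lower), encoding$upper)
  v <- ifelse(encoding$integer, round(x), x)
  list(lr = 10^v[encoding$name == "log10_lr"],
       width = as.integer(v[encoding$name == "width"]),
       init_range = v[encoding$name == "init_range"],
       epochs = as.integer(v[encoding$name == "epochs"]))
}

#' @rdname hyperparam_encoding
#' @export
encoding_bounds <- function(encoding) {
  rbind(encoding$lower, encoding$upper)
}

#' Validation-MSE objective for network hyperparameter search
#'
#' Builds the objective a firefly position is scored with: decode the
#' position, initialise a network of the given depth with the encoded
#' init range, train on a seeded 80/20 train/validation split of the
#' supplied (already scaled) data for the encoded epoch budget, and return
#' the validation mean squared error.  Deterministic for a fixed seed.
#'
#' @param X scaled input matrix.
#' @param y scaled target matrix (single column typical).
#' @param n_hidden_layers network depth used for every evaluation.
#' @param encoding an `fx_encoding`.
#' @param seed integer seed controlling the split and the weight init.
#' @param val_frac validation fraction.
#' @return function: position vector -> validation MSE.
#' @export
make_dnn_objective <- function(X, y, n_hidden_layers = 2,
                               encoding = hyperparam_encoding(),
                               seed = 1L, val_frac = 0.2) {
  X <- as.matrix(X); y <- as.matrix(y)
  n <- nrow(X)
  idx_val <- with_seed(derive_seed(seed, 17),
                       sample.int(n, max(1L, round(val_frac * n))))
  Xtr <- X[-idx_val, , drop = FALSE]; ytr <- y[-idx_val, , drop = FALSE]
  Xva <- X[idx_val, , drop = FALSE]; yva <- y[idx_val, , drop = FALSE]
  function(pos) {
    hp <- decode_position(encoding, pos)
    arch <- network_arch(ncol(X), rep(hp$width, n_hidden_layers), ncol(y))
    net <- init_network(arch, hp$init_range, seed = derive_seed(seed, 29))
    fit <- tryCatch(train_network(net, Xtr, ytr, hp$epochs, hp$lr),
                    error = function(e) NULL)
    if (is.null(fit)) return(1e6)       # diverged candidates are very unfit
    mse_mean(forward(fit$params, Xva)$prediction, yva)
  }
}
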