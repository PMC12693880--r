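bounds2 <- rbind(c(-5, -5), c(5, 5))

test_that("brightness, attractiveness and distance follow their formulas", {
  expect_equal(brightness(0), 1.0)
  expect_equal(brightness(1), 0.5)
  expect_equal(brightness(3), 0.25)
  expect_error(brightness(-1), ">= 0")
  expect_equal(attractiveness(0, beta0 = 2), 2)
  expect_equal(attractiveness(10, beta0 = 2, gamma = 0), 2)
  expect_equal(attractiveness(1, 1, 1), exp(-1))
  expect_equal(firefly_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(firefly_distance(c(0, 0), c(3, 4)), 5)
  set.seed(1)
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(firefly_distance(a, b), sqrt(sum((a - b)^2)),
               tolerance = 1e-12)
  expect_error(firefly_distance(1:2, 1:3), "dimension")
})

test_that("the attraction move reduces to a clipped random walk when xi = xj", {
  cfg <- ifa_config(bounds = bounds2, alpha = 0.3, seed = 1)
  x <- c(1, 2)
  set.seed(42)
  moved <- ff_move(x, x, cfg)
  set.seed(42)
  eps <- runif(2)
  expect_equal(moved, x + 0.3 * eps, tolerance = 1e-12)
  ## gamma -> Inf kills the attraction term at any positive distance
  cfg_inf <- ifa_config(bounds = bounds2, gamma = 1e12, alpha = 0.3, seed = 1)
  set.seed(42)
  moved2 <- ff_move(c(1, 2), c(3, 3), cfg_inf)
  expect_equal(moved2, c(1, 2) + 0.3 * eps, tolerance = 1e-9)
  ## clipping keeps positions inside the box
  cfg9 <- ifa_config(bounds = rbind(c(0, 0), c(1, 1)), alpha = 0.9, seed = 1)
  for (s in 1:20) {
    set.seed(s)
    m <- ff_move(c(0.95, 0.95), c(1, 1), cfg9)
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("perturbation replays the documented random stream", {
  cfg <- ifa_config(bounds = bounds2, seed = 1)
  pop <- rbind(c(0, 0), c(1, 1), c(2, 0), c(0, 2))
  ## duplicate population: x_p - x_q = 0 for all draws
  dup <- rbind(c(1, 1), c(1, 1), c(1, 1))
  set.seed(7)
  expect_equal(ff_perturb(c(1, 1), dup, 1, cfg), c(1, 1))
  ## replay oracle: same seed, same draws
  set.seed(9)
  got <- ff_perturb(c(0.5, 0.5), pop, 2, cfg)
  set.seed(9)
  pq <- sample(c(1, 3, 4), 2)
  delta <- runif(1)
  want <- pmin(pmax(c(0.5, 0.5) + delta * (pop[pq[1], ] - pop[pq[2], ]),
                    -5), 5)
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(ff_perturb(c(1, 1), dup[1:2, ], 1, cfg), "at least 3")
})

test_that("crossover probabilities are fitness-proportional and normalized", {
  expect_equal(crossover_prob(rep(0.3, 4)), rep(0.25, 4))
  expect_equal(crossover_prob(c(0.5, 0.25, 0.25)), c(0.5, 0.25, 0.25))
  set.seed(2)
  p <- crossover_prob(runif(10, 0.1, 1))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(crossover_prob(numeric(0)), "empty")
  expect_error(crossover_prob(c(0.5, 0)), "> 0")
})

test_that("crossover mixes with the global best per dimension", {
  xi <- c(1, 2, 3, 4); xb <- c(9, 9, 9, 9)
  expect_equal(ff_crossover(xi, xb, 0), xi)
  expect_equal(ff_crossover(xi, xb, 1), xb)
  set.seed(11)
  got <- ff_crossover(xi, xb, 0.5)
  set.seed(11)
  mask <- runif(4) < 0.5
  expect_equal(got, ifelse(mask, xb, xi))
})

test_that("Mantegna Levy steps have the right scale and tail", {
  ## lambda = 1: sigma_u = 1 exactly, so s = u / |v|
  set.seed(3)
  s1 <- levy_step(1, 5)
  set.seed(3)
  u <- rnorm(5, 0, 1); v <- rnorm(5)
  expect_equal(s1, u / abs(v), tolerance = 1e-12)
  ## seeded determinism
  set.seed(4); a <- levy_step(1.5, 10)
  set.seed(4); b <- levy_step(1.5, 10)
  expect_identical(a, b)
  ## tail exponent consistent with lambda (Hill estimator on 1e5 draws)
  set.seed(5)
  s <- levy_step(1.5, 1e5)
  expect_lt(abs(hill_tail_exponent(s, 2000) - 1.5), 0.2)
  expect_error(levy_step(2.5), "lambda")
})

test_that("optimization is reproducible, monotone, in-bounds, and effective", {
  sphere <- function(x) sum(x^2)
  cfg <- ifa_config(n_fireflies = 15, max_iter = 50, bounds = bounds2,
                    seed = 123)
  res <- ifa_optimize(sphere, cfg)
  expect_lt(res$best_loss, 1e-2)
  expect_true(all(diff(res$history) <= 0))
  expect_true(all(res$best_position >= -5 & res$best_position <= 5))
  res2 <- ifa_optimize(sphere, cfg)
  expect_identical(res$history, res2$history)
  ## every evaluated position stayed inside the box
  seen <- new.env(); seen$bad <- 0
  watched <- function(x) {
    if (any(x < bounds2[1, ] - 1e-12) || any(x > bounds2[2, ] + 1e-12))
      seen$bad <- seen$bad + 1
    sum(x^2)
  }
  invisible(ifa_optimize(watched, ifa_config(n_fireflies = 8, max_iter = 10,
                                             bounds = bounds2, seed = 5)))
  expect_equal(seen$bad, 0)
})

test_that("degenerate objectives and budgets behave as specified", {
  cfg0 <- ifa_config(n_fireflies = 6, max_iter = 0, bounds = bounds2,
                     seed = 31)
  flat <- ifa_optimize(function(x) 2.5, cfg0)
  expect_equal(flat$best_loss, 2.5)
  expect_equal(flat$n_evals, 6)        # best of the initial population only
  cfgf <- ifa_config(n_fireflies = 6, max_iter = 5, bounds = bounds2,
                     seed = 31)
  flat5 <- ifa_optimize(function(x) 2.5, cfgf)
  expect_true(all(flat5$history == 2.5))
  expect_error(ifa_optimize(function(x) NaN, cfgf), "non-finite")
  ## early stop on plateau
  cfg_es <- ifa_config(n_fireflies = 6, max_iter = 50, bounds = bounds2,
                       seed = 31, plateau_patience = 3, plateau_tol = 0)
  es <- ifa_optimize(function(x) 2.5, cfg_es)
  expect_lte(length(es$history), 4)
})

test_that("configuration and encoding validation catches bad input", {
  expect_error(ifa_config(alpha = 1.5, bounds = bounds2), "alpha")
  expect_error(ifa_config(levy_lambda = 2, bounds = bounds2), "levy_lambda")
  expect_error(ifa_config(bounds = rbind(c(1, 1), c(0, 2))), "lower < upper")
  enc <- hyperparam_encoding()
  hp <- decode_position(enc, c(-2, 6.6, 0.5, 199.4))
  expect_equal(hp$lr, 1e-2)
  expect_equal(hp$width, 7L)
  expect_equal(hp$epochs, 199L)
  ## decoded values stay in range even for out-of-box positions
  hp2 <- decode_position(enc, c(-99, 99, 99, 99))
  expect_equal(hp2$width, 10L)
  expect_equal(hp2$lr, 1e-4)
  expect_equal(unname(encoding_bounds(enc)[, 1]), c(-4, -1))
})
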