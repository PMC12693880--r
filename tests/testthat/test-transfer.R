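test_that("feature extraction matches the forward cache", {
  net <- tiny_net(c(2, 3, 1), seed = 1)
  X <- matrix(rnorm(10), 5, 2)
  fw <- forward(net, X)
  expect_identical(extract_features(net, X, 2), fw$prediction)
  expect_identical(extract_features(net, X, 1), fw$activations[[2]])
  expect_identical(extract_features(net, X, 0), X)
  zero <- net
  zero$weights <- lapply(zero$weights, function(w) w * 0)
  zero$biases <- lapply(zero$biases, function(b) b * 0)
  expect_true(all(extract_features(zero, X, 1) == 0.5))
  expect_error(extract_features(net, X, 5), "invalid")
})

test_that("mean-embedding MMD follows its definition", {
  Z <- matrix(rnorm(20), 5, 4)
  expect_equal(mmd(Z, Z), 0)
  expect_equal(mmd(matrix(0), matrix(1)), 1.0)
  expect_equal(mmd(rbind(c(0, 0), c(2, 0)), matrix(c(1, 1), 1)), 1.0)
  set.seed(2)
  A <- matrix(rnorm(30), 6, 5); B <- matrix(rnorm(40), 8, 5)
  expect_gte(mmd(A, B), 0)
  expect_equal(mmd(A, B), sum((colMeans(A) - colMeans(B))^2),
               tolerance = 1e-12)
  ## zero iff equal column means
  B2 <- sweep(B, 2, colMeans(B)) + matrix(colMeans(A), 8, 5, byrow = TRUE)
  expect_lt(mmd(A, B2), 1e-12)
  expect_error(mmd(A, B[, 1:3]), "dimension")
  expect_error(mmd(A[0, ], B), "empty")
})

test_that("freeze plans assign rates by depth", {
  plan <- transfer_plan(lr_frozen = 0, lr_finetune = 1e-5)
  expect_equal(freeze_plan(4, 4, plan), rep(0, 4))
  expect_equal(freeze_plan(4, 0, plan), rep(1e-5, 4))
  expect_equal(freeze_plan(5, 3, plan), c(0, 0, 0, 1e-5, 1e-5))
  expect_error(freeze_plan(4, 5, plan), "out of range")
  expect_error(transfer_plan(lr_frozen = 1, lr_finetune = 1e-5), "lr_frozen")
})

test_that("frozen layers stay bit-identical through fine-tuning", {
  net <- tiny_net(c(3, 4, 4, 1), seed = 3)
  Xs <- matrix(rnorm(30), 10, 3)
  Xt <- matrix(rnorm(24), 8, 3)
  Yt <- matrix(runif(8, 0.2, 0.8))
  plan <- transfer_plan(frozen_depth = 2, lr_finetune = 0.05, epochs = 10)
  ft <- fine_tune(net, Xs, Xt, Yt, plan)
  expect_identical(ft$params$weights[[1]], net$weights[[1]])
  expect_identical(ft$params$weights[[2]], net$weights[[2]])
  expect_identical(ft$params$biases[[1]], net$biases[[1]])
  expect_false(identical(ft$params$weights[[3]], net$weights[[3]]))
  expect_equal(nrow(ft$history), 11)
})

test_that("transfer with nothing frozen and no MMD reduces to plain training", {
  net <- tiny_net(c(2, 3, 1), seed = 4)
  Xt <- matrix(rnorm(12), 6, 2)
  Yt <- matrix(runif(6, 0.1, 0.9))
  plan <- transfer_plan(frozen_depth = 0, lr_finetune = 0.05, epochs = 15,
                        mmd_weight = 0)
  ft <- fine_tune(net, Xt, Xt, Yt, plan)
  plain <- train_network(net, Xt, Yt, 15, 0.05, loss = "mean")
  expect_identical(ft$params$weights, plain$params$weights)
  expect_identical(ft$params$biases, plain$params$biases)
})

test_that("the combined objective's gradient step matches finite differences", {
  net <- tiny_net(c(2, 3, 1), seed = 5)
  Xs <- matrix(rnorm(10), 5, 2)
  Xt <- matrix(rnorm(8), 4, 2)
  Yt <- matrix(runif(4, 0.2, 0.8))
  w <- 0.7
  plan <- transfer_plan(frozen_depth = 0, lr_finetune = 1, epochs = 1,
                        mmd_weight = w, feature_layer = 1)
  ft <- fine_tune(net, Xs, Xt, Yt, plan)
  loss_fun <- function(p) {
    mse_mean(forward(p, Xt)$prediction, Yt) +
      w * mmd(extract_features(p, Xs, 1), extract_features(p, Xt, 1))
  }
  fd <- fd_gradients(net, loss_fun)
  for (l in 1:2) {
    expect_equal(ft$params$weights[[l]], net$weights[[l]] - fd$dW[[l]],
                 tolerance = 1e-7)
    expect_equal(ft$params$biases[[l]], net$biases[[l]] - fd$db[[l]],
                 tolerance = 1e-7)
  }
})

test_that("alignment training shrinks the feature-space MMD on shifted data", {
  drops <- replicate(10, {
    s <- sample.int(1e6, 1)
    net <- tiny_net(c(3, 4, 1), seed = s)
    set.seed(s)
    Xs <- matrix(rnorm(60), 20, 3)
    Xt <- matrix(rnorm(45, mean = 1.5), 15, 3)   # mean-shifted covariates
    Yt <- matrix(runif(15, 0.2, 0.8))
    plan <- transfer_plan(frozen_depth = 0, lr_finetune = 0.05, epochs = 30,
                          mmd_weight = 1, feature_layer = 1)
    ft <- fine_tune(net, Xs, Xt, Yt, plan)
    h <- ft$history
    (h$mmd[1] - h$mmd[nrow(h)]) / h$mmd[1]
  })
  expect_gte(median(drops), 0.05)
})

test_that("sequential unfreezing respects its stopping rule", {
  net <- tiny_net(c(2, 4, 4, 1), seed = 6)
  set.seed(6)
  Xs <- matrix(rnorm(40), 20, 2)
  Ys <- forward(net, Xs)$prediction
  ## an infinite threshold stops after the first (output-layer) stage
  plan_inf <- transfer_plan(lr_finetune = 0.05, epochs = 5,
                            unfreeze_tol = Inf, mmd_weight = 0)
  res <- sequential_unfreeze(net, Xs, Xs, Ys, plan_inf, seed = 1)
  expect_equal(res$k_final, 2)         # 3 layers: only the last was tuned
  expect_equal(nrow(res$report), 2)

  ## target identical to source: no improvement possible, early stop
  plan <- transfer_plan(lr_finetune = 0.05, epochs = 5, unfreeze_tol = 1e-3,
                        mmd_weight = 0)
  res2 <- sequential_unfreeze(net, Xs, Xs, Ys, plan, seed = 1)
  expect_equal(res2$k_final, 2)
  expect_lt(abs(res2$report$val_mse[2] - res2$report$val_mse[1]), 1e-4)

  ## a real covariate shift keeps unfreezing past the first stage
  set.seed(7)
  src_net <- tiny_net(c(2, 4, 4, 1), seed = 7)
  Xt <- matrix(rnorm(60, 1), 30, 2)
  Yt <- matrix(0.2 + 0.6 * plogis(rowSums(Xt)))
  plan_s <- transfer_plan(lr_finetune = 0.3, epochs = 40,
                          unfreeze_tol = 1e-4, mmd_weight = 0)
  res3 <- sequential_unfreeze(src_net, Xs, Xt, Yt, plan_s, seed = 2)
  expect_lt(res3$k_final, 2)
  ## returned parameters are the best-validation stage
  expect_equal(min(res3$report$val_mse),
               mse_mean(forward(res3$params,
                                Xt[fermxfer:::with_seed(
                                  fermxfer:::derive_seed(2, 31),
                                  sample.int(30, 6)), ])$prediction,
                        Yt[fermxfer:::with_seed(
                          fermxfer:::derive_seed(2, 31),
                          sample.int(30, 6)), , drop = FALSE]),
               tolerance = 1e-10)
  expect_error(sequential_unfreeze(net, Xs, Xs[1, , drop = FALSE],
                                   Ys[1, , drop = FALSE], plan, seed = 1),
               "too few")
})
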