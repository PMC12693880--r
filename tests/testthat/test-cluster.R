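test_that("K = 1 recovers the column mean and total sum of squares", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3)
  m <- kmeans_fit(X, 1, seed = 1)
  expect_equal(m$centroids[1, ], colMeans(X), tolerance = 1e-12)
  expect_equal(m$wcss, sum(sweep(X, 2, colMeans(X))^2), tolerance = 1e-10)
})

test_that("two far-separated pairs are clustered optimally", {
  X <- rbind(c(0, 0), c(0.1, 0), c(10, 0), c(10.1, 0))
  m <- kmeans_fit(X, 2, seed = 4)
  expect_equal(m$assignment[1], m$assignment[2])
  expect_equal(m$assignment[3], m$assignment[4])
  expect_false(m$assignment[1] == m$assignment[3])
  expect_equal(m$wcss, brute_force_wcss(X, 2), tolerance = 1e-10)
  dom <- partition_domains(X, matrix(1:4), m)
  expect_equal(vapply(dom, function(d) nrow(d$samples_X), 1L), c(2L, 2L))
})

test_that("duplicating every row doubles the WCSS but keeps the centroids", {
  set.seed(2)
  X <- rbind(matrix(rnorm(10), 5, 2), matrix(rnorm(10, 6), 5, 2))
  m1 <- kmeans_fit(X, 2, seed = 9)
  m2 <- kmeans_fit(rbind(X, X), 2, seed = 9)
  expect_equal(m2$wcss, 2 * m1$wcss, tolerance = 1e-8)
  o1 <- m1$centroids[order(m1$centroids[, 1]), ]
  o2 <- m2$centroids[order(m2$centroids[, 1]), ]
  expect_equal(o1, o2, tolerance = 1e-8)
})

test_that("restarted fits attain the enumerated optimum on small problems", {
  for (s in 1:8) {
    set.seed(s)
    n <- sample(4:8, 1)
    K <- sample(2:3, 1)
    X <- matrix(rnorm(2 * n), n, 2)
    fit <- kmeans_fit(X, K, seed = s, n_init = 10)
    expect_equal(fit$wcss, brute_force_wcss(X, K), tolerance = 1e-8)
    ## recomputable wcss from the assignment
    w <- sum(vapply(seq_len(n), function(i)
      sum((X[i, ] - fit$centroids[fit$assignment[i], ])^2), numeric(1)))
    expect_equal(fit$wcss, w, tolerance = 1e-10)
  }
})

test_that("WCSS is non-increasing across Lloyd iterations", {
  set.seed(6)
  X <- matrix(rnorm(100), 50, 2)
  m <- kmeans_fit(X, 4, seed = 6)
  expect_true(all(diff(m$wcss_trace) <= 1e-10))
})

test_that("our WCSS never loses to the stats::kmeans reference", {
  set.seed(12)
  X <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 4), 20),
             matrix(rnorm(40, 8), 20))
  ours <- kmeans_fit(X, 3, seed = 12)$wcss
  ref <- stats::kmeans(X, 3, nstart = 10)$tot.withinss
  expect_lte(ours, ref * (1 + 1e-8))
})

test_that("the SSE curve has the expected end points and elbow shape", {
  set.seed(5)
  X <- rbind(matrix(rnorm(16, 0, 0.2), 8, 2),
             matrix(rnorm(16, 5, 0.2), 8, 2),
             matrix(rnorm(16, c(0, 8), 0.2), 8, 2))
  sse <- sse_curve(X, 8, seed = 5)
  expect_equal(sse[1], sum(sweep(X, 2, colMeans(X))^2), tolerance = 1e-8)
  expect_true(all(diff(sse) <= 1e-8))
  ## 3 true groups: big drop into k = 3, marginal gains after
  expect_lt(sse[3], 0.2 * sse[2])
  expect_gt(sse[4], 0.5 * sse[3])
  full <- sse_curve(X, nrow(X), seed = 5)
  expect_equal(full[nrow(X)], 0, tolerance = 1e-10)
  expect_error(sse_curve(X, nrow(X) + 1, seed = 1), "k_max")
})

test_that("elbow selection maximises discrete curvature with low-k ties", {
  expect_equal(elbow_select(c(100, 30, 28, 27)), 2)
  expect_equal(elbow_select(c(40, 30, 20, 10)), 2)   # flat curvature: tie rule
  expect_equal(elbow_select(c(100, 80, 20, 18, 17)), 3)
  expect_error(elbow_select(c(3, 2)), "at least 3")
})

test_that("cluster assignments recover the generating phases", {
  camp <- simulate_campaign(kinetics_config(seed = 21), 3,
                            heterogeneity_config(kinetic_jitter_sd = 0.02))
  aug <- lapply(camp, augment_batch, points_per_gap = 2)
  X <- do.call(rbind, lapply(aug, `[[`, "X_aux"))
  ph <- unlist(lapply(aug, `[[`, "phase_label"))
  sc <- fit_scaler(X)
  pca <- fit_pca(apply_scaler(sc, X))
  Xp <- transform_pca(pca, apply_scaler(sc, X), select_components(pca, 0.99))
  km <- kmeans_fit(Xp, 3, seed = 21)
  expect_gte(rand_index(km$assignment, ph), 0.9)
})

test_that("domain matching follows nearest-centroid with low-id ties", {
  mk_dom <- function(id, centroid) structure(
    list(domain_id = id, samples_X = matrix(centroid, 1),
         samples_y = matrix(0), centroid = centroid, model_ref = NULL),
    class = "fx_domain")
  doms <- list(mk_dom(1, c(0, 0)), mk_dom(2, c(4, 0)))
  m <- match_domain(c(1, 0), doms)
  expect_equal(m$domain_id, 1)
  expect_equal(m$distances, c(1, 3))
  expect_equal(match_domain(c(4, 0), doms)$distances[2], 0)
  expect_equal(match_domain(c(2, 0), doms)$domain_id, 1)  # tie -> lowest id
  ## translation invariance
  doms_t <- list(mk_dom(1, c(10, 7)), mk_dom(2, c(14, 7)))
  expect_equal(match_domain(c(11, 7), doms_t)$distances, c(1, 3))
  expect_error(match_domain(c(1, 2, 3), doms), "dimension")
})

test_that("partitioning is exhaustive, disjoint, and rejects empty clusters", {
  set.seed(30)
  X <- matrix(rnorm(40), 20, 2)
  y <- matrix(rnorm(20))
  m <- kmeans_fit(X, 3, seed = 30)
  dom <- partition_domains(X, y, m)
  sizes <- vapply(dom, function(d) nrow(d$samples_X), 1L)
  expect_equal(sum(sizes), 20)
  for (d in dom)
    expect_equal(d$centroid, m$centroids[d$domain_id, ], tolerance = 1e-10)
  ## single domain contains everything
  m1 <- kmeans_fit(X, 1, seed = 1)
  expect_equal(nrow(partition_domains(X, y, m1)[[1]]$samples_X), 20)
  ## forced empty cluster errors with advice
  m_bad <- m
  m_bad$assignment[m_bad$assignment == 2] <- 1L
  expect_error(partition_domains(X, y, m_bad), "empty")
  expect_error(kmeans_fit(X, 21, seed = 1), "exceed")
})
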