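test_that("k-means: exact fits, determinism, and input validation", {
  # k equal to the number of distinct points: zero inertia
  X <- matrix(c(0, 0, 5, 5, 9, 1), 3, 2, byrow = TRUE)
  X3 <- X[rep(1:3, each = 4), ]
  fit <- kmeans_fit(X3, 3, seed = 1)
  expect_equal(fit$inertia, 0)
  # k = 1: total sum of squares about the grand centroid (closed form)
  Xr <- matrix(rnorm(60), 20, 3)
  fit1 <- kmeans_fit(Xr, 1, seed = 1)
  expect_equal(fit1$inertia, sum(sweep(Xr, 2, colMeans(Xr))^2),
               tolerance = 1e-9)
  # determinism under a fixed seed
  expect_identical(kmeans_fit(Xr, 3, seed = 7)$centroids,
                   kmeans_fit(Xr, 3, seed = 7)$centroids)
  Xbad <- Xr; Xbad[1] <- NA
  expect_error(kmeans_fit(Xbad, 2), "non-finite")
  expect_error(kmeans_fit(Xr, 21), "k must satisfy")
})

test_that("per-iteration inertia trace never increases", {
  set.seed(31)
  for (rep in 1:10) {
    X <- matrix(rnorm(200), 50, 4)
    fit <- kmeans_fit(X, sample(2:6, 1), restarts = 1)
    expect_true(all(diff(fit$inertia_trace) <= 1e-9))
  }
})

test_that("2-cluster fits on 8-point toys match exhaustive search", {
  set.seed(17)
  for (rep in 1:20) {
    X <- matrix(rnorm(16), 8, 2)
    oracle <- brute_best_2partition(X)
    fit <- kmeans_fit(X, 2, restarts = 20)
    expect_equal(fit$inertia, oracle$inertia, tolerance = 1e-8)
  }
})

test_that("two separated groups of 4 recover the true group means", {
  X <- rbind(matrix(rnorm(8, 0, 0.1), 4, 2),
             matrix(rnorm(8, 6, 0.1), 4, 2))
  fit <- kmeans_fit(X, 2, seed = 3)
  C <- fit$centroids[order(fit$centroids[, 1]), ]
  expect_equal(unname(C),
               unname(rbind(colMeans(X[1:4, ]), colMeans(X[5:8, ]))),
               tolerance = 1e-9)
})

test_that("elbow curve is non-increasing and zero at saturation", {
  X <- matrix(rnorm(150), 50, 3)
  inert <- elbow_curve(X, k_range = 1:8, restarts = 10, seed = 5)
  expect_equal(as.integer(names(inert)), 1:8)
  expect_true(all(diff(inert) <= 1e-6 * inert[1]))  # up to restart noise
  # exactly k distinct repeated points at that k -> inertia 0
  Xk <- matrix(c(0, 0, 4, 0, 0, 4), 3, 2, byrow = TRUE)[rep(1:3, 5), ]
  expect_equal(unname(elbow_curve(Xk, k_range = 3, seed = 1)), 0)
  expect_error(elbow_curve(X, k_range = 1:60), "infeasible")
})

test_that("silhouette agrees with the brute-force oracle on random instances", {
  set.seed(23)
  for (rep in 1:30) {
    n <- sample(6:50, 1)
    X <- matrix(rnorm(2 * n), n, 2)
    labels <- sample(1:3, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    got <- silhouette_scores(X, labels)
    expect_equal(got$s, brute_silhouette(X, labels), tolerance = 1e-9)
    expect_equal(got$mean, mean(brute_silhouette(X, labels)),
                 tolerance = 1e-9)
    expect_true(all(got$s >= -1 - 1e-12 & got$s <= 1 + 1e-12))
  }
})

test_that("silhouette matches cluster::silhouette and handles edge cases", {
  skip_if_not_installed("cluster")
  set.seed(5)
  X <- matrix(rnorm(80), 40, 2)
  labels <- sample(1:4, 40, replace = TRUE)
  got <- silhouette_scores(X, labels)
  ref <- cluster::silhouette(labels, dist(X))
  expect_equal(got$s, as.numeric(ref[, "sil_width"]), tolerance = 1e-9)
  # two tight far-apart clusters: mean silhouette near 1
  Y <- rbind(matrix(rnorm(20, 0, 0.05), 10, 2),
             matrix(rnorm(20, 50, 0.05), 10, 2))
  expect_gt(silhouette_scores(Y, rep(1:2, each = 10))$mean, 0.9)
  # point 0 in 1-D {0,2 | 1,3}: a = 2 and b = mean(1,3) = 2, so s = 0
  s <- silhouette_scores(matrix(c(0, 2, 1, 3)), c(1, 1, 2, 2))$s
  expect_equal(s[1], 0)
  # singleton clusters score 0 by convention
  s2 <- silhouette_scores(matrix(c(0, 5, 9)), c(1, 2, 3))$s
  expect_equal(s2, c(0, 0, 0))
  expect_error(silhouette_scores(X, rep(1, 40)), "single cluster")
})

test_that("select_k maximizes mean silhouette with smallest-k ties", {
  expect_equal(select_k(NULL, c(`2` = 0.4, `3` = 0.5, `5` = 0.7, `6` = 0.6)),
               5)
  expect_equal(select_k(NULL, c(`2` = 0.5, `3` = 0.5, `4` = 0.5)), 2)
  expect_error(select_k(NULL, numeric(0)), "empty")
})

test_that("assign_pattern picks the nearest centroid, low label on ties", {
  model <- structure(
    list(k = 3L,
         centroids = rbind(SM1 = c(0, 0), SM2 = c(4, 0), SM3 = c(0, 4)),
         norm_params = NULL),
    class = "pattern_model")
  expect_equal(assign_pattern(c(4, 0), model), "SM2")        # at a centroid
  expect_equal(assign_pattern(c(2, 0), model), "SM1")        # exact midpoint
  set.seed(9)
  for (rep in 1:50) {
    x <- rnorm(2, sd = 3)
    j <- brute_nearest_centroid(x, model$centroids)
    expect_equal(assign_pattern(x, model), rownames(model$centroids)[j])
  }
  expect_error(assign_pattern(c(0, 0), structure(list(), class = "pattern_model")),
               "not a fitted")
})

test_that("noiseless archetype data is recovered exactly (ARI = 1)", {
  skip_if_not_installed("mclust")
  cfg <- synthetic_config(n_users = 100, feature_noise_sd = rep(0, 5),
                          seed = 13)
  data <- generate_users(cfg)
  profiles <- build_profiles(data)
  model <- cspd(profiles, k = 5, seed = 13)
  labs <- model$labels[data$truth$uid]
  expect_equal(mclust::adjustedRandIndex(labs, data$truth$true_label), 1)
})

test_that("cspd on archetype data selects k = 5 and stores diagnostics", {
  cfg <- synthetic_config(n_users = 250, seed = 29)
  data <- generate_users(cfg)
  model <- cspd(build_profiles(data), k = "auto", seed = 29)
  expect_equal(model$k, 5L)
  expect_equal(names(model$silhouette_by_k), as.character(2:8))
  expect_true(all(model$silhouette_by_k >= -1 & model$silhouette_by_k <= 1))
  expect_true(all(model$inertia_by_k >= 0))
  path <- withr::local_tempfile(fileext = ".json")
  write_pattern_model(model, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$k, 5)
  expect_equal(length(back$centroids), 5)
})

test_that("clustering can drop the movement feature via the features switch", {
  cfg <- synthetic_config(n_users = 120, seed = 37)
  data <- generate_users(cfg)
  profiles <- build_profiles(data)
  four <- setdiff(sleep_feature_names(), "moving")
  model <- cspd(profiles, k = 5, restarts = 5, seed = 37, features = four)
  expect_equal(ncol(model$centroids), 4L)
  expect_equal(names(model$norm_params$center), four)
  # assignment from a full 5-feature profile honours the subset
  lab <- assign_pattern(profiles[[1]], model)
  expect_true(lab %in% rownames(model$centroids))
  st <- cdsrs_state(profiles, model,
                    simulate_ratings(
                      apply_normalization(profile_matrix(profiles, four),
                                          model$norm_params),
                      model$centroids, cfg))
  expect_equal(ncol(st$features), 4L)
})
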