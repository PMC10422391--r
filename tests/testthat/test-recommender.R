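# small fitted world shared across recommender tests
make_world <- function(seed = 19, n = 80, missing = 0.4) {
  cfg <- synthetic_config(n_users = n, nights_per_user = 3,
                          missing_rate = missing, seed = seed)
  data <- generate_users(cfg)
  profiles <- build_profiles(data)
  model <- cspd(profiles, k = 5, restarts = 5, seed = seed)
  features <- apply_normalization(profile_matrix(profiles),
                                  model$norm_params)
  rm <- simulate_ratings(features, model$centroids, cfg)
  state <- cdsrs_state(profiles, model, rm)
  list(cfg = cfg, profiles = profiles, model = model, features = features,
       rm = rm, state = state)
}

test_that("predict_rating reproduces hand-evaluated weighted averages", {
  raw <- rbind(U1 = c(NA, NA), U2 = c(4, 5), U3 = c(2, 1))
  colnames(raw) <- c("SM1", "SM2")
  rm <- rating_matrix(raw)
  nb <- function(uids, sims) data.frame(uid = uids, sim = sims)
  # equal weights -> plain mean
  expect_equal(predict_rating("U1", "SM1", nb(c("U2", "U3"), c(1, 1)),
                              rm)$r_predict, 3.0)
  # a single neighbor's weight cancels
  expect_equal(predict_rating("U1", "SM2", nb("U2", 0.5), rm)$r_predict, 5.0)
  # (0.8 * 5 + 0.2 * 1) / 1.0 = 4.2
  expect_equal(predict_rating("U1", "SM2", nb(c("U2", "U3"), c(0.8, 0.2)),
                              rm)$r_predict, 4.2, tolerance = 1e-12)
  # neighbor missing the rating is a contract violation
  raw2 <- raw; raw2["U3", "SM1"] <- NA
  rm2 <- rating_matrix(raw2)
  expect_error(predict_rating("U1", "SM1", nb(c("U2", "U3"), c(1, 1)), rm2),
               "contract violation")
  # empty or zero-mass neighborhoods are undefined
  expect_true(is.na(predict_rating("U1", "SM1", nb(character(), numeric()),
                                   rm)$r_predict))
  expect_equal(predict_rating("U1", "SM1", nb(c("U2", "U3"), c(0, 0)),
                              rm)$method, "undefined")
})

test_that("positive-weight predictions are convex combinations (fuzzed)", {
  set.seed(55)
  for (rep in 1:1000) {
    m <- sample(1:6, 1)
    ratings <- sample(1:5, m, replace = TRUE)
    sims <- runif(m, 0.01, 1)
    raw <- matrix(c(rep(NA, 1), ratings), ncol = 1,
                  dimnames = list(c("U0", paste0("N", seq_len(m))), "SM1"))
    rm <- rating_matrix(raw)
    p <- predict_rating("U0", "SM1",
                        data.frame(uid = paste0("N", seq_len(m)), sim = sims),
                        rm)
    expect_gte(p$r_predict, min(ratings) - 1e-12)
    expect_lte(p$r_predict, max(ratings) + 1e-12)
    expect_equal(p$r_predict, brute_weighted_avg(sims, ratings),
                 tolerance = 1e-12)
  }
})

test_that("knn fallback: single donor, empty-matrix prior, brute-force check", {
  feats <- matrix(rnorm(10 * 3), 10, 3,
                  dimnames = list(sprintf("U%02d", 1:10), NULL))
  raw <- matrix(NA_real_, 10, 2,
                dimnames = list(rownames(feats), c("SM1", "SM2")))
  # empty matrix: 3.0 prior
  expect_equal(knn_fallback("U01", "SM1", feats, rating_matrix(raw))$r_predict,
               3.0)
  # one rater: their rating
  raw1 <- raw; raw1["U05", "SM1"] <- 4
  expect_equal(knn_fallback("U01", "SM1", feats,
                            rating_matrix(raw1))$r_predict, 4.0)
  # nobody rated SM2 but SM1 has ratings: global mean
  raw2 <- raw; raw2["U05", "SM1"] <- 4; raw2["U06", "SM1"] <- 2
  expect_equal(knn_fallback("U01", "SM2", feats,
                            rating_matrix(raw2))$r_predict, 3.0)
  # k_nn = 3 among many raters matches a brute-force distance sort
  set.seed(61)
  for (rep in 1:25) {
    rawr <- raw
    raters <- sample(rownames(feats)[-1], sample(4:9, 1))
    rawr[raters, "SM1"] <- sample(1:5, length(raters), replace = TRUE)
    got <- knn_fallback("U01", "SM1", feats, rating_matrix(rawr), k_nn = 3)
    expect_equal(got$r_predict,
                 brute_knn_mean("U01", "SM1", feats, rawr, 3),
                 tolerance = 1e-12)
  }
})

test_that("top_n sorts by prediction, breaks ties by label, truncates", {
  w <- make_world()
  u <- rownames(w$rm$raw)[which(rowSums(!is.na(w$rm$raw)) <= 2)[1]]
  rec <- top_n(u, 2, w$state)
  expect_lte(nrow(rec$entries), 2)
  expect_true(all(diff(rec$entries$r_predict) <= 1e-12))
  expect_true(all(rec$entries$r_predict >= 1 & rec$entries$r_predict <= 5))
  expect_true(all(is.na(w$rm$raw[u, rec$entries$smid])))  # only unrated
  full <- top_n(u, 10, w$state)
  expect_equal(sort(full$entries$smid),
               colnames(w$rm$raw)[is.na(w$rm$raw[u, ])])
  # all patterns rated -> empty list
  raw_full <- w$rm$raw
  raw_full[u, ] <- 3
  st <- w$state; st$rm <- rating_matrix(raw_full)
  expect_equal(nrow(top_n(u, 3, st)$entries), 0)
  # tie-break: equal predictions come back in label order
  tied <- full$entries[duplicated(full$entries$r_predict) |
                         duplicated(full$entries$r_predict, fromLast = TRUE), ]
  if (nrow(tied) > 1) expect_equal(tied$smid, sort(tied$smid))
  expect_error(top_n(u, 0, w$state), "positive")
})

test_that("cold-start users always get a full-length list", {
  w <- make_world()
  raw <- w$rm$raw
  newbie <- rownames(raw)[1]
  raw[newbie, ] <- NA
  st <- w$state; st$rm <- rating_matrix(raw)
  rec <- top_n(newbie, 5, st)
  expect_equal(nrow(rec$entries), 5)
  expect_true(all(is.finite(rec$entries$r_predict)))
  # even on a fully empty matrix, the prior serves every pattern
  raw[] <- NA
  st$rm <- rating_matrix(raw)
  rec0 <- top_n(newbie, 5, st)
  expect_equal(nrow(rec0$entries), 5)
  expect_true(all(rec0$entries$r_predict == 3.0))
})

test_that("hybrid_round records feedback and stops re-recommending it", {
  w <- make_world()
  u <- rownames(w$rm$raw)[which(rowSums(!is.na(w$rm$raw)) <= 2)[1]]
  fb <- function(uid, smid) 4
  out <- hybrid_round(w$state, u, 3, fb)
  sm <- out$recommendations$entries$smid[1]
  expect_equal(out$state$rm$raw[u, sm], 4)
  expect_equal(out$state$profiles[[u]]$ratings[[sm]], 4)
  expect_equal(out$state$profiles[[u]]$feedback_round, 1L)
  rec2 <- top_n(u, 5, out$state)
  expect_false(sm %in% rec2$entries$smid)
  # features untouched by feedback
  expect_identical(out$state$profiles[[u]]$features, w$profiles[[u]]$features)
})

test_that("cf_global equals within-pattern prediction when one cluster holds all", {
  raw <- rbind(U1 = c(NA, 4), U2 = c(4, 5), U3 = c(2, 1), U4 = c(5, 4))
  colnames(raw) <- c("SM1", "SM2")
  rm <- rating_matrix(raw)
  labels <- c(U1 = "SM1", U2 = "SM1", U3 = "SM1", U4 = "SM1")
  nb <- neighbor_set("U1", rm, labels)
  raters <- nb[!is.na(rm$raw[nb$uid, "SM1"]), ]
  phra <- predict_rating("U1", "SM1", raters, rm)
  cf <- cf_global_baseline("U1", "SM1", rm)
  expect_equal(cf$r_predict, phra$r_predict, tolerance = 1e-12)
})

test_that("cf_global matches a brute-force weighted average", {
  set.seed(71)
  for (rep in 1:15) {
    rm <- random_rating_matrix(15, 5, missing = 0.3)
    Z <- normalize_ratings(rm)
    u <- sample(rownames(rm$raw), 1)
    sm <- sample(colnames(rm$raw), 1)
    raters <- setdiff(rownames(rm$raw)[!is.na(rm$raw[, sm])], u)
    sims <- vapply(raters, function(v) brute_cosine(Z[u, ], Z[v, ])$sim,
                   numeric(1))
    keep <- sims >= 0
    got <- cf_global_baseline(u, sm, rm)
    if (any(keep) && sum(sims[keep]) > 1e-12) {
      want <- unname(brute_weighted_avg(sims[keep], rm$raw[raters[keep], sm]))
      expect_equal(got$r_predict, want, tolerance = 1e-12)
    } else {
      expect_true(is.finite(got$r_predict))
    }
  }
})

test_that("cbf is exact at the centroid and recovers a noiseless slope", {
  w <- make_world()
  beta <- cbf_fit_beta(w$rm, w$features, w$model)
  cent_user <- rownames(w$features)[
    which.min(rowSums((w$features -
                         w$model$centroids[w$state$labels[rownames(w$features)],
                                           ])^2))]
  lab <- w$state$labels[[cent_user]]
  p <- cbf_baseline(cent_user, lab, w$features, w$model, beta)
  expect_gte(p$r_predict, 4.5)   # essentially at the centroid -> near max

  # recovery: users placed so the linear form lands exactly on integers
  beta_true <- 1.7
  r <- rep(1:5, times = 2)
  feats <- cbind((5 - r) / beta_true, 0)
  rownames(feats) <- sprintf("U%02d", seq_along(r))
  model <- structure(list(k = 1L, centroids = rbind(SM1 = c(0, 0)),
                          norm_params = NULL),
                     class = "pattern_model")
  raw <- matrix(r, ncol = 1, dimnames = list(rownames(feats), "SM1"))
  beta_hat <- cbf_fit_beta(rating_matrix(raw), feats, model)
  expect_lt(abs(beta_hat - beta_true) / beta_true, 0.05)

  # combination is the unweighted mean
  pc <- combine_cf_cbf(new_pred <- structure(
    list(uid = "U1", smid = "SM1", r_predict = 4, support = 2L,
         method = "cf_global"), class = "prediction"),
    structure(list(uid = "U1", smid = "SM1", r_predict = 2, support = 0L,
                   method = "cbf"), class = "prediction"))
  expect_equal(pc$r_predict, 3.0)
})
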