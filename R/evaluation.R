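#' Mean squared error
#'
#' `(1/n) * sum((actual - predicted)^2)`: squaring weights large errors
#' more heavily, so MSE blends bias and variance of the predictions.
#'
#' @param actual,predicted numeric vectors of equal nonzero length.
#' @return nonnegative scalar.
#' @export
mse <- function(actual, predicted) {
  if (length(actual) == 0L || length(actual) != length(predicted))
    stop("actual and predicted must have equal nonzero length", call. = FALSE)
  mean((actual - predicted)^2)
}

#' Mean absolute percentage error
#'
#' `(100/n) * sum(|actual - predicted| / actual)`, in percent.  Undefined
#' when any actual value is zero (the error is relative to the true
#' observation); ratings of 1–5 guarantee positivity in this package, but a
#' zero raises an explicit error rather than an infinity.
#'
#' @inheritParams mse
#' @return nonnegative percentage.
#' @export
mape <- function(actual, predicted) {
  if (length(actual) == 0L || length(actual) != length(predicted))
    stop("actual and predicted must have equal nonzero length", call. = FALSE)
  if (any(actual == 0))
    stop("mape undefined: actual contains zero", call. = FALSE)
  100 * mean(abs(actual - predicted) / abs(actual))
}

#' Per-user train/test split of observed ratings
#'
#' Holds out `test_frac` of each user's observed ratings (at least one for
#' users with two or more; users with a single rating keep it in training),
#' so every user contributes to both folds where possible.
#'
#' @param rm a [rating_matrix()].
#' @param test_frac held-out fraction (default 0.2).
#' @param seed RNG seed for the draw.
#' @return list with `train` (a `rating_matrix` with test entries masked),
#'   `test` (data frame `uid`, `smid`, `actual`) and `mask` (logical matrix
#'   of held-out positions).
#' @export
split_ratings <- function(rm, test_frac = 0.2, seed = NULL) {
  stopifnot(inherits(rm, "rating_matrix"))
  raw <- rm$raw
  mask <- matrix(FALSE, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  draw <- function() {
    for (i in seq_len(nrow(raw))) {
      obs <- which(!is.na(raw[i, ]))
      if (length(obs) < 2L) next
      n_test <- max(1L, round(test_frac * length(obs)))
      n_test <- min(n_test, length(obs) - 1L)   # keep >=1 training rating
      mask[i, sample(obs, n_test)] <- TRUE
    }
    mask
  }
  mask <- if (is.null(seed)) draw() else with_seed(seed, draw())
  if (!any(mask))
    stop("test fold is empty; not enough observed ratings", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  test <- data.frame(uid = rownames(raw)[idx[, 1]],
                     smid = colnames(raw)[idx[, 2]],
                     actual = raw[idx])
  train_raw <- raw
  train_raw[mask] <- NA
  list(train = rating_matrix(train_raw), test = test, mask = mask)
}

clip15 <- function(x) pmin(5, pmax(1, x))

# predict every held-out pair with the hybrid recommender (PHRA + fallback)
predict_heldout_cdsrs <- function(state, test) {
  pred <- numeric(nrow(test))
  for (u in unique(test$uid)) {
    rows <- which(test$uid == u)
    nb <- neighbor_set(u, state$rm, state$labels, state$tau)
    for (i in rows)
      pred[i] <- predict_one(state, u, test$smid[i], nb)$r_predict
  }
  clip15(pred)
}

# assemble the full pipeline once (shared by run_experiment and the
# feedback-trajectory diagnostic)
build_experiment <- function(config, seed, test_frac = 0.2, k_range = 1:8,
                             restarts = 10L, tau = 0, k_nn = 5L,
                             refit_every = 10L) {
  cfg <- config
  cfg$seed <- as.integer(seed)
  data <- generate_users(cfg)
  profiles <- build_profiles(data)
  model <- cspd(profiles, k = "auto", k_range = k_range, restarts = restarts,
                seed = seed + 101L)
  features <- apply_normalization(profile_matrix(profiles), model$norm_params)
  # users rate the system's own fitted patterns: in the deployed service the
  # rated "sleep patterns" are cluster outcomes, so the affinity ground truth
  # is anchored at the fitted centroids
  rm_full <- simulate_ratings(features, model$centroids, cfg,
                              seed = seed + 202L)
  sp <- split_ratings(rm_full, test_frac, seed = seed + 303L)
  state <- cdsrs_state(profiles, model, sp$train, tau = tau, k_nn = k_nn,
                       refit_every = refit_every, exclude = sp$mask)
  feedback_fn <- function(uid, smid)
    simulate_feedback(uid, smid, features, model$centroids, cfg)
  list(cfg = cfg, data = data, profiles = profiles, model = model,
       features = features, rm_full = rm_full, split = sp, state = state,
       feedback_fn = feedback_fn)
}

#' Run the four-model comparison experiment
#'
#' End-to-end benchmark on synthetic data: generate users, fit the pattern
#' model (k chosen by silhouette), simulate sparse ratings, split them
#' 80/20 per user, and score four predictors on the held-out fold:
#'
#' * `CF` — global user-based collaborative filtering (no pattern
#'   restriction, no feedback);
#' * `CBF` — content-based prediction from feature-to-centroid distance;
#' * `CF+CBF` — unweighted mean of the two;
#' * `CDSRS` — within-pattern collaborative filtering with Knn fallback,
#'   after `feedback_rounds` simulated feedback passes over the training
#'   data (held-out pairs are excluded from the loop's recommendations, so
#'   feedback can never reveal a test rating).
#'
#' Accuracy is reported as `100 - MAPE` alongside the raw errors.
#'
#' @param config a [synthetic_config()].
#' @param seed master seed for the run (generation, clustering, split and
#'   feedback all derive from it).
#' @param feedback_rounds simulated feedback passes for the hybrid model
#'   (default 10).
#' @param test_frac held-out fraction (default 0.2).
#' @param k_range candidate cluster counts (default `1:8`).
#' @param restarts K-means restarts (default 10).
#' @param tau similarity threshold (default 0).
#' @param k_nn fallback neighborhood size (default 5).
#' @return data frame of class `evaluation_report`: one row per model with
#'   `model`, `mse`, `mape`, `accuracy`, `n_test`, `seed`, `k_selected`.
#' @export
run_experiment <- function(config, seed, feedback_rounds = 10L,
                           test_frac = 0.2, k_range = 1:8, restarts = 10L,
                           tau = 0, k_nn = 5L) {
  ex <- build_experiment(config, seed, test_frac, k_range, restarts, tau,
                         k_nn)
  test <- ex$split$test
  n_test <- nrow(test)

  # static baselines on the raw training matrix
  cf_pred <- clip15(vapply(seq_len(n_test), function(i)
    cf_global_baseline(test$uid[i], test$smid[i], ex$split$train,
                       tau = tau)$r_predict, numeric(1)))
  beta <- cbf_fit_beta(ex$split$train, ex$features, ex$model)
  cbf_pred <- clip15(vapply(seq_len(n_test), function(i)
    cbf_baseline(test$uid[i], test$smid[i], ex$features, ex$model,
                 beta)$r_predict, numeric(1)))
  combo_pred <- clip15((cf_pred + cbf_pred) / 2)

  # hybrid model: feedback loop on training data, then held-out prediction
  state <- with_seed(seed + 404L,
                     run_feedback_loop(ex$state, feedback_rounds,
                                       ex$feedback_fn))
  cdsrs_pred <- predict_heldout_cdsrs(state, test)

  models <- list(CF = cf_pred, CBF = cbf_pred, `CF+CBF` = combo_pred,
                 CDSRS = cdsrs_pred)
  report <- do.call(rbind, lapply(names(models), function(m) {
    data.frame(model = m,
               mse = mse(test$actual, models[[m]]),
               mape = mape(test$actual, models[[m]]),
               accuracy = 100 - mape(test$actual, models[[m]]),
               n_test = n_test, seed = seed, k_selected = ex$model$k,
               config_digest = config_digest(config))
  }))
  class(report) <- c("evaluation_report", class(report))
  report
}

# compact, human-readable fingerprint of the generator settings
config_digest <- function(config) {
  paste0("u", config$n_users, "k", config$k_true, "n", config$nights_per_user,
         "|fsd:", paste(signif(config$feature_noise_sd, 3), collapse = ","),
         "|rsd:", signif(config$rating_noise_sd, 3),
         "|a:", signif(config$affinity_scale, 3),
         "|m:", signif(config$missing_rate, 3))
}

#' Wide MSE/MAPE comparison table
#'
#' Reshapes evaluation reports into the conventional comparison layout:
#' rows MSE and MAPE, one column per model, medians across seeds when
#' several runs are stacked.
#'
#' @param reports one or more stacked [run_experiment()] reports.
#' @return data frame with a `metric` column and one column per model.
#' @export
evaluation_table <- function(reports) {
  med <- stats::aggregate(cbind(mse, mape) ~ model, data = reports,
                          FUN = stats::median)
  ord <- intersect(c("CF", "CBF", "CF+CBF", "CDSRS"), med$model)
  med <- med[match(ord, med$model), ]
  out <- data.frame(metric = c("MSE", "MAPE"),
                    rbind(med$mse, med$mape))
  names(out)[-1] <- med$model
  out
}

#' Held-out error along the feedback loop
#'
#' Diagnostic for the feedback mechanism: runs the hybrid loop round by
#' round and records the held-out MAPE (and MSE) after each round, starting
#' from the pre-feedback state (round 0).
#'
#' @inheritParams run_experiment
#' @param rounds number of feedback rounds to trace (default 20).
#' @return data frame with `round`, `mse`, `mape`.
#' @export
feedback_trajectory <- function(config, seed, rounds = 20L, test_frac = 0.2,
                                k_range = 1:8, restarts = 10L, tau = 0,
                                k_nn = 5L) {
  ex <- build_experiment(config, seed, test_frac, k_range, restarts, tau,
                         k_nn)
  test <- ex$split$test
  traj <- new.env()
  p0 <- predict_heldout_cdsrs(ex$state, test)
  traj$rows <- list(data.frame(round = 0L, mse = mse(test$actual, p0),
                               mape = mape(test$actual, p0)))
  cb <- function(state, r) {
    p <- predict_heldout_cdsrs(state, test)
    traj$rows[[length(traj$rows) + 1L]] <-
      data.frame(round = r, mse = mse(test$actual, p),
                 mape = mape(test$actual, p))
  }
  with_seed(seed + 404L,
            run_feedback_loop(ex$state, rounds, ex$feedback_fn,
                              after_round = cb))
  do.call(rbind, traj$rows)
}
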