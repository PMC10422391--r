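new_prediction <- function(uid, smid, r_predict, support, method) {
  structure(list(uid = uid, smid = smid, r_predict = r_predict,
                 support = as.integer(support), method = method),
            class = "prediction")
}

#' @export
print.prediction <- function(x, ...) {
  cat(sprintf("Prediction %s ~ %s: %.3f  (%s, support %d)\n",
              x$uid, x$smid, x$r_predict, x$method, x$support))
  invisible(x)
}

#' Similarity-weighted rating prediction
#'
#' The hybrid predictor's core: the predicted rating of `smid` for `uid` is
#' the similarity-weighted average of the neighbors' raw 1–5 ratings,
#' `sum(sim_i * R_i) / sum(sim_i)`.  Every neighbor must have rated `smid`
#' (the caller filters the neighbor set).  With no neighbors or zero total
#' similarity the prediction is undefined (`r_predict = NA`, method
#' `"undefined"`); callers route such cases to [knn_fallback()].
#'
#' @param uid,smid target user and sleep-pattern label.
#' @param neighbors data frame with columns `uid` and `sim`, typically from
#'   [neighbor_set()] filtered to raters of `smid`.
#' @param rm a [rating_matrix()] supplying the neighbors' raw ratings.
#' @return a `prediction` object.
#' @export
predict_rating <- function(uid, smid, neighbors, rm) {
  stopifnot(inherits(rm, "rating_matrix"))
  if (nrow(neighbors) == 0L)
    return(new_prediction(uid, smid, NA_real_, 0L, "undefined"))
  r <- rm$raw[neighbors$uid, smid]
  if (any(is.na(r)))
    stop("neighbor without a rating for ", smid,
         ": contract violation", call. = FALSE)
  w <- neighbors$sim
  if (sum(w) <= 1e-12)
    return(new_prediction(uid, smid, NA_real_, nrow(neighbors), "undefined"))
  new_prediction(uid, smid, sum(w * r) / sum(w), nrow(neighbors), "phra")
}

#' Feature-space Knn fallback prediction
#'
#' Cold-start path: when the similarity-weighted prediction is undefined
#' (the "Nan" branch of the control flow), predict the mean raw rating of
#' the `k_nn` users nearest to `uid` in normalized feature space among all
#' users — any pattern label — who rated `smid`.  Fewer raters than `k_nn`
#' means all are used; no rater at all falls back to the global mean rating,
#' and an entirely empty matrix to the scale midpoint 3.0.  Always returns
#' a defined prediction: this is the cold-start guarantee.
#'
#' @param uid,smid target user and pattern label.
#' @param features n x 5 normalized feature matrix (rownames = uids).
#' @param rm a [rating_matrix()].
#' @param k_nn neighborhood size (default 5).
#' @return a `prediction` object (method `"knn_fallback"`).
#' @export
knn_fallback <- function(uid, smid, features, rm, k_nn = 5L) {
  stopifnot(inherits(rm, "rating_matrix"))
  raters <- rownames(rm$raw)[!is.na(rm$raw[, smid])]
  raters <- setdiff(raters, uid)
  if (length(raters) == 0L) {
    obs <- rm$raw[!is.na(rm$raw)]
    r <- if (length(obs)) mean(obs) else 3.0
    return(new_prediction(uid, smid, r, 0L, "knn_fallback"))
  }
  d <- cross_dist(features[uid, , drop = FALSE],
                  features[raters, , drop = FALSE])[1, ]
  take <- raters[order(d, raters)][seq_len(min(k_nn, length(raters)))]
  new_prediction(uid, smid, mean(rm$raw[take, smid]), length(take),
                 "knn_fallback")
}

#' Recommender state
#'
#' Bundles everything one round of recommendation needs: user profiles, the
#' fitted pattern model, normalized features, per-user pattern assignments,
#' and the rating matrix.  `exclude` is an optional logical matrix flagging
#' (user, pattern) pairs that must never be recommended — evaluation
#' harnesses use it to shield held-out ratings from the feedback loop.
#'
#' @param profiles named list of `user_profile`s.
#' @param model a fitted `pattern_model` (with `norm_params`).
#' @param rm a [rating_matrix()] whose columns match the model's labels.
#' @param tau similarity threshold for [neighbor_set()].
#' @param k_nn fallback neighborhood size.
#' @param refit_every refit pattern centroids every this many feedback
#'   rounds (default 10).
#' @param exclude optional logical matrix, same shape as the rating matrix.
#' @return an object of class `cdsrs_state`.
#' @export
cdsrs_state <- function(profiles, model, rm, tau = 0, k_nn = 5L,
                        refit_every = 10L, exclude = NULL) {
  stopifnot(inherits(model, "pattern_model"), inherits(rm, "rating_matrix"))
  fn <- names(model$norm_params$center) %||% sleep_feature_names()
  X <- profile_matrix(profiles, fn)
  Xn <- apply_normalization(X, model$norm_params)
  labels <- assign_pattern(X, model)
  names(labels) <- rownames(X)
  structure(
    list(profiles = profiles, model = model, rm = rm, features = Xn,
         labels = labels, tau = tau, k_nn = as.integer(k_nn),
         refit_every = as.integer(refit_every), round = 0L,
         exclude = exclude),
    class = "cdsrs_state")
}

#' @export
print.cdsrs_state <- function(x, ...) {
  cat(sprintf("CDSRS state: %d users, k = %d patterns, round %d\n",
              length(x$profiles), x$model$k, x$round))
  print(x$rm)
  invisible(x)
}

# PHRA with Knn fallback for a single (uid, smid); nb = full neighbor set
predict_one <- function(state, uid, smid, nb) {
  raters <- nb[!is.na(state$rm$raw[nb$uid, smid]), , drop = FALSE]
  p <- predict_rating(uid, smid, raters, state$rm)
  if (is.na(p$r_predict))
    p <- knn_fallback(uid, smid, state$features, state$rm, state$k_nn)
  p
}

#' Top-N sleep-pattern recommendations
#'
#' Predicts a rating for every pattern the user has not yet rated (the
#' similarity-weighted predictor, falling back to feature-space Knn when
#' undefined), sorts descending by predicted rating — ties by pattern label
#' ascending — and returns the first `n`.  Predictions are clipped to the
#' 1–5 rating scale.
#'
#' @param uid target user.
#' @param n number of recommendations requested (> 0).
#' @param state a [cdsrs_state()].
#' @return an object of class `recommendation_list`: `uid`, `entries`
#'   (data frame `smid`, `r_predict`, `method`), `n_requested`.
#' @export
top_n <- function(uid, n, state) {
  stopifnot(inherits(state, "cdsrs_state"))
  if (length(n) != 1L || is.na(n) || n <= 0)
    stop("n must be a positive count", call. = FALSE)
  smids <- colnames(state$rm$raw)
  open <- smids[is.na(state$rm$raw[uid, ])]
  if (!is.null(state$exclude))
    open <- setdiff(open, smids[state$exclude[uid, ]])
  if (length(open) == 0L) {
    entries <- data.frame(smid = character(), r_predict = numeric(),
                          method = character())
  } else {
    nb <- neighbor_set(uid, state$rm, state$labels, state$tau)
    preds <- lapply(open, function(sm) predict_one(state, uid, sm, nb))
    entries <- data.frame(
      smid = open,
      r_predict = pmin(5, pmax(1, vapply(preds, `[[`, numeric(1),
                                         "r_predict"))),
      method = vapply(preds, `[[`, character(1), "method"))
    entries <- entries[order(-entries$r_predict, entries$smid), , drop = FALSE]
    entries <- entries[seq_len(min(n, nrow(entries))), , drop = FALSE]
    rownames(entries) <- NULL
  }
  structure(list(uid = uid, entries = entries, n_requested = as.integer(n)),
            class = "recommendation_list")
}

#' @export
print.recommendation_list <- function(x, ...) {
  cat(sprintf("Top-%d recommendations for %s:\n", x$n_requested, x$uid))
  if (nrow(x$entries) == 0L) cat("  (nothing recommendable)\n")
  else print(x$entries)
  invisible(x)
}

#' One hybrid feedback round for a user
#'
#' The full loop the live system runs: recommend top-`n` patterns, obtain
#' the user's rating of the top entry through `feedback_fn`, fold it into
#' the profile ([reconstruct_profile()]) and the rating matrix, so the next
#' round's neighborhoods see it.  When everything recommendable is already
#' rated the state is returned unchanged.
#'
#' @param state a [cdsrs_state()].
#' @param uid user to serve.
#' @param n recommendations per round.
#' @param feedback_fn `function(uid, smid) -> rating in {1..5}`; in
#'   experiments a [simulate_feedback()] closure, in live use a prompt/API.
#' @return list with `recommendations` and the updated `state`.
#' @export
hybrid_round <- function(state, uid, n, feedback_fn) {
  rec <- top_n(uid, n, state)
  if (nrow(rec$entries) > 0L) {
    sm <- rec$entries$smid[1]
    rating <- feedback_fn(uid, sm)
    state$profiles[[uid]] <- reconstruct_profile(state$profiles[[uid]],
                                                 sm, rating)
    state$rm <- set_rating(state$rm, uid, sm, rating)
  }
  list(recommendations = rec, state = state)
}

#' Run simulated feedback rounds over all users
#'
#' Repeats [hybrid_round()] for every user, `rounds` times.  Pattern
#' centroids are refit (same k, same normalized features) every
#' `refit_every` rounds, as the live system would periodically re-cluster.
#'
#' @param state a [cdsrs_state()].
#' @param rounds number of passes over the users.
#' @param feedback_fn as in [hybrid_round()].
#' @param uids users to serve each round (default: all).
#' @param n recommendations per round (default 3).
#' @param after_round optional `function(state, round)` callback, e.g. to
#'   trace held-out error per round.
#' @return the final `cdsrs_state`.
#' @export
run_feedback_loop <- function(state, rounds, feedback_fn,
                              uids = names(state$profiles), n = 3L,
                              after_round = NULL) {
  for (r in seq_len(rounds)) {
    for (u in uids) {
      out <- hybrid_round(state, u, n, feedback_fn)
      state <- out$state
    }
    state$round <- state$round + 1L
    if (state$refit_every > 0L && state$round %% state$refit_every == 0L) {
      refit <- fit_patterns(state$features, state$model$k,
                            norm_params = state$model$norm_params,
                            inertia_by_k = state$model$inertia_by_k,
                            silhouette_by_k = state$model$silhouette_by_k)
      state$model <- refit
      state$labels <- refit$labels
    }
    if (!is.null(after_round)) after_round(state, r)
  }
  state
}

# --- baselines --------------------------------------------------------------

#' Global collaborative-filtering baseline
#'
#' The same similarity-weighted average as [predict_rating()], but neighbors
#' are drawn from all users who rated `smid` regardless of pattern label,
#' and there is no feedback loop.  An undefined weighted average falls back
#' to the item's mean training rating, then the global mean, then 3.0.
#'
#' @param uid,smid target pair.
#' @param rm a [rating_matrix()].
#' @param tau similarity threshold (default 0).
#' @return a `prediction` object (method `"cf_global"`).
#' @export
cf_global_baseline <- function(uid, smid, rm, tau = 0) {
  stopifnot(inherits(rm, "rating_matrix"))
  cand <- rownames(rm$raw)[!is.na(rm$raw[, smid])]
  cand <- setdiff(cand, uid)
  if (length(cand)) {
    sims <- sims_vs_user(uid, rm, cand)
    sims <- sims[sims$sim >= tau, , drop = FALSE]
    w <- sims$sim
    if (nrow(sims) && sum(w) > 1e-12) {
      r <- sum(w * rm$raw[sims$uid, smid]) / sum(w)
      return(new_prediction(uid, smid, r, nrow(sims), "cf_global"))
    }
  }
  item <- rm$raw[setdiff(rownames(rm$raw), uid), smid]
  item <- item[!is.na(item)]
  obs <- rm$raw[!is.na(rm$raw)]
  r <- if (length(item)) mean(item) else if (length(obs)) mean(obs) else 3.0
  new_prediction(uid, smid, r, length(item), "cf_global")
}

#' Content-based baseline and the CF + CBF combination
#'
#' The content model predicts from features alone:
#' `r = clip(5 - beta * dist(user, centroid of smid), 1, 5)`, with the slope
#' `beta` calibrated by least squares on the observed training ratings
#' (`cbf_fit_beta`, closed form `sum(d * (5 - r)) / sum(d^2)`).
#' `combine_cf_cbf` is the unweighted mean of a collaborative and a content
#' prediction.
#'
#' @param uid,smid target pair.
#' @param features normalized user-feature matrix (rownames = uids).
#' @param model a fitted `pattern_model` whose centroid labels match the
#'   rating-matrix columns.
#' @param beta calibrated distance slope from `cbf_fit_beta`.
#' @param rm training [rating_matrix()] (for calibration).
#' @return `cbf_baseline` / `combine_cf_cbf`: a `prediction`;
#'   `cbf_fit_beta`: a positive scalar.
#' @export
cbf_baseline <- function(uid, smid, features, model, beta) {
  if (!inherits(model, "pattern_model") || is.null(model$centroids))
    stop("model is not a fitted pattern model", call. = FALSE)
  d <- sqrt(sum((features[uid, ] - model$centroids[smid, ])^2))
  r <- min(5, max(1, 5 - beta * d))
  new_prediction(uid, smid, r, 0L, "cbf")
}

#' @rdname cbf_baseline
#' @export
cbf_fit_beta <- function(rm, features, model) {
  stopifnot(inherits(rm, "rating_matrix"))
  idx <- which(!is.na(rm$raw), arr.ind = TRUE)
  if (nrow(idx) == 0L) return(1.0)
  u <- rownames(rm$raw)[idx[, 1]]
  sm <- colnames(rm$raw)[idx[, 2]]
  d <- sqrt(rowSums((features[u, , drop = FALSE] -
                       model$centroids[sm, , drop = FALSE])^2))
  r <- rm$raw[idx]
  if (sum(d^2) <= 0) return(1.0)
  max(0, sum(d * (5 - r)) / sum(d^2))
}

#' @rdname cbf_baseline
#' @param p_cf,p_cbf `prediction` objects to combine.
#' @export
combine_cf_cbf <- function(p_cf, p_cbf) {
  new_prediction(p_cf$uid, p_cf$smid,
                 mean(c(p_cf$r_predict, p_cbf$r_predict)),
                 p_cf$support, "combo")
}
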