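#' Build a user profile from nightly records
#'
#' Aggregates a user's nightly sensor records by the arithmetic mean and
#' appends BMI from demographics, giving the 5-vector
#' (sleep_time, moving, sound, snoring, bmi) used for clustering and
#' content-based prediction.  The profile starts with no ratings and no
#' pattern label; both are filled in downstream.
#'
#' @param records data frame of nightly records for a single uid, with
#'   columns `uid, sleep_time, moving, sound, snoring`.
#' @param demographics one-row data frame (or list) with at least `bmi`;
#'   `birth` and `gender` are carried along when present.
#' @return an object of class `user_profile`.
#' @export
build_profile <- function(records, demographics) {
  if (nrow(records) == 0L)
    stop("cannot build a profile from zero records", call. = FALSE)
  uid <- unique(records$uid)
  if (length(uid) != 1L)
    stop("records must belong to a single uid", call. = FALSE)
  sensor <- sleep_feature_names()[1:4]
  meas <- as.matrix(records[, sensor])
  if (any(!is.finite(meas)))
    stop("non-finite measurement in records for ", uid, call. = FALSE)
  bmi <- as.numeric(demographics$bmi)
  if (length(bmi) != 1L || !is.finite(bmi))
    stop("demographics must supply one finite bmi", call. = FALSE)
  features <- c(colMeans(meas), bmi = bmi)
  names(features) <- sleep_feature_names()
  structure(
    list(uid = uid, features = features,
         birth = demographics$birth %||% NA_integer_,
         gender = demographics$gender %||% NA_character_,
         pattern_label = NA_character_,
         ratings = stats::setNames(numeric(0), character(0)),
         feedback_round = 0L),
    class = "user_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.user_profile <- function(x, ...) {
  cat(sprintf("User profile %s  (pattern: %s, feedback rounds: %d)\n",
              x$uid, x$pattern_label, x$feedback_round))
  print(round(x$features, 3))
  invisible(x)
}

#' Build profiles for every user in a dataset
#'
#' @param dataset a `cdsrs_dataset` (see [generate_users()] /
#'   [read_dataset()]).
#' @return a named list of [build_profile()] objects, keyed by uid.
#' @export
build_profiles <- function(dataset) {
  recs <- split(dataset$records, dataset$records$uid)
  demo <- dataset$users[match(names(recs), dataset$users$uid), ]
  out <- lapply(seq_along(recs),
                function(i) build_profile(recs[[i]], demo[i, ]))
  names(out) <- names(recs)
  out
}

#' Stack profile feature vectors into a matrix
#'
#' @param profiles a list of `user_profile`s.
#' @param features which profile features to keep, in order; the default is
#'   all five.  Dropping `"moving"` reproduces the four-feature variant
#'   (snoring, noise, BMI, sleep time) of the clustering stage.
#' @return n x length(features) numeric matrix, rownames = uids.
#' @export
profile_matrix <- function(profiles, features = sleep_feature_names()) {
  m <- t(vapply(profiles, function(p) p$features, numeric(5)))
  rownames(m) <- vapply(profiles, function(p) p$uid, character(1))
  colnames(m) <- sleep_feature_names()
  m[, features, drop = FALSE]
}

#' Fit and apply z-score normalization
#'
#' `fit_normalization` learns per-feature location (mean) and scale
#' (population SD, i.e. dividing by n — so a two-point feature {1, 3} maps
#' to exactly {-1, +1}); `apply_normalization` maps features into the
#' z-scored space in which all Euclidean distances are computed, and
#' `inverse_normalization` undoes it.
#'
#' @param x for fitting: an n x 5 feature matrix or a list of profiles;
#'   for applying: a feature matrix, vector, or `user_profile`.
#' @param params a `norm_params` object from `fit_normalization`.
#' @return `fit_normalization`: a `norm_params` list with `center` and
#'   `scale`; the others: a numeric vector or matrix of transformed features.
#' @export
fit_normalization <- function(x) {
  if (is.list(x) && !is.matrix(x) && !is.data.frame(x)) x <- profile_matrix(x)
  x <- as.matrix(x)
  if (nrow(x) < 2L)
    stop("normalization needs at least 2 profiles", call. = FALSE)
  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2, center)^2))
  if (any(scale <= 0)) {
    bad <- colnames(x)[scale <= 0] %||% which(scale <= 0)
    stop("degenerate constant feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(center = center, scale = scale), class = "norm_params")
}

#' @rdname fit_normalization
#' @export
apply_normalization <- function(x, params) {
  stopifnot(inherits(params, "norm_params"))
  if (inherits(x, "user_profile")) x <- x$features
  if (is.matrix(x) || is.data.frame(x))
    return(sweep(sweep(as.matrix(x), 2, params$center), 2, params$scale, "/"))
  (x - params$center) / params$scale
}

#' @rdname fit_normalization
#' @export
inverse_normalization <- function(x, params) {
  stopifnot(inherits(params, "norm_params"))
  if (is.matrix(x) || is.data.frame(x))
    return(sweep(sweep(as.matrix(x), 2, params$scale, "*"), 2, params$center,
                 "+"))
  x * params$scale + params$center
}

#' Fold one feedback rating into a profile
#'
#' Records the user's rating of a recommended pattern: the rating for that
#' label is set (overwriting any earlier one — latest wins, keeping the
#' feedback loop responsive) and the feedback round counter is incremented.
#' The feature vector is never touched by feedback.
#'
#' @param profile a `user_profile`.
#' @param smid pattern label being rated.
#' @param rating integer in `{1..5}`.
#' @return the updated `user_profile`.
#' @export
reconstruct_profile <- function(profile, smid, rating) {
  stopifnot(inherits(profile, "user_profile"))
  check_ratings(rating)
  profile$ratings[[smid]] <- as.numeric(rating)
  profile$feedback_round <- profile$feedback_round + 1L
  profile
}

#' Write / read profiles as JSON
#'
#' @param profiles named list of `user_profile`s.
#' @param path JSON file path.
#' @return `write_profiles` returns `path` invisibly; `read_profiles` the
#'   profile list.
#' @export
write_profiles <- function(profiles, path) {
  payload <- lapply(profiles, function(p)
    list(uid = p$uid, features = as.list(p$features),
         birth = p$birth, gender = p$gender,
         pattern_label = p$pattern_label,
         ratings = as.list(p$ratings),
         feedback_round = p$feedback_round))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(payload, function(p) {
    structure(
      list(uid = p$uid,
           features = stats::setNames(as.numeric(unlist(p$features)),
                                      sleep_feature_names()),
           birth = p$birth %||% NA_integer_,
           gender = p$gender %||% NA_character_,
           pattern_label = p$pattern_label %||% NA_character_,
           ratings = stats::setNames(as.numeric(unlist(p$ratings)),
                                     names(p$ratings)),
           feedback_round = as.integer(p$feedback_round)),
      class = "user_profile")
  })
  names(out) <- vapply(out, function(p) p$uid, character(1))
  out
}
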