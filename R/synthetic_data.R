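# RNG discipline: generators seed explicitly (fixed kinds, so results are
# stable across machines) and restore the caller's RNG state on exit.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

rnorm_trunc0 <- function(n, mean, sd) pmax(0, stats::rnorm(n, mean, sd))

#' Generate a synthetic motion-bed population
#'
#' Draws `n_users` users from the configured archetypes: each user gets a
#' latent feature vector (archetype mean plus Gaussian between-user noise,
#' truncated at zero) and `nights_per_user` nightly sensor records around it
#' (night-to-night noise at half the between-user SD).  BMI is a per-user
#' demographic, constant across nights.  The same config and seed give
#' bit-identical output.
#'
#' @param config a [synthetic_config()].
#' @return a list of class `cdsrs_dataset` with elements
#'   `records` (uid, night_index, sleep_time, moving, sound, snoring),
#'   `users` (uid, bmi, birth, gender) and `truth` (uid, true_label with
#'   labels in `0..k_true-1`).
#' @export
generate_users <- function(config) {
  stopifnot(inherits(config, "cdsrs_config"))
  n <- config$n_users
  k <- config$k_true
  sensor <- sleep_feature_names()[1:4]
  if (n == 0L) {
    empty_rec <- data.frame(uid = character(), night_index = integer(),
                            sleep_time = numeric(), moving = numeric(),
                            sound = numeric(), snoring = numeric())
    out <- list(records = empty_rec,
                users = data.frame(uid = character(), bmi = numeric(),
                                   birth = integer(), gender = character()),
                truth = data.frame(uid = character(), true_label = integer()))
    class(out) <- "cdsrs_dataset"
    return(out)
  }
  with_seed(config$seed, {
    uid <- sprintf("U%0*d", max(4L, nchar(n)), seq_len(n))
    label <- sample(0:(k - 1L), n, replace = TRUE)
    mu <- config$archetype_means[label + 1L, , drop = FALSE]
    sds <- config$feature_noise_sd
    latent <- matrix(0, n, 5L, dimnames = list(uid, sleep_feature_names()))
    for (j in 1:5)
      latent[, j] <- rnorm_trunc0(n, mu[, j], sds[j])
    nights <- config$nights_per_user
    rec_uid <- rep(uid, each = nights)
    rec <- data.frame(uid = rec_uid,
                      night_index = rep(seq_len(nights), times = n))
    for (j in seq_along(sensor))
      rec[[sensor[j]]] <- rnorm_trunc0(n * nights,
                                       rep(latent[, j], each = nights),
                                       0.5 * sds[j])
    users <- data.frame(uid = uid,
                        bmi = latent[, "bmi"],
                        birth = sample(1950:2005, n, replace = TRUE),
                        gender = sample(c("F", "M"), n, replace = TRUE),
                        row.names = NULL)
    out <- list(records = rec, users = users,
                truth = data.frame(uid = uid, true_label = label))
    class(out) <- "cdsrs_dataset"
    out
  })
}

#' @export
print.cdsrs_dataset <- function(x, ...) {
  cat(sprintf("Synthetic sleep dataset: %d users, %d nightly records\n",
              nrow(x$users), nrow(x$records)))
  invisible(x)
}

# distance from each row of features to each row of centroids (Euclidean)
cross_dist <- function(features, centroids) {
  d2 <- outer(rowSums(features^2), rowSums(centroids^2), "+") -
    2 * tcrossprod(features, centroids)
  sqrt(pmax(d2, 0))
}

# the shared affinity rating model: 5 minus scaled distance, plus noise,
# rounded (half to even, base R) and clipped to the 1..5 scale
affinity_rating <- function(dist, eps, affinity_scale) {
  pmin(5, pmax(1, round(5 - affinity_scale * dist + eps)))
}

#' Simulate the sleep rating matrix
#'
#' Users rate each pattern as a noisy decreasing function of their distance
#' to the pattern centroid in normalized feature space:
#' `clip(round(5 - affinity_scale * dist + eps), 1, 5)`,
#' `eps ~ N(0, rating_noise_sd)`.  Each entry is then independently masked
#' missing with probability `missing_rate`.
#'
#' @param features n x 5 matrix of user features (rownames = uids), in the
#'   same normalized space as `centroids`.
#' @param centroids k x 5 matrix of pattern centroids; rownames become the
#'   pattern labels (default `SM1..SMk`).
#' @param config a [synthetic_config()] (rating noise, affinity scale,
#'   missing rate).
#' @param seed RNG seed; defaults to `config$seed + 1` so that a dataset and
#'   its ratings are jointly reproducible yet independently drawn.
#' @return a [rating_matrix()] of raw 1–5 ratings with `NA` where masked.
#' @export
simulate_ratings <- function(features, centroids, config,
                             seed = config$seed + 1L) {
  stopifnot(inherits(config, "cdsrs_config"))
  features <- as.matrix(features)
  centroids <- as.matrix(centroids)
  if (ncol(features) != ncol(centroids))
    stop("features and centroids must share a feature space", call. = FALSE)
  if (is.null(rownames(centroids)))
    rownames(centroids) <- paste0("SM", seq_len(nrow(centroids)))
  if (is.null(rownames(features)))
    rownames(features) <- sprintf("U%04d", seq_len(nrow(features)))
  d <- cross_dist(features, centroids)
  with_seed(seed, {
    eps <- matrix(stats::rnorm(length(d), 0, config$rating_noise_sd),
                  nrow(d), ncol(d))
    raw <- affinity_rating(d, eps, config$affinity_scale)
    dim(raw) <- dim(d)   # pmin/pmax may drop matrix attributes
    raw[matrix(stats::runif(length(raw)) < config$missing_rate,
               nrow(raw), ncol(raw))] <- NA
    dimnames(raw) <- list(rownames(features), rownames(centroids))
    rating_matrix(raw)
  })
}

#' Simulate one feedback rating
#'
#' Draws a single rating for `uid` on the recommended pattern label from the
#' same affinity model as [simulate_ratings()].  Uses the current RNG state
#' unless `seed` is given, so a feedback loop seeds once and stays
#' reproducible.
#'
#' @param uid user identifier (must be a rowname of `features`).
#' @param smid recommended pattern label (rowname of `centroids`).
#' @param features,centroids as in [simulate_ratings()].
#' @param config a [synthetic_config()].
#' @param seed optional seed for a standalone reproducible draw.
#' @return a single integer rating in `{1..5}`.
#' @export
simulate_feedback <- function(uid, smid, features, centroids, config,
                              seed = NULL) {
  stopifnot(inherits(config, "cdsrs_config"))
  features <- as.matrix(features)
  centroids <- as.matrix(centroids)
  if (!uid %in% rownames(features)) stop("unknown uid: ", uid, call. = FALSE)
  if (!smid %in% rownames(centroids)) stop("unknown smid: ", smid, call. = FALSE)
  d <- sqrt(sum((features[uid, ] - centroids[smid, ])^2))
  draw <- function() {
    eps <- stats::rnorm(1, 0, config$rating_noise_sd)
    as.numeric(affinity_rating(d, eps, config$affinity_scale))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Write / read a synthetic dataset as CSV files
#'
#' Writes `records.csv`, `users.csv` and `truth.csv` (headers, UTF-8,
#' RFC-4180) into `dir`; a rating matrix, if supplied, goes to
#' `ratings.csv` as triplets.
#'
#' @param dataset a `cdsrs_dataset` from [generate_users()].
#' @param dir output directory (created if needed).
#' @param ratings optional [rating_matrix()].
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` a
#'   `cdsrs_dataset` (plus `ratings` when present on disk).
#' @export
write_dataset <- function(dataset, dir, ratings = NULL) {
  stopifnot(inherits(dataset, "cdsrs_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                         row.names = FALSE, quote = TRUE,
                                         fileEncoding = "UTF-8")
  wr(dataset$records, "records.csv")
  wr(dataset$users, "users.csv")
  wr(dataset$truth, "truth.csv")
  if (!is.null(ratings)) write_ratings_csv(ratings, file.path(dir, "ratings.csv"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f),
                                    stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8")
  out <- list(records = rd("records.csv"), users = rd("users.csv"),
              truth = if (file.exists(file.path(dir, "truth.csv")))
                rd("truth.csv") else NULL)
  class(out) <- "cdsrs_dataset"
  if (file.exists(file.path(dir, "ratings.csv")))
    out$ratings <- read_ratings_csv(file.path(dir, "ratings.csv"))
  out
}
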