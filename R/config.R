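#' Default sleep-pattern archetypes
#'
#' Five latent archetypes over the profile features
#' (sleep_time h, moving events/night, sound dB, snoring index, bmi kg/m2):
#' a long restful sleeper, a short sleeper, a heavy snorer, a restless
#' sleeper, and a sleeper in a noisy environment.  They span the plausible
#' range of motion-bed measurements and are mutually well separated, so
#' the generated population carries a recoverable cluster structure.
#'
#' @param k_true number of archetypes; only 5 has a built-in definition.
#' @return a `k_true` x 5 numeric matrix with feature column names.
#' @export
default_archetypes <- function(k_true = 5L) {
  if (k_true != 5L)
    stop("built-in archetypes exist only for k_true = 5; supply archetype_means",
         call. = FALSE)
  m <- rbind(
    restful_long  = c(7.9,  8, 33, 0.5, 22.0),
    short_sleeper = c(5.6, 16, 38, 1.2, 24.5),
    heavy_snorer  = c(6.4, 21, 54, 6.0, 30.5),
    restless      = c(6.9, 34, 44, 2.2, 26.0),
    noisy_room    = c(7.4, 12, 61, 1.4, 21.5)
  )
  colnames(m) <- sleep_feature_names()
  m
}

#' Profile feature names, in canonical order
#' @return character vector of the five profile features.
#' @export
sleep_feature_names <- function() {
  c("sleep_time", "moving", "sound", "snoring", "bmi")
}

#' Configuration for the synthetic motion-bed dataset
#'
#' Describes a population of `n_users` drawn from `k_true` latent sleep
#' archetypes, each observed for `nights_per_user` nights with Gaussian
#' measurement noise (truncated at zero: all sensor quantities are
#' nonnegative), plus a rating model: the rating a user gives a sleep
#' pattern decreases linearly with the distance between the user and the
#' pattern centroid in normalized feature space,
#' `clip(round(5 - affinity_scale * dist + eps), 1, 5)` with
#' `eps ~ N(0, rating_noise_sd)`, and each rating is independently missing
#' with probability `missing_rate`.
#'
#' @param n_users number of users (default 1000).
#' @param k_true number of latent archetypes (default 5).
#' @param nights_per_user nights recorded per user (default 7).
#' @param archetype_means `k_true` x 5 matrix of archetype feature means.
#' @param feature_noise_sd per-feature between-user SD around the archetype
#'   mean (length 5, nonnegative).
#' @param rating_noise_sd SD of the additive rating noise (>= 0).
#' @param affinity_scale positive slope of the distance-to-rating map.
#' @param missing_rate probability that a rating is unobserved, in \[0, 1\].
#' @param seed integer seed; identical configs give bit-identical datasets.
#' @return an object of class `cdsrs_config`.
#' @export
synthetic_config <- function(n_users = 1000L,
                             k_true = 5L,
                             nights_per_user = 7L,
                             archetype_means = NULL,
                             feature_noise_sd = c(0.35, 3.0, 2.5, 0.45, 1.2),
                             rating_noise_sd = 0.5,
                             affinity_scale = 1.2,
                             missing_rate = 0.5,
                             seed = 1L) {
  n_users <- as.integer(n_users)
  k_true <- as.integer(k_true)
  nights_per_user <- as.integer(nights_per_user)
  if (is.na(n_users) || n_users < 0L)
    stop("n_users must be a nonnegative count", call. = FALSE)
  if (is.na(k_true) || k_true < 1L)
    stop("k_true must be a positive count", call. = FALSE)
  if (is.na(nights_per_user) || nights_per_user < 1L)
    stop("nights_per_user must be a positive count", call. = FALSE)
  if (is.null(archetype_means)) archetype_means <- default_archetypes(k_true)
  archetype_means <- as.matrix(archetype_means)
  if (nrow(archetype_means) != k_true || ncol(archetype_means) != 5L)
    stop("archetype_means must have k_true rows and 5 columns", call. = FALSE)
  if (any(!is.finite(archetype_means)))
    stop("archetype_means must be finite", call. = FALSE)
  if (length(feature_noise_sd) != 5L || any(feature_noise_sd < 0))
    stop("feature_noise_sd must be 5 nonnegative values", call. = FALSE)
  if (length(rating_noise_sd) != 1L || rating_noise_sd < 0)
    stop("rating_noise_sd must be a nonnegative real", call. = FALSE)
  if (length(affinity_scale) != 1L || !is.finite(affinity_scale) ||
      affinity_scale <= 0)
    stop("affinity_scale must be positive", call. = FALSE)
  if (length(missing_rate) != 1L || missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]", call. = FALSE)
  colnames(archetype_means) <- sleep_feature_names()
  structure(
    list(n_users = n_users, k_true = k_true,
         nights_per_user = nights_per_user,
         archetype_means = archetype_means,
         feature_noise_sd = as.numeric(feature_noise_sd),
         rating_noise_sd = as.numeric(rating_noise_sd),
         affinity_scale = as.numeric(affinity_scale),
         missing_rate = as.numeric(missing_rate),
         seed = as.integer(seed)),
    class = "cdsrs_config")
}

#' @export
print.cdsrs_config <- function(x, ...) {
  cat("Synthetic sleep-data configuration\n")
  cat(sprintf("  users: %d   archetypes: %d   nights/user: %d   seed: %d\n",
              x$n_users, x$k_true, x$nights_per_user, x$seed))
  cat(sprintf("  rating noise SD: %.3g   affinity scale: %.3g   missing rate: %.3g\n",
              x$rating_noise_sd, x$affinity_scale, x$missing_rate))
  invisible(x)
}

#' Read / write a configuration as JSON
#' @param path file path.
#' @param config a `cdsrs_config`.
#' @return `read_config` returns a `cdsrs_config`; `write_config` the path,
#'   invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  synthetic_config(
    n_users = raw$n_users, k_true = raw$k_true,
    nights_per_user = raw$nights_per_user,
    archetype_means = if (!is.null(raw$archetype_means))
      matrix(unlist(raw$archetype_means), nrow = raw$k_true, byrow = TRUE),
    feature_noise_sd = raw$feature_noise_sd,
    rating_noise_sd = raw$rating_noise_sd,
    affinity_scale = raw$affinity_scale,
    missing_rate = raw$missing_rate,
    seed = raw$seed)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cdsrs_config"))
  out <- config
  out$archetype_means <- apply(config$archetype_means, 1, as.numeric,
                               simplify = FALSE)
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
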