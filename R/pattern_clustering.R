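# --- K-means core -----------------------------------------------------------
#
# Lloyd's algorithm with k-means++ seeding, written here rather than taken
# from stats::kmeans so that the per-iteration inertia trace is exposed (the
# monotonicity of that trace is a tested invariant) and empty-cluster repair
# is explicit (reseed at the point farthest from its centroid).

# squared Euclidean distances, n x k
cross_dist2 <- function(X, C) {
  pmax(outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C), 0)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- rep(Inf, n)
  for (j in seq_len(k - 1L)) {
    d2 <- pmin(d2, cross_dist2(X, X[idx[j], , drop = FALSE])[, 1])
    if (sum(d2) <= 0) {
      # fewer distinct points than k: fall back to sampling leftovers
      idx[j + 1L] <- sample(setdiff(seq_len(n), idx[seq_len(j)]), 1L)
    } else {
      idx[j + 1L] <- sample.int(n, 1L, prob = d2)
    }
  }
  X[idx, , drop = FALSE]
}

lloyd_once <- function(X, k, tol, max_iter) {
  C <- kmeanspp_init(X, k)
  trace <- numeric(0)
  labels <- integer(nrow(X))
  for (it in seq_len(max_iter)) {
    d2 <- cross_dist2(X, C)
    labels <- max.col(-d2, ties.method = "first")
    trace <- c(trace, sum(d2[cbind(seq_len(nrow(X)), labels)]))
    Cnew <- C
    for (j in seq_len(k)) {
      members <- labels == j
      if (any(members)) {
        Cnew[j, ] <- colMeans(X[members, , drop = FALSE])
      } else {
        # empty cluster: reseed at the point farthest from its own centroid
        far <- which.max(d2[cbind(seq_len(nrow(X)), labels)])
        Cnew[j, ] <- X[far, ]
        labels[far] <- j
      }
    }
    shift <- sqrt(max(rowSums((Cnew - C)^2)))
    C <- Cnew
    if (shift < tol) break
  }
  d2 <- cross_dist2(X, C)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(nrow(X)), labels)])
  list(centroids = C, labels = labels, inertia = inertia,
       inertia_trace = c(trace, inertia))
}

#' K-means clustering with restarts
#'
#' Lloyd's algorithm with k-means++ initialization; the best of `restarts`
#' runs by within-cluster sum of squares (inertia) is returned.  Convergence
#' when the largest centroid shift falls below `tol` or after `max_iter`
#' iterations.  The per-iteration inertia trace of the winning run is kept:
#' Lloyd iterations can never increase inertia.
#'
#' @param X numeric matrix, observations in rows.
#' @param k number of clusters, `2 <= k <= nrow(X)` (k = 1 allowed for the
#'   elbow curve).
#' @param restarts independent initializations (default 10).
#' @param tol centroid-shift convergence tolerance (default 1e-6).
#' @param max_iter iteration cap per restart (default 300).
#' @param seed optional seed for reproducible fits.
#' @return list with `centroids`, `labels` (1-based), `inertia`,
#'   `inertia_trace`.
#' @export
kmeans_fit <- function(X, k, restarts = 10L, tol = 1e-6, max_iter = 300L,
                       seed = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite values in input", call. = FALSE)
  if (k < 1L || k > nrow(X))
    stop("k must satisfy 1 <= k <= n (k = ", k, ", n = ", nrow(X), ")",
         call. = FALSE)
  run <- function() {
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- lloyd_once(X, k, tol, max_iter)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
    best
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# --- diagnostics ------------------------------------------------------------

#' Elbow curve: inertia as a function of k
#'
#' Fits K-means for every k in `k_range` and records the within-cluster sum
#' of squared distances, the quantity plotted against k in the elbow method.
#'
#' @inheritParams kmeans_fit
#' @param k_range candidate cluster counts (default `1:8`).
#' @return named numeric vector, inertia by k.
#' @export
elbow_curve <- function(X, k_range = 1:8, restarts = 10L, tol = 1e-6,
                        max_iter = 300L, seed = NULL) {
  X <- as.matrix(X)
  if (max(k_range) > nrow(X))
    stop("k = ", max(k_range), " infeasible for n = ", nrow(X), call. = FALSE)
  run <- function() {
    vapply(k_range, function(k)
      kmeans_fit(X, k, restarts, tol, max_iter)$inertia, numeric(1))
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  stats::setNames(out, k_range)
}

#' Silhouette scores
#'
#' For each point, cohesion `a(i)` is the mean distance to the other members
#' of its own cluster and separation `b(i)` the smallest mean distance to
#' any other cluster; `s(i) = (b - a) / max(a, b)`.  Points in singleton
#' clusters get `s(i) = 0`, as do points with `a = b`.
#'
#' @param X numeric matrix of observations (ignored when `D` is given).
#' @param labels integer cluster labels, at least two distinct values.
#' @param D optional precomputed full distance matrix (reused across k when
#'   selecting the cluster count).
#' @return list with per-point `s` and the `mean` silhouette.
#' @export
silhouette_scores <- function(X, labels, D = NULL) {
  if (is.null(D)) D <- as.matrix(stats::dist(as.matrix(X)))
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L)
    stop("silhouette undefined for a single cluster", call. = FALSE)
  n <- nrow(D)
  sizes <- tabulate(labels, k)
  ind <- matrix(0, n, k)
  ind[cbind(seq_len(n), labels)] <- 1
  sums <- D %*% ind                      # n x k: total distance to each cluster
  own <- sums[cbind(seq_len(n), labels)]
  a <- ifelse(sizes[labels] > 1L, own / (sizes[labels] - 1L), NA_real_)
  means <- sweep(sums, 2, sizes, "/")
  means[cbind(seq_len(n), labels)] <- Inf # exclude own cluster from b
  b <- apply(means, 1, min)
  s <- ifelse(is.na(a) | pmax(a, b) == 0, 0, (b - a) / pmax(a, b))
  s[!is.na(a) & a == b] <- 0
  list(s = as.numeric(s), mean = mean(s))
}

#' Choose the number of sleep patterns
#'
#' Two-step procedure: the elbow curve shortlists plausible cluster counts
#' (retained as a diagnostic), and the mean silhouette decides — the k with
#' the largest mean silhouette wins, ties going to the smallest k.
#'
#' @param inertia_by_k named vector from [elbow_curve()] (diagnostic only).
#' @param silhouette_by_k named vector of mean silhouettes for k >= 2.
#' @return the selected k (integer).
#' @export
select_k <- function(inertia_by_k, silhouette_by_k) {
  if (length(silhouette_by_k) == 0L)
    stop("empty candidate set for k selection", call. = FALSE)
  ks <- as.integer(names(silhouette_by_k))
  ord <- order(ks)
  ks <- ks[ord]; sil <- as.numeric(silhouette_by_k)[ord]
  ks[which.max(sil)]   # which.max takes the first maximum -> smallest k
}

#' Fit the sleep-pattern model
#'
#' Runs K-means on the normalized feature matrix and packages centroids with
#' the normalization parameters and the k-selection diagnostics, so new
#' users can be mapped into pattern labels later.
#'
#' @inheritParams kmeans_fit
#' @param norm_params the [fit_normalization()] parameters used to produce
#'   `X` (stored so new profiles can be normalized consistently).
#' @param inertia_by_k,silhouette_by_k optional diagnostics to carry along.
#' @return an object of class `pattern_model` with fields `k`, `centroids`
#'   (rownames `SM1..SMk`), `labels`, `inertia`, `inertia_trace`,
#'   `inertia_by_k`, `silhouette_by_k`, `norm_params`, `seed`.
#' @export
fit_patterns <- function(X, k, seed = NULL, restarts = 10L, tol = 1e-6,
                         max_iter = 300L, norm_params = NULL,
                         inertia_by_k = NULL, silhouette_by_k = NULL) {
  X <- as.matrix(X)
  fit <- kmeans_fit(X, k, restarts, tol, max_iter, seed = seed)
  rownames(fit$centroids) <- paste0("SM", seq_len(k))
  labels <- stats::setNames(rownames(fit$centroids)[fit$labels], rownames(X))
  structure(
    list(k = as.integer(k), centroids = fit$centroids, labels = labels,
         inertia = fit$inertia, inertia_trace = fit$inertia_trace,
         inertia_by_k = inertia_by_k, silhouette_by_k = silhouette_by_k,
         norm_params = norm_params, seed = seed),
    class = "pattern_model")
}

#' @export
print.pattern_model <- function(x, ...) {
  cat(sprintf("Sleep pattern model: k = %d, inertia = %.4g\n", x$k, x$inertia))
  if (!is.null(x$silhouette_by_k)) {
    cat("  mean silhouette by k: ",
        paste(sprintf("%s:%.3f", names(x$silhouette_by_k),
                      x$silhouette_by_k), collapse = "  "), "\n")
  }
  invisible(x)
}

#' Full pattern-definition stage
#'
#' Convenience wrapper for the whole cluster-definition stage: z-score the
#' profile features, compute the elbow curve over `k_range`, validate with
#' the mean silhouette for every k >= 2, select k (or use a fixed one), and
#' fit the final model.
#'
#' @param profiles named list of `user_profile`s, or an n x 5 feature matrix.
#' @param k `"auto"` (silhouette-selected) or a fixed integer.
#' @param k_range candidate counts for the diagnostics (default `1:8`).
#' @param features profile features used for clustering (default all five;
#'   pass `setdiff(sleep_feature_names(), "moving")` for the four-feature
#'   variant).  Ignored when `profiles` is already a matrix.
#' @inheritParams kmeans_fit
#' @return a `pattern_model` (see [fit_patterns()]).
#' @export
cspd <- function(profiles, k = "auto", k_range = 1:8, restarts = 10L,
                 tol = 1e-6, max_iter = 300L, seed = NULL,
                 features = sleep_feature_names()) {
  X_raw <- if (is.matrix(profiles)) profiles
           else profile_matrix(profiles, features)
  np <- fit_normalization(X_raw)
  X <- apply_normalization(X_raw, np)
  run <- function() {
    inertia <- stats::setNames(numeric(length(k_range)), k_range)
    sil <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
    D <- as.matrix(stats::dist(X))
    for (i in seq_along(k_range)) {
      kk <- k_range[i]
      fit <- kmeans_fit(X, kk, restarts, tol, max_iter)
      inertia[i] <- fit$inertia
      if (kk >= 2L && length(unique(fit$labels)) >= 2L)
        sil[i] <- silhouette_scores(labels = fit$labels, D = D)$mean
    }
    sil <- sil[!is.na(sil)]
    k_sel <- if (identical(k, "auto")) select_k(inertia, sil) else as.integer(k)
    fit_patterns(X, k_sel, restarts = restarts, tol = tol,
                 max_iter = max_iter, norm_params = np,
                 inertia_by_k = inertia, silhouette_by_k = sil)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Assign a profile to its nearest sleep pattern
#'
#' Normalizes the profile's features with the model's stored parameters and
#' returns the label of the nearest centroid by Euclidean distance, ties
#' going to the lowest label index.
#'
#' @param profile a `user_profile`, or a feature vector / matrix.  Raw
#'   features are expected when the model carries `norm_params`; otherwise
#'   features must already be normalized.
#' @param model a fitted `pattern_model`.
#' @return pattern label(s) (`"SM1"`, ...).
#' @export
assign_pattern <- function(profile, model) {
  if (!inherits(model, "pattern_model") || is.null(model$centroids))
    stop("model is not a fitted pattern model", call. = FALSE)
  x <- if (inherits(profile, "user_profile")) profile$features else profile
  if (!is.matrix(x)) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (!is.null(model$norm_params)) {
    fn <- names(model$norm_params$center)
    if (!is.null(fn) && !is.null(colnames(x)) && all(fn %in% colnames(x)))
      x <- x[, fn, drop = FALSE]    # model may cluster on a feature subset
    x <- apply_normalization(x, model$norm_params)
  }
  d2 <- cross_dist2(x, model$centroids)
  lab <- rownames(model$centroids)[max.col(-d2, ties.method = "first")]
  if (length(lab) == 1L) lab else stats::setNames(lab, rownames(x))
}

#' Write a fitted pattern model to JSON
#' @param model a `pattern_model`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_pattern_model <- function(model, path) {
  stopifnot(inherits(model, "pattern_model"))
  payload <- list(
    k = model$k,
    centroids = apply(model$centroids, 1, as.numeric, simplify = FALSE),
    inertia = model$inertia,
    inertia_by_k = as.list(model$inertia_by_k),
    silhouette_by_k = as.list(model$silhouette_by_k),
    norm_params = if (!is.null(model$norm_params))
      list(center = as.list(model$norm_params$center),
           scale = as.list(model$norm_params$scale)),
    seed = model$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
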