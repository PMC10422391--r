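# Independent brute-force oracles: explicit loops, no shared code with the
# package internals.  They are deliberately slow and only run on tiny inputs.

# cosine over co-rated entries of two rating rows (normalized scale, NA = missing)
brute_cosine <- function(a, b) {
  num <- 0; na2 <- 0; nb2 <- 0; n_co <- 0
  for (i in seq_along(a)) {
    if (!is.na(a[i]) && !is.na(b[i])) {
      num <- num + a[i] * b[i]
      na2 <- na2 + a[i]^2
      nb2 <- nb2 + b[i]^2
      n_co <- n_co + 1
    }
  }
  if (n_co == 0 || na2 == 0 || nb2 == 0) return(list(sim = 0, n_co = n_co))
  list(sim = unname(num / (sqrt(na2) * sqrt(nb2))), n_co = n_co)
}

# per-point silhouette from pairwise loops
brute_silhouette <- function(X, labels) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      mem <- which(labels == cl)
      b <- min(b, mean(vapply(mem, function(j) d(i, j), numeric(1))))
    }
    s[i] <- if (max(a, b) == 0 || a == b) 0 else (b - a) / max(a, b)
  }
  s
}

# exhaustive best 2-partition by within-cluster sum of squares
brute_best_2partition <- function(X) {
  n <- nrow(X)
  best <- Inf
  best_assign <- NULL
  for (code in 1:(2^(n - 1) - 1)) {      # fix point 1 in cluster 1; skip empty
    assign <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    wss <- 0
    for (cl in 1:2) {
      mem <- X[assign == cl, , drop = FALSE]
      if (nrow(mem) == 0) { wss <- Inf; break }
      ctr <- colMeans(mem)
      wss <- wss + sum(sweep(mem, 2, ctr)^2)
    }
    if (wss < best) { best <- wss; best_assign <- assign }
  }
  list(inertia = best, assign = best_assign)
}

# k-nearest raters by explicit sort
brute_knn_mean <- function(u, smid, features, raw, k) {
  raters <- setdiff(rownames(raw)[!is.na(raw[, smid])], u)
  d <- vapply(raters, function(v) sqrt(sum((features[u, ] - features[v, ])^2)),
              numeric(1))
  take <- raters[order(d, raters)][seq_len(min(k, length(raters)))]
  mean(raw[take, smid])
}

brute_weighted_avg <- function(sims, ratings) {
  num <- 0; den <- 0
  for (i in seq_along(sims)) {
    num <- num + sims[i] * ratings[i]
    den <- den + sims[i]
  }
  num / den
}

brute_mse <- function(a, p) {
  tot <- 0
  for (i in seq_along(a)) tot <- tot + (a[i] - p[i])^2
  tot / length(a)
}

brute_mape <- function(a, p) {
  tot <- 0
  for (i in seq_along(a)) tot <- tot + abs(a[i] - p[i]) / a[i]
  100 * tot / length(a)
}

brute_nearest_centroid <- function(x, centroids) {
  d <- vapply(seq_len(nrow(centroids)),
              function(j) sqrt(sum((x - centroids[j, ])^2)), numeric(1))
  which(d == min(d))[1]
}

# a small random rating matrix with controllable sparsity
random_rating_matrix <- function(n_users, n_items, missing = 0.3) {
  raw <- matrix(sample(1:5, n_users * n_items, replace = TRUE),
                n_users, n_items,
                dimnames = list(sprintf("U%02d", seq_len(n_users)),
                                paste0("SM", seq_len(n_items))))
  raw[matrix(runif(length(raw)) < missing, n_users, n_items)] <- NA
  rating_matrix(raw)
}

tiny_config <- function(...) {
  synthetic_config(n_users = 60, nights_per_user = 3, seed = 11, ...)
}
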