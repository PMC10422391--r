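# Cosine similarity over co-rated entries, vectorized over candidates.
# Operates on the normalized (-1..1) view; entries a pair has not both
# rated contribute nothing (pairwise-complete support: zero-filling unrated
# items would manufacture agreement).  Returns sim and co-rating counts.
sims_vs_user <- function(uid, rm, candidates) {
  Z <- normalize_ratings(rm)
  M <- !is.na(Z)
  Z[!M] <- 0
  zu <- Z[uid, ]
  mu <- M[uid, ]
  Zc <- Z[candidates, , drop = FALSE]
  Mc <- M[candidates, , drop = FALSE]
  dot <- as.numeric(Zc %*% zu)                   # zeros kill non-co-rated terms
  n2_c <- as.numeric((Zc^2) %*% mu)              # candidate norm on co-rated
  n2_u <- as.numeric(Mc %*% (zu^2))              # uid norm on co-rated
  n_co <- as.integer(Mc %*% mu)
  denom <- sqrt(n2_c * n2_u)
  sim <- ifelse(n_co == 0L | denom == 0, 0, dot / ifelse(denom == 0, 1, denom))
  sim <- pmin(1, pmax(-1, sim))                  # guard against rounding
  data.frame(uid = candidates, sim = sim, n_corated = n_co,
             stringsAsFactors = FALSE)
}

#' Similarity between two users on the sleep rating matrix
#'
#' Cosine similarity restricted to the sleep patterns both users have rated,
#' computed on the normalized \[-1, 1\] ratings, so the result itself lies in
#' \[-1, 1\]: +1 for users who rate patterns identically (up to positive
#' scale), -1 for opposite raters.  If the pair shares no rated pattern, or
#' either co-rated sub-vector is all zero (all midpoint ratings), the
#' similarity is 0 and `n_corated` records the support.
#'
#' @param uid_a,uid_b user identifiers present in the matrix.
#' @param rm a [rating_matrix()].
#' @return one-row data frame with `uid_a`, `uid_b`, `sim`, `n_corated`.
#' @export
sim_score <- function(uid_a, uid_b, rm) {
  stopifnot(inherits(rm, "rating_matrix"))
  for (u in c(uid_a, uid_b))
    if (!u %in% rownames(rm$raw)) stop("unknown uid: ", u, call. = FALSE)
  r <- sims_vs_user(uid_a, rm, uid_b)
  data.frame(uid_a = uid_a, uid_b = uid_b, sim = r$sim,
             n_corated = r$n_corated, stringsAsFactors = FALSE)
}

#' Ranked within-pattern neighbor set
#'
#' Candidate neighbors are the other users assigned the same sleep-pattern
#' label as `uid` (users from other patterns are ignored); pairs with
#' similarity below `tau` are dropped, the rest are sorted by similarity
#' descending (ties broken by uid lexical order) and truncated to
#' `max_neighbors`.  An empty result is valid — it is the cold-start path.
#'
#' @param uid target user.
#' @param rm a [rating_matrix()].
#' @param labels named character vector of assigned pattern labels per uid
#'   (e.g. `model$labels` or [assign_pattern()] output).
#' @param tau similarity threshold; default 0 keeps non-negative similarities
#'   so that prediction weights can never cancel.
#' @param max_neighbors cap on the neighborhood size (default unlimited).
#' @return data frame with `uid`, `sim`, `n_corated`, ranked.
#' @export
neighbor_set <- function(uid, rm, labels, tau = 0, max_neighbors = Inf) {
  stopifnot(inherits(rm, "rating_matrix"))
  if (!uid %in% names(labels))
    stop("uid has no assigned pattern label: ", uid, call. = FALSE)
  cand <- names(labels)[labels == labels[[uid]]]
  cand <- setdiff(intersect(cand, rownames(rm$raw)), uid)
  if (length(cand) == 0L)
    return(data.frame(uid = character(), sim = numeric(),
                      n_corated = integer()))
  res <- sims_vs_user(uid, rm, cand)
  res <- res[res$sim >= tau, , drop = FALSE]
  res <- res[order(-res$sim, res$uid), , drop = FALSE]
  if (is.finite(max_neighbors) && nrow(res) > max_neighbors)
    res <- res[seq_len(max_neighbors), , drop = FALSE]
  rownames(res) <- NULL
  res
}
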