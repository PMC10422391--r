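#' Sparse sleep rating matrix
#'
#' A users x sleep-pattern-labels matrix of integer ratings 1–5, with `NA`
#' marking unobserved entries.  With at most a handful of pattern labels the
#' matrix is stored dense; sparsity lives in the `NA` mask.  Similarity
#' computations use the normalized view in \[-1, 1\] (see
#' [normalize_ratings()]); predictions are made on the raw 1–5 scale.
#'
#' @param raw numeric matrix of ratings in `{1..5}` with `NA` for missing.
#' @param users,smids optional identifiers; default to dimnames of `raw`.
#' @return an object of class `rating_matrix`.
#' @export
rating_matrix <- function(raw, users = rownames(raw), smids = colnames(raw)) {
  raw <- as.matrix(raw)
  if (is.null(users) || is.null(smids))
    stop("users and smids must be supplied or present as dimnames",
         call. = FALSE)
  if (length(users) != nrow(raw) || length(smids) != ncol(raw))
    stop("dimnames length mismatch", call. = FALSE)
  check_ratings(raw[!is.na(raw)])
  storage.mode(raw) <- "double"
  dimnames(raw) <- list(users, smids)
  structure(list(raw = raw), class = "rating_matrix")
}

# shared 1..5 integer validation
check_ratings <- function(r) {
  if (length(r) && (any(!is.finite(r)) || any(r < 1 | r > 5) ||
                    any(r != round(r))))
    stop("ratings must be integers in {1..5}", call. = FALSE)
  invisible(r)
}

#' @export
print.rating_matrix <- function(x, ...) {
  obs <- sum(!is.na(x$raw))
  cat(sprintf("Sleep rating matrix: %d users x %d pattern labels, %d observed (%.1f%%)\n",
              nrow(x$raw), ncol(x$raw), obs, 100 * obs / max(1, length(x$raw))))
  invisible(x)
}

#' @export
dim.rating_matrix <- function(x) dim(x$raw)

#' Normalize ratings from the 1–5 scale to \[-1, 1\]
#'
#' Affine map `r -> (r - 3) / 2`, so 1 -> -1, 3 -> 0, 5 -> +1; missing
#' entries stay missing.  With `ternary = TRUE` the result is quantized to
#' `sign(r - 3)`, i.e. {-1, 0, +1} only.
#'
#' @param x a [rating_matrix()].
#' @param ternary quantize to {-1, 0, 1}? Default `FALSE` (continuous).
#' @return numeric matrix of normalized ratings with `NA` where unobserved.
#' @export
normalize_ratings <- function(x, ternary = FALSE) {
  stopifnot(inherits(x, "rating_matrix"))
  z <- (x$raw - 3) / 2
  if (ternary) z <- sign(z)
  z
}

#' Set or overwrite one rating
#'
#' @param x a [rating_matrix()].
#' @param uid,smid row / column identifiers (must exist).
#' @param rating integer in `{1..5}`.
#' @return the updated `rating_matrix`.
#' @export
set_rating <- function(x, uid, smid, rating) {
  stopifnot(inherits(x, "rating_matrix"))
  if (!uid %in% rownames(x$raw)) stop("unknown uid: ", uid, call. = FALSE)
  if (!smid %in% colnames(x$raw)) stop("unknown smid: ", smid, call. = FALSE)
  check_ratings(rating)
  x$raw[uid, smid] <- rating
  x
}

#' Read / write the rating matrix as a sparse triplet CSV
#'
#' Plain-text triplet format with header `uid,smid,rating`, one observed
#' entry per row (RFC-4180, UTF-8).
#'
#' @param x a [rating_matrix()].
#' @param path CSV file path.
#' @param users,smids full identifier sets; needed on read so that all-NA
#'   rows/columns survive the round trip (default: those present in the file).
#' @return `write_ratings_csv` returns `path` invisibly; `read_ratings_csv`
#'   a `rating_matrix`.
#' @export
write_ratings_csv <- function(x, path) {
  stopifnot(inherits(x, "rating_matrix"))
  idx <- which(!is.na(x$raw), arr.ind = TRUE)
  df <- data.frame(uid = rownames(x$raw)[idx[, 1]],
                   smid = colnames(x$raw)[idx[, 2]],
                   rating = as.integer(x$raw[idx]))
  df <- df[order(df$uid, df$smid), ]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_ratings_csv
#' @export
read_ratings_csv <- function(path, users = NULL, smids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!all(c("uid", "smid", "rating") %in% names(df)))
    stop("ratings CSV needs columns uid, smid, rating", call. = FALSE)
  if (is.null(users)) users <- sort(unique(df$uid))
  if (is.null(smids)) smids <- sort(unique(df$smid))
  raw <- matrix(NA_real_, length(users), length(smids),
                dimnames = list(users, smids))
  raw[cbind(match(df$uid, users), match(df$smid, smids))] <- df$rating
  rating_matrix(raw)
}
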