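#' Harrell's concordance index via order-indicator products
#'
#' Fraction of comparable patient pairs whose prediction order matches
#' their survival order. Predictions are risk scores: higher score should
#' mean shorter survival. A pair is comparable unless both patients have
#' events at the same time, or the shorter observed time is censored
#' (then the true order is unknown). Formally the survival-order
#' indicator is +1/-1 when the order is determinable and 0 otherwise; the
#' prediction-order indicator is the sign of the score difference; a pair
#' is concordant when the product is 1. Tied predictions give product 0:
#' the pair stays in the denominator but adds nothing to the numerator.
#'
#' @param predictions Numeric risk scores, length n.
#' @param time,event Survival outcome vectors.
#' @return The concordance index in `[0, 1]`.
#' @export
concordance_index <- function(predictions, time, event) {
  D <- survival_order_matrix(time, event)
  if (!any(D != 0)) stop("no comparable pairs for concordance")
  concordance_from_matrix(predictions, D)
}

# D[i, j] = +1 if patient i determinably survives longer than j,
# -1 if shorter, 0 if the pair is not comparable. Upper triangle used.
survival_order_matrix <- function(time, event) {
  n <- length(time)
  ti <- matrix(time, n, n)
  tj <- t(ti)
  ei <- matrix(event, n, n)
  ej <- t(ei)
  # i outlives j: j has an event, and either strictly earlier, or at the
  # same time with i censored (i is then known to survive past it)
  longer <- (ej == 1) & ((tj < ti) | (tj == ti & ei == 0))
  D <- matrix(0L, n, n)
  D[longer] <- 1L
  D[t(longer)] <- -1L
  D[longer & t(longer)] <- 0L   # defensive; cannot both hold
  diag(D) <- 0L
  D
}

concordance_from_matrix <- function(predictions, D) {
  n <- length(predictions)
  P <- sign(outer(predictions, predictions, FUN = function(a, b) b - a))
  ut <- upper.tri(D)
  comparable <- ut & D != 0
  concordant <- comparable & (D * P == 1)
  sum(concordant) / sum(comparable)
}

#' Jaccard stability of a collection of signatures
#'
#' Mean over all unordered pairs of signatures of
#' |intersection| / |union|. Signatures may differ in size. A pair of
#' empty signatures counts as perfectly stable (contributes 1); this is
#' logged because it only arises in degenerate runs.
#'
#' @param signatures List (length >= 2) of character vectors of feature
#'   ids.
#' @return Value in `[0, 1]`.
#' @export
jaccard_stability <- function(signatures) {
  if (length(signatures) < 2) stop("need at least 2 signatures")
  signatures <- lapply(signatures, unique)
  pairs <- utils::combn(length(signatures), 2)
  vals <- apply(pairs, 2, function(ij) {
    a <- signatures[[ij[1]]]; b <- signatures[[ij[2]]]
    u <- length(union(a, b))
    if (u == 0) return(NA_real_)
    length(intersect(a, b)) / u
  })
  if (anyNA(vals)) {
    message("jaccard_stability: ", sum(is.na(vals)),
            " empty-empty pairs counted as 1")
    vals[is.na(vals)] <- 1
  }
  mean(vals)
}

#' Kuncheva stability index for equal-size signatures
#'
#' Chance-corrected mean pairwise overlap: for signatures of size k over
#' a universe of p features, a pair contributes
#' `(|intersection| - k^2/p) / (k - k^2/p)`. Random k-subsets score 0 on
#' average; identical signatures score 1.
#'
#' @param signatures List (length >= 2) of character vectors, all of the
#'   same size k with `0 < k < p`.
#' @param p Universe size (number of candidate features).
#' @return Value in `[-1, 1]`.
#' @export
kuncheva_index <- function(signatures, p) {
  if (length(signatures) < 2) stop("need at least 2 signatures")
  sizes <- lengths(lapply(signatures, unique))
  k <- sizes[1]
  if (!all(sizes == k))
    stop("Kuncheva index requires signatures of the same size; got sizes ",
         paste(sizes, collapse = ", "))
  if (k <= 0 || k >= p)
    stop("need 0 < k < p (k = ", k, ", p = ", p, ")")
  expect <- k^2 / p
  pairs <- utils::combn(length(signatures), 2)
  vals <- apply(pairs, 2, function(ij) {
    ov <- length(intersect(signatures[[ij[1]]], signatures[[ij[2]]]))
    (ov - expect) / (k - expect)
  })
  mean(vals)
}

# Canberra distance between two ranked top-k lists (vectors ordered by
# rank, best first). Features absent from a list take rank k + 1;
# features absent from both contribute 0 and are skipped.
canberra_topk_pair <- function(a, b, k) {
  feats <- union(a, b)
  ra <- match(feats, a); ra[is.na(ra)] <- k + 1
  rb <- match(feats, b); rb[is.na(rb)] <- k + 1
  sum(abs(ra - rb) / (ra + rb))
}

.canberra_cache <- new.env(parent = emptyenv())

# Expected Canberra top-k distance of two independent uniformly random
# ranked k-lists over p features; Monte-Carlo with a fixed internal seed
# so the normalizer is a deterministic constant per (k, p).
expected_random_canberra <- function(k, p, n_draws = 10000) {
  key <- paste(k, p, n_draws, sep = "_")
  if (!is.null(.canberra_cache[[key]])) return(.canberra_cache[[key]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(20251201L)
  ids <- seq_len(p)
  tot <- 0
  for (i in seq_len(n_draws)) {
    tot <- tot + canberra_topk_pair(sample(ids, k), sample(ids, k), k)
  }
  val <- tot / n_draws
  .canberra_cache[[key]] <- val
  val
}

#' Canberra rank distance between ranked signatures
#'
#' Measures how well the order of feature contributions is preserved
#' across signatures. Each signature is a top-k list (features ordered by
#' decreasing coefficient magnitude, rank 1 = largest); features outside
#' a list take rank k + 1. A pair's distance is
#' `sum_f |r_A(f) - r_B(f)| / (r_A(f) + r_B(f))` over the union of the
#' lists, and the reported value is the mean pairwise distance divided by
#' the expected distance of two independent uniformly random top-k lists
#' over the p-feature universe (Monte-Carlo, 10000 draws, fixed internal
#' seed), so chance-level order preservation scores about 1.
#'
#' @param signatures List (length >= 2) of ranked character vectors, all
#'   of size k (rank order = vector order).
#' @param p Universe size.
#' @return Normalized distance >= 0 (0 = identical ranked lists).
#' @export
canberra_rank_distance <- function(signatures, p) {
  if (length(signatures) < 2) stop("need at least 2 signatures")
  sizes <- lengths(signatures)
  k <- sizes[1]
  if (!all(sizes == k)) stop("ranked signatures must share one size")
  if (any(vapply(signatures, anyDuplicated, integer(1)) > 0))
    stop("ranked signatures must not contain duplicate features")
  pairs <- utils::combn(length(signatures), 2)
  raw <- mean(apply(pairs, 2, function(ij)
    canberra_topk_pair(signatures[[ij[1]]], signatures[[ij[2]]], k)))
  raw / expected_random_canberra(k, p)
}

#' Rank-penalized Kuncheva index
#'
#' Summary of membership stability and rank preservation: the ratio of
#' the (non-negativity-clamped) Kuncheva index to the normalized Canberra
#' rank distance of the same ranked signatures. Ranges from 0 (chance
#' overlap or worse) to Inf (identical sets with identical ranks).
#'
#' @param signatures List of ranked character vectors of equal size.
#' @param p Universe size.
#' @return Value in `[0, Inf]`.
#' @export
rank_penalized_kuncheva <- function(signatures, p) {
  num <- max(kuncheva_index(signatures, p), 0)
  if (num == 0) return(0)
  den <- canberra_rank_distance(signatures, p)
  if (den == 0) Inf else num / den
}

#' One-sided paired comparison of two methods over shared splits
#'
#' Paired one-sided t-test on the per-split differences of a metric
#' between two methods evaluated on identical data splits (the pairing
#' that the shared-split experimental design supports).
#'
#' @param a,b Metric values for the two methods, same split ordering,
#'   length >= 3.
#' @param alternative `"greater"` tests whether `a` exceeds `b` on
#'   average; `"less"` the reverse.
#' @return The one-sided p-value.
#' @export
paired_welch_test <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b), length(a) >= 3)
  d <- a - b
  if (stats::sd(d) == 0) {
    message("paired_welch_test: zero-variance differences; p from sign")
    m <- mean(d)
    if (m == 0) return(0.5)
    hit <- (m > 0) == (alternative == "greater")
    return(if (hit) 0 else 1)
  }
  stats::t.test(a, b, paired = TRUE, alternative = alternative)$p.value
}
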