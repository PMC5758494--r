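# Quantile risk ranks and per-rank summaries -----------------------------

#' Classify probabilities into quantile risk ranks
#'
#' Class boundaries sit at the 20/40/60/80 percentiles (for the default 5
#' classes) of the probability vector, using the linear-interpolation
#' percentile definition (`stats::quantile` type 7). A value lying exactly
#' on a boundary goes to the lower class, so an all-constant vector maps
#' entirely to rank 1. Rank 5 = very high, 4 = high, 3 = intermediate,
#' 2 = low, 1 = negligible.
#'
#' @param probabilities Named (by waterbody id) probability vector.
#' @param n_classes Number of quantile classes (default 5).
#' @return Object of class `risk_ranking`: data frame `id`, `prob`, `rank`.
#' @export
rank_by_quantiles <- function(probabilities, n_classes = 5) {
  if (length(probabilities) == 0) {
    stop("cannot rank an empty probability vector", call. = FALSE)
  }
  if (anyNA(probabilities)) {
    stop("probabilities contain missing values", call. = FALSE)
  }
  qs <- quantile(probabilities, probs = seq_len(n_classes - 1) / n_classes,
                 type = 7, names = FALSE)
  rank <- rep(1L, length(probabilities))
  for (k in seq_along(qs)) {
    rank[probabilities > qs[k]] <- k + 1L
  }
  ids <- names(probabilities)
  if (is.null(ids)) ids <- as.character(seq_along(probabilities))
  structure(
    data.frame(id = ids, prob = as.numeric(probabilities), rank = rank,
               stringsAsFactors = FALSE),
    class = c("risk_ranking", "data.frame")
  )
}

#' Count waterbodies at or above a risk rank
#'
#' @param ranking A `risk_ranking`.
#' @param rank Threshold rank in 1..5.
#' @param digits,method Percentage formatting, see [pct_of()].
#' @return List: `count`, `percentage` (of all ranked waterbodies).
#' @export
count_at_or_above <- function(ranking, rank, digits = 2,
                              method = "truncate") {
  if (!is.numeric(rank) || rank < 1 || rank > 5) {
    stop("rank must lie in 1..5", call. = FALSE)
  }
  n <- sum(ranking$rank >= rank)
  list(count = n,
       percentage = pct_of(n, nrow(ranking), digits, method))
}

#' Union and intersection of two species' sets at a risk rank
#'
#' Takes the waterbodies at exactly the given rank (rank 5 usage: the
#' "very high" sets) in each ranking and reports the inclusion-exclusion
#' union, the intersection, and the union as a percentage of all
#' waterbodies.
#'
#' @param ranking_a,ranking_b `risk_ranking`s over the same waterbody set.
#' @param rank Rank defining the sets (default 5).
#' @param digits,method Percentage formatting, see [pct_of()].
#' @return List: `union`, `intersection`, `count_a`, `count_b`,
#'   `percentage`.
#' @export
union_at_rank <- function(ranking_a, ranking_b, rank = 5, digits = 2,
                          method = "truncate") {
  if (!setequal(ranking_a$id, ranking_b$id)) {
    stop("rankings cover different waterbody sets", call. = FALSE)
  }
  a <- ranking_a$id[ranking_a$rank == rank]
  b <- ranking_b$id[ranking_b$rank == rank]
  inter <- length(intersect(a, b))
  uni <- length(a) + length(b) - inter
  list(union = uni, intersection = inter,
       count_a = length(a), count_b = length(b),
       percentage = pct_of(uni, nrow(ranking_a), digits, method))
}
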