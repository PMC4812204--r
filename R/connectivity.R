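#' Kolmogorov-Smirnov tag-enrichment score
#'
#' The CMAP tag-list statistic: given the positions `V(1) < ... < V(t)` of
#' `t` tagged probes within a ranked list of `n`, compute
#' \deqn{a = \max_j \left[ j/t - V(j)/n \right], \quad
#'       b = \max_j \left[ V(j)/n - (j-1)/t \right]}
#' and return `a` if `a > b`, else `-b`. Positive scores mean the tags
#' concentrate near the top of the list (rank 1 = most up-regulated by the
#' treatment); negative scores mean they sit near the bottom.
#'
#' Equivalently, `a` and `b` are the suprema of the signed deviation between
#' the tag empirical CDF and the uniform CDF (the negative side taken as the
#' left limit at jumps), the classical one-sample KS decomposition.
#'
#' @param positions Integer vector of tag ranks, values in `1..n`, no
#'   duplicates (order irrelevant; sorted internally).
#' @param n Length of the ranked list.
#' @return A score in (-1, 1].
#' @examples
#' ks_tag_score(c(1, 2), 10)   #  0.8: tags at the very top
#' ks_tag_score(c(9, 10), 10)  # -0.9: tags at the very bottom
#' @export
ks_tag_score <- function(positions, n) {
  if (length(positions) == 0) abort("empty tag list.")
  positions <- as.integer(positions)
  if (anyDuplicated(positions)) abort("duplicate tag positions.")
  if (any(positions < 1L) || any(positions > n)) {
    abort("tag positions must lie in 1..n.")
  }
  v <- sort(positions)
  t <- length(v)
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Combine up- and down-tag KS scores into a raw connectivity score
#'
#' A query signature connects to an instance only when its up and down sets
#' are enriched at *opposite* ends of the ranked list. When the two KS
#' scores share a sign (both strictly positive or both strictly negative)
#' the raw score is 0; otherwise it is `up_score - down_score`. A single
#' zero score counts as opposite-signed, so a one-sided signal still scores.
#'
#' @param up_score,down_score KS tag scores in `[-1, 1]` (vectorized).
#' @return Raw connectivity score(s) in `[-2, 2]`.
#' @examples
#' combine_scores(-0.077, 0.223)  # -0.3
#' combine_scores(0.5, 0.5)       #  0
#' @export
combine_scores <- function(up_score, down_score) {
  same_sign <- up_score * down_score > 0
  ifelse(same_sign, 0, up_score - down_score)
}

#' Normalize raw connectivity scores across instances to [-1, 1]
#'
#' The CMAP display convention: let `p` be the largest positive raw score
#' and `q` the most negative. Positive raw scores are divided by `p`,
#' negative ones by `|q|`, zeros stay zero — so the extreme instance on each
#' side attains exactly +1 / -1. Scale-free: multiplying all raw scores by a
#' positive constant leaves the result unchanged.
#'
#' @param raw_scores Numeric vector of raw scores (at least one).
#' @return Numeric vector of connectivity scores in `[-1, 1]`.
#' @export
normalize_connectivity <- function(raw_scores) {
  if (length(raw_scores) == 0) abort("need at least one instance.")
  out <- numeric(length(raw_scores))
  pos <- raw_scores > 0
  neg <- raw_scores < 0
  if (any(pos)) out[pos] <- raw_scores[pos] / max(raw_scores[pos])
  if (any(neg)) out[neg] <- raw_scores[neg] / abs(min(raw_scores[neg]))
  out
}

#' Score a query signature against every instance of a rank database
#'
#' The KS connectivity screen: for each instance, the up and down tag lists
#' of `signature` are located in the instance's probe ranking, KS-scored
#' with [ks_tag_score()], combined by [combine_scores()], and normalized
#' across all instances with [normalize_connectivity()]. Results are sorted
#' ascending by connectivity so the strongest *reversers* (most negative
#' scores: query-up probes at the bottom, query-down probes at the top)
#' come first; ties break by instance id.
#'
#' Signature probes absent from the database are dropped with a logged
#' count; if either tag set empties, that is an error.
#'
#' @param signature A probe-space [signature_set()] with non-empty sets.
#' @param db A [rank_db()].
#' @return A tibble of class `ks_result`: `rank`, `instance_id`,
#'   `perturbagen`, `dose`, `cell`, `connectivity`, `up_score`,
#'   `down_score`, `raw_s`.
#' @export
run_ks_query <- function(signature, db) {
  stopifnot(inherits(signature, "signature_set"), inherits(db, "rank_db"))
  if (length(signature$up) == 0 || length(signature$down) == 0) {
    abort("query signature needs non-empty up and down sets.")
  }
  probes <- rownames(db$ranks)
  up <- intersect(signature$up, probes)
  down <- intersect(signature$down, probes)
  dropped <- (length(signature$up) - length(up)) +
    (length(signature$down) - length(down))
  if (dropped > 0) {
    sig_log("ks", "dropped %d query probe(s) absent from the database", dropped)
  }
  if (length(up) == 0 || length(down) == 0) {
    abort("query signature has no probes in common with the database.")
  }
  n <- nrow(db$ranks)
  iu <- match(up, probes)
  id <- match(down, probes)
  up_score <- apply(db$ranks[iu, , drop = FALSE], 2, ks_tag_score, n = n)
  down_score <- apply(db$ranks[id, , drop = FALSE], 2, ks_tag_score, n = n)
  raw_s <- combine_scores(up_score, down_score)
  out <- db$meta |>
    mutate(up_score = unname(up_score),
           down_score = unname(down_score),
           raw_s = unname(raw_s),
           connectivity = normalize_connectivity(.data$raw_s)) |>
    arrange(.data$connectivity, .data$instance_id) |>
    mutate(rank = row_number()) |>
    select("rank", "instance_id", "perturbagen", "dose", "cell",
           "connectivity", "up_score", "down_score", "raw_s")
  class(out) <- c("ks_result", class(out))
  out
}

#' @export
glance.ks_result <- function(x, ...) {
  tibble(n_instances = nrow(x),
         n_negative = sum(x$connectivity < 0),
         n_zero = sum(x$connectivity == 0),
         min_connectivity = min(x$connectivity),
         max_connectivity = max(x$connectivity))
}

#' @export
tidy.ks_result <- function(x, ...) as_tibble(unclass(x))
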