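#' Ternary drug-by-gene reversal matrix
#'
#' Flattens a [run_matching_query()] result into a drugs x genes matrix with
#' entries +1 (gene reversed by the drug), -1 (aggravated), 0 (untouched) —
#' the data behind the reversal heat map and the clustering.
#'
#' @param results A `matching_result` tibble (usually its top rows).
#' @param id_col Column used as row labels (default `"instance_id"`; use
#'   e.g. a pasted perturbagen-instance label for display).
#' @return Integer matrix of class `reversal_matrix` with drug row names and
#'   gene column names (genes sorted lexicographically).
#' @export
reversal_matrix <- function(results, id_col = "instance_id") {
  stopifnot(all(c("reversed", "aggravated") %in% names(results)))
  ids <- as.character(results[[id_col]])
  check_unique(ids, "drug row label")
  genes <- sort(unique(c(unlist(results$reversed), unlist(results$aggravated))))
  m <- matrix(0L, nrow = length(ids), ncol = length(genes),
              dimnames = list(ids, genes))
  for (i in seq_along(ids)) {
    m[i, match(results$reversed[[i]], genes)] <- 1L
    m[i, match(results$aggravated[[i]], genes)] <- -1L
  }
  structure(m, class = c("reversal_matrix", class(m)))
}

# Jaccard distance between the +1 (reversed) gene sets of each drug pair;
# a drug with an empty reversed set is at distance 1 from everything.
jaccard_reversed_dist <- function(mat) {
  bin <- (unclass(mat) == 1L) * 1L
  inter <- tcrossprod(bin)
  sizes <- diag(inter)
  union <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / union
  d[union == 0] <- 1
  diag(d) <- 0
  as.dist(d)
}

#' Cluster drugs by the similarity of their reversed gene sets
#'
#' Agglomerative hierarchical clustering of candidate reversers: pairwise
#' Jaccard distance between reversed-gene sets (the +1 entries of the
#' reversal matrix) and average linkage. Drugs with identical reversed sets
#' are at distance 0 and merge first; a drug that reverses nothing is at
#' distance 1 from everything (logged). Rows are pre-sorted by drug id so
#' the outcome is invariant to input row order up to that tie-break.
#'
#' @param mat A [reversal_matrix()] with at least two rows, or a
#'   `matching_result` (converted internally).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return List of class `drug_clustering`: `order` (drug labels in leaf
#'   order), `merge`, `height` (the agglomeration trace) and `hclust` (the
#'   underlying object, usable with `cutree()` / `plot()`).
#' @export
cluster_drugs <- function(mat, linkage = "average") {
  if (inherits(mat, "matching_result")) mat <- reversal_matrix(mat)
  stopifnot(inherits(mat, "reversal_matrix"))
  if (nrow(mat) < 2) abort("need at least 2 drugs to cluster.")
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  n_empty <- sum(rowSums(unclass(mat) == 1L) == 0)
  if (n_empty > 0) {
    sig_log("cluster", "%d drug(s) reverse no genes (distance 1 to all)",
            n_empty)
  }
  hc <- hclust(jaccard_reversed_dist(mat), method = linkage)
  structure(list(order = rownames(mat)[hc$order], merge = hc$merge,
                 height = hc$height, hclust = hc),
            class = "drug_clustering")
}

#' @export
print.drug_clustering <- function(x, ...) {
  cat("<drug_clustering> ", length(x$order), " drugs; leaf order: ",
      paste(head(x$order, 8), collapse = ", "),
      if (length(x$order) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}
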