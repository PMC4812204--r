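#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The classical exact test used for categorical clinical contrasts and as
#' the building block of gene-set over-representation: conditional on the
#' margins, the two-sided p-value sums the probabilities of all
#' hypergeometric tables no more likely than the observed one (a small
#' relative tolerance absorbs floating-point noise, as in
#' [stats::fisher.test()]). A table that is entirely zero is degenerate and
#' returns p = 1 by convention.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `[[a, b], [c, d]]`.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(3, 3, 3, 9)  # 0.344
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers.")
  }
  if (all(cells == 0)) return(1)
  fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
}

#' Gene-set over-representation of a query gene list
#'
#' For each set in the collection, intersect its members with `universe`
#' (sets that vanish are skipped), build the 2x2 table of query/set
#' membership, and report the one-sided over-representation p-value
#' (hypergeometric upper tail) alongside the two-sided Fisher p, with
#' Benjamini-Hochberg adjustment of the one-sided values across sets.
#'
#' @param genes Character vector of query genes; must be a subset of
#'   `universe`.
#' @param collection Gene-set tibble as from [read_gmt()].
#' @param universe Character vector: the background gene universe
#'   (typically all genes represented on the platform).
#' @return Tibble of class `enrichment_result` with columns `set_name`,
#'   `k` (query genes in set), `K` (universe genes in set), `n` (query
#'   size), `N` (universe size), `p_over`, `p_two_sided`, `fdr`, sorted by
#'   `p_over`.
#' @export
enrich <- function(genes, collection, universe) {
  genes <- unique(as.character(genes))
  universe <- unique(as.character(universe))
  bad <- setdiff(genes, universe)
  if (length(bad) > 0) {
    abort(paste0("query genes outside the universe: ",
                 paste(head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) ", ..." else ""))
  }
  n <- length(genes)
  N <- length(universe)
  rows <- purrr::map2(collection$set_name, collection$genes, function(nm, members) {
    members <- intersect(members, universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(genes, members))
    tibble(set_name = nm, k = k, K = K, n = n, N = N,
           p_over = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
           p_two_sided = fisher_exact_2x2(k, n - k, K - k, N - K - n + k))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) abort("no gene set overlaps the universe.")
  out <- out |>
    mutate(fdr = p.adjust(.data$p_over, method = "BH")) |>
    arrange(.data$p_over, .data$set_name)
  class(out) <- c("enrichment_result", class(out))
  out
}
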