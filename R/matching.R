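#' Condense probe ranks to gene ranks by median
#'
#' Where several probes interrogate one gene, the gene's rank statistic is
#' the median of its probes' ranks (even counts: mean of the two central
#' values). Genes are then densely re-ranked 1..G by ascending median, ties
#' broken by gene symbol (lexicographic) so the ordering is deterministic.
#' Unmapped probes are dropped with a logged count.
#'
#' @param ranks Named integer vector: probe id -> rank within one instance
#'   (e.g. a column of a [rank_db()]).
#' @param map Probe-to-gene tibble as from [read_probe_map()].
#' @return Tibble of class `gene_rank_list` with columns `gene_symbol`,
#'   `median_rank`, `rank` (dense 1..G), sorted by `rank`.
#' @examples
#' r <- c(p1 = 5L, p2 = 15L, p3 = 10L)
#' m <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
#'                     gene_symbol = c("A", "A", "B"))
#' condense_probes_to_genes(r, m)  # A: median 10, B: 10; tie broken A first
#' @export
condense_probes_to_genes <- function(ranks, map) {
  probe_ids <- names(ranks)
  if (is.null(probe_ids)) abort("`ranks` must be named by probe id.")
  idx <- match(probe_ids, map$probe_id)
  mapped <- !is.na(idx)
  n_drop <- sum(!mapped)
  if (n_drop > 0) {
    sig_log("condense", "dropped %d unmapped probe(s)", n_drop)
  }
  if (!any(mapped)) abort("no probes could be mapped to gene symbols.")
  med <- tapply(as.numeric(ranks[mapped]), map$gene_symbol[idx[mapped]], median)
  out <- tibble(gene_symbol = names(med), median_rank = unname(med)) |>
    arrange(.data$median_rank, .data$gene_symbol) |>
    mutate(rank = row_number())
  class(out) <- c("gene_rank_list", class(out))
  out
}

#' Extract a drug signature from a condensed gene ranking
#'
#' The drug's own up/down gene sets: the first `k` genes of the dense order
#' (most up-regulated by the treatment) and the last `k` (most
#' down-regulated).
#'
#' @param gene_ranks A `gene_rank_list` from [condense_probes_to_genes()].
#' @param k Genes per tail (default 500); requires at least `2k` genes.
#' @return A gene-space [signature_set()].
#' @export
drug_signature <- function(gene_ranks, k = 500) {
  g <- nrow(gene_ranks)
  if (g < 2 * k) {
    abort(paste0("need >= 2k genes: have G = ", g, ", k = ", k, "."))
  }
  ord <- gene_ranks$gene_symbol[order(gene_ranks$rank)]
  signature_set(up = ord[seq_len(k)], down = ord[g - k + seq_len(k)],
                space = "gene")
}

#' Set-overlap reversing score of a drug against a disease signature
#'
#' Counts how the drug's expression response opposes the disease state:
#' *reversed* genes are disease-up genes the drug pushes down plus
#' disease-down genes the drug pushes up; *aggravated* genes move with the
#' disease. The score is
#' `|up n down_di| + |down n up_di| - |up n up_di| - |down n down_di|`,
#' i.e. `|reversed| - |aggravated|`; disease genes absent from both drug
#' sets contribute nothing.
#'
#' @param disease Gene-space [signature_set()], both sets non-empty.
#' @param drug Gene-space [signature_set()] (the drug's up/down sets).
#' @return List of class `reversal_result`: `reversed`, `aggravated`
#'   (character vectors) and `score` (integer).
#' @examples
#' dis <- signature_set(c("A", "B"), c("C"), space = "gene")
#' drg <- signature_set(c("C"), c("A", "B"), space = "gene")
#' reversing_score(dis, drg)$score  # 3: perfect reversal
#' @export
reversing_score <- function(disease, drug) {
  stopifnot(inherits(disease, "signature_set"), inherits(drug, "signature_set"))
  if (length(disease$up) == 0 || length(disease$down) == 0) {
    abort("disease signature needs non-empty up and down sets.")
  }
  reversed <- c(intersect(disease$up, drug$down),
                intersect(disease$down, drug$up))
  aggravated <- c(intersect(disease$up, drug$up),
                  intersect(disease$down, drug$down))
  structure(list(reversed = reversed, aggravated = aggravated,
                 score = length(reversed) - length(aggravated)),
            class = "reversal_result")
}

#' @export
print.reversal_result <- function(x, ...) {
  cat("<reversal_result> score ", x$score, " (", length(x$reversed),
      " reversed / ", length(x$aggravated), " aggravated)\n", sep = "")
  invisible(x)
}

#' Reversing-score screen of a rank database
#'
#' For every instance: condense probe ranks to gene ranks
#' ([condense_probes_to_genes()]), take the top/bottom-`k` drug signature
#' ([drug_signature()]), and score it against the disease signature with
#' [reversing_score()]. Results are sorted by score descending (ties: more
#' reversed genes first, then instance id), so the most promising
#' disease-reversing perturbations lead the table.
#'
#' @param disease Gene-space [signature_set()] (typically the full DEG set
#'   at FDR/fold-change thresholds, not the fixed-size KS query).
#' @param db A [rank_db()].
#' @param map Probe-to-gene tibble as from [read_probe_map()].
#' @param k Drug-signature tail size (default 500).
#' @return Tibble of class `matching_result`: `rank`, `instance_id`,
#'   `perturbagen`, `score`, `n_reversed`, `n_aggravated`, plus
#'   list-columns `reversed` and `aggravated` with the gene sets.
#' @export
run_matching_query <- function(disease, db, map, k = 500) {
  stopifnot(inherits(disease, "signature_set"), inherits(db, "rank_db"))
  if (disease$space != "gene") {
    abort("`disease` must be a gene-space signature for the matching screen.")
  }
  n_unmapped <- sum(!rownames(db$ranks) %in% map$probe_id)
  if (n_unmapped > 0) {
    sig_log("match", "%d database probe(s) have no gene symbol and are dropped",
            n_unmapped)
  }
  res <- purrr::map(seq_len(ncol(db$ranks)), function(j) {
    gr <- withr::with_options(list(sigreverse.quiet = TRUE),
                              condense_probes_to_genes(db$ranks[, j], map))
    rv <- reversing_score(disease, drug_signature(gr, k))
    tibble(instance_id = colnames(db$ranks)[j], score = rv$score,
           n_reversed = length(rv$reversed),
           n_aggravated = length(rv$aggravated),
           reversed = list(rv$reversed), aggravated = list(rv$aggravated))
  })
  out <- bind_rows(res) |>
    left_join(db$meta, by = "instance_id") |>
    arrange(desc(.data$score), desc(.data$n_reversed), .data$instance_id) |>
    mutate(rank = row_number()) |>
    select("rank", "instance_id", "perturbagen", "score",
           "n_reversed", "n_aggravated", "reversed", "aggravated")
  class(out) <- c("matching_result", class(out))
  out
}

#' @export
glance.matching_result <- function(x, ...) {
  tibble(n_instances = nrow(x),
         max_score = max(x$score), min_score = min(x$score),
         mean_score = mean(x$score))
}

#' @export
tidy.matching_result <- function(x, ...) {
  as_tibble(unclass(x))[, c("rank", "instance_id", "perturbagen", "score",
                            "n_reversed", "n_aggravated")]
}
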