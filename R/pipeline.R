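#' Translate a probe-space signature to gene-symbol space
#'
#' Maps each probe through the lookup table and deduplicates. A gene whose
#' probes land in both the up and the down set is direction-ambiguous and is
#' dropped from both (with a logged count); unmapped probes are dropped.
#'
#' @param signature Probe-space [signature_set()].
#' @param map Probe-to-gene tibble as from [read_probe_map()].
#' @return Gene-space [signature_set()].
#' @export
signature_to_genes <- function(signature, map) {
  stopifnot(inherits(signature, "signature_set"))
  if (signature$space != "probe") abort("signature is not in probe space.")
  up <- unique(map$gene_symbol[map$probe_id %in% signature$up])
  down <- unique(map$gene_symbol[map$probe_id %in% signature$down])
  both <- intersect(up, down)
  if (length(both) > 0) {
    sig_log("map", "%d gene(s) with conflicting probe directions dropped",
            length(both))
  }
  signature_set(setdiff(up, both), setdiff(down, both), space = "gene")
}

#' Assemble a pipeline configuration
#'
#' Collects every input and tuning parameter of [run_pipeline()] in one
#' list. Inputs may be file paths (read with the package's readers) or
#' already-loaded objects; a YAML file with the same keys can be loaded by
#' passing its path to `run_pipeline()` directly.
#'
#' @param expression,groups Expression TSV + groups TSV paths, or pass an
#'   [expression_set()] as `expression`.
#' @param rank_meta,rank_ranks Rank-database metadata/ranks TSV paths, or
#'   pass a [rank_db()] as `rank_meta`.
#' @param probe_map Lookup TSV path or tibble.
#' @param gmt Optional GMT path or collection tibble for enrichment.
#' @param group_a,group_b Contrast groups (defaults "early", "late";
#'   `b - a`).
#' @param fdr_max,fc_min DEG thresholds (defaults 0.05 and 1.5).
#' @param n_top KS query size (default 1000).
#' @param k Drug-signature tail size (default 500).
#' @param consensus_m Top-list depth for the consensus (default 20).
#' @param seed Integer recorded in the run manifest (the pipeline itself is
#'   deterministic; the seed documents any upstream simulation).
#' @param out_dir Optional directory; when set, every result table plus a
#'   run manifest is written there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, groups = NULL, rank_meta,
                            rank_ranks = NULL, probe_map, gmt = NULL,
                            group_a = "early", group_b = "late",
                            fdr_max = 0.05, fc_min = 1.5, n_top = 1000,
                            k = 500, consensus_m = 20, seed = NULL,
                            out_dir = NULL) {
  if (fdr_max <= 0 || fc_min <= 1 || n_top < 2 || k < 1 || consensus_m < 1) {
    abort("thresholds must be positive (and fc_min > 1, n_top >= 2).")
  }
  structure(list(expression = expression, groups = groups,
                 rank_meta = rank_meta, rank_ranks = rank_ranks,
                 probe_map = probe_map, gmt = gmt,
                 group_a = group_a, group_b = group_b,
                 fdr_max = fdr_max, fc_min = fc_min, n_top = n_top, k = k,
                 consensus_m = consensus_m, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full signature-reversal screen
#'
#' End-to-end orchestration: differential expression between the contrast
#' groups, DEG signature selection, the fixed-size KS query, both scoring
#' screens against the rank database, the top-list consensus, clustering of
#' the top reversers by reversed genes, and (when a gene-set collection is
#' supplied) over-representation analysis of the consensus reversed genes.
#'
#' The consensus combines the two algorithms: perturbagen *names* appearing
#' in the top `consensus_m` of both the KS ranking (most negative
#' connectivity first) and the matching ranking (highest reversing score
#' first). Names rather than instance ids are intersected because the same
#' compound typically scores through different instances in the two
#' screens. An empty consensus is a warning, not an error.
#'
#' Every stage logs one line (suppress with
#' `options(sigreverse.quiet = TRUE)`); any stage failure aborts with the
#' stage name. Reruns with identical config and inputs are byte-identical.
#'
#' @param config A [pipeline_config()], a list with its fields, or the path
#'   to a YAML file of those fields.
#' @return List of class `pipeline_result`: `deg_table`, `disease_probe_sig`,
#'   `disease_gene_sig`, `ks_query_sig`, `ks`, `matching`, `consensus`
#'   (tibble: `perturbagen`, `ks_rank`, `matching_rank`), `clustering`,
#'   `enrichment` (or `NULL`), `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  cfg <- config

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  expr <- stage("load-expression", {
    if (inherits(cfg$expression, "expression_set")) cfg$expression
    else read_expression(cfg$expression, cfg$groups)
  })
  db <- stage("load-rankdb", {
    if (inherits(cfg$rank_meta, "rank_db")) cfg$rank_meta
    else read_rank_database(cfg$rank_meta, cfg$rank_ranks)
  })
  map <- stage("load-map", {
    if (is.data.frame(cfg$probe_map)) cfg$probe_map
    else read_probe_map(cfg$probe_map)
  })
  sig_log("input", "%d features x %d samples; %d probes x %d instances",
          nrow(expr$values), ncol(expr$values), nrow(db$ranks), ncol(db$ranks))

  deg <- stage("differential-expression",
               moderated_t_table(expr, cfg$group_a, cfg$group_b))
  disease_probe_sig <- stage("select-degs",
                             select_degs(deg, cfg$fdr_max, cfg$fc_min))
  sig_log("degs", "%d up / %d down at FDR<%g & FC>%g",
          length(disease_probe_sig$up), length(disease_probe_sig$down),
          cfg$fdr_max, cfg$fc_min)
  ks_query <- stage("ks-query-signature",
                    top_changing_probes(deg, cfg$n_top))
  ks <- stage("ks-screen", run_ks_query(ks_query, db))
  disease_gene_sig <- stage("map-to-genes",
                            signature_to_genes(disease_probe_sig, map))
  matching <- stage("matching-screen",
                    run_matching_query(disease_gene_sig, db, map, cfg$k))

  m <- cfg$consensus_m
  ks_top <- head(ks, m)
  match_top <- head(matching, m)
  consensus <- stage("consensus", {
    shared <- intersect(ks_top$perturbagen, match_top$perturbagen)
    tibble(perturbagen = shared,
           ks_rank = ks_top$rank[match(shared, ks_top$perturbagen)],
           matching_rank = match_top$rank[match(shared, match_top$perturbagen)]) |>
      arrange(.data$ks_rank)
  })
  if (nrow(consensus) == 0) {
    warn("consensus is empty: the two top lists share no perturbagen.")
  }
  sig_log("consensus", "%d perturbagen(s) in both top-%d lists",
          nrow(consensus), m)

  clustering <- if (nrow(match_top) >= 2) {
    stage("clustering", cluster_drugs(reversal_matrix(match_top)))
  }

  enrichment <- NULL
  if (!is.null(cfg$gmt)) {
    enrichment <- stage("enrichment", {
      collection <- if (is.data.frame(cfg$gmt)) cfg$gmt else read_gmt(cfg$gmt)
      hits <- matching$perturbagen %in% consensus$perturbagen &
        matching$rank <= m
      query <- unique(unlist(matching$reversed[hits]))
      universe <- unique(map$gene_symbol)
      if (length(query) == 0) NULL else enrich(query, collection, universe)
    })
  }

  out <- structure(
    list(deg_table = deg, disease_probe_sig = disease_probe_sig,
         disease_gene_sig = disease_gene_sig, ks_query_sig = ks_query,
         ks = ks, matching = matching, consensus = consensus,
         clustering = clustering, enrichment = enrichment, config = cfg),
    class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_result(out, cfg$out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  DEGs: ", length(x$disease_probe_sig$up), " up / ",
      length(x$disease_probe_sig$down), " down\n", sep = "")
  cat("  instances scored: ", nrow(x$ks), "\n", sep = "")
  cat("  consensus: ",
      if (nrow(x$consensus)) paste(x$consensus$perturbagen, collapse = ", ")
      else "(empty)", "\n", sep = "")
  invisible(x)
}

# Write all result tables plus a manifest. List-columns are exploded into a
# long drug/direction/gene table so everything on disk is plain TSV.
write_pipeline_result <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(tidy(x$deg_table), p("deg_table.tsv"))
  readr::write_tsv(tidy(x$ks), p("ks_scores.tsv"))
  readr::write_tsv(tidy(x$matching), p("matching_scores.tsv"))
  detail <- x$matching |>
    select("instance_id", "reversed", "aggravated") |>
    tidyr::pivot_longer(c("reversed", "aggravated"), names_to = "direction",
                        values_to = "gene") |>
    tidyr::unnest("gene")
  readr::write_tsv(detail, p("reversed_genes.tsv"))
  readr::write_tsv(x$consensus, p("consensus.tsv"))
  if (!is.null(x$clustering)) {
    readr::write_tsv(tibble(leaf = seq_along(x$clustering$order),
                            drug = x$clustering$order),
                     p("cluster_order.tsv"))
  }
  if (!is.null(x$enrichment)) {
    readr::write_tsv(as_tibble(unclass(x$enrichment)), p("enrichment.tsv"))
  }
  cfg <- x$config
  manifest <- list(
    package = "sigreverse",
    version = as.character(utils::packageVersion("sigreverse")),
    seed = cfg$seed,
    contrast = list(a = cfg$group_a, b = cfg$group_b),
    thresholds = list(fdr_max = cfg$fdr_max, fc_min = cfg$fc_min,
                      n_top = cfg$n_top, k = cfg$k,
                      consensus_m = cfg$consensus_m),
    inputs = lapply(cfg[c("expression", "groups", "rank_meta", "rank_ranks",
                          "probe_map", "gmt")],
                    function(v) if (is.character(v)) v else class(v)[1])
  )
  yaml::write_yaml(manifest, p("manifest.yml"))
  invisible(x)
}
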