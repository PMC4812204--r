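#' Simulate a grouped expression matrix with planted differential expression
#'
#' Emulates an RMA-style log2 expression study with a control group and two
#' disease-stage groups ("early", "late"). Per-feature baselines are drawn
#' from Normal(8, 1.5) on the log2 scale; planted features are shifted by
#' `+effect_log2` (up set) or `-effect_log2` (down set) in the *late* group
#' relative to *early* (controls sit at baseline, like early); iid Gaussian
#' noise with standard deviation `sd` is added everywhere. The generator is
#' deterministic for a fixed `seed` and never touches the global RNG state.
#'
#' @param n_genes Number of features.
#' @param group_sizes Named integer vector of samples per group; default
#'   `c(control = 6, early = 6, late = 12)`.
#' @param n_up,n_down Number of planted up- / down-regulated features
#'   (ignored when `planted_up` / `planted_down` are given).
#' @param effect_log2 Log2 shift planted in the late group (>= 0).
#' @param sd Noise standard deviation on the log2 scale (> 0).
#' @param seed Integer seed; required.
#' @param feature_ids Optional feature id vector (length `n_genes`);
#'   defaults to `g00001, g00002, ...`.
#' @param planted_up,planted_down Optional explicit planted feature ids
#'   (must be subsets of `feature_ids`, disjoint).
#' @return List with elements `expr` (an [expression_set()]) and `truth`
#'   (list: `planted_up`, `planted_down`, `effect_log2`, `group_sizes`).
#' @examples
#' sim <- simulate_expression(200, n_up = 10, n_down = 5,
#'                            effect_log2 = 2, sd = 0.5, seed = 1)
#' sim$expr
#' @export
simulate_expression <- function(n_genes,
                                group_sizes = c(control = 6, early = 6, late = 12),
                                n_up = 0, n_down = 0,
                                effect_log2 = 1, sd = 0.5, seed,
                                feature_ids = NULL,
                                planted_up = NULL, planted_down = NULL) {
  if (missing(seed)) abort("`seed` is required: randomness is always explicit.")
  if (n_genes < 1 || any(group_sizes < 1)) {
    abort("n_genes and every group size must be positive.")
  }
  if (sd <= 0) abort("`sd` must be > 0.")
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    abort("`group_sizes` must be a named vector of group labels.")
  }
  if (is.null(feature_ids)) {
    feature_ids <- sprintf("g%05d", seq_len(n_genes))
  }
  if (length(feature_ids) != n_genes) {
    abort("`feature_ids` must have length `n_genes`.")
  }
  check_unique(feature_ids, "feature id")

  withr::with_seed(seed, {
    if (is.null(planted_up) && n_up > 0) {
      planted_up <- feature_ids[seq_len(n_up)]
    }
    if (is.null(planted_down) && n_down > 0) {
      planted_down <- feature_ids[n_up + seq_len(n_down)]
    }
    planted_up <- as.character(planted_up %||% character(0))
    planted_down <- as.character(planted_down %||% character(0))
    if (length(intersect(planted_up, planted_down)) > 0) {
      abort("planted up and down sets must be disjoint.")
    }
    if (!all(c(planted_up, planted_down) %in% feature_ids)) {
      abort("planted features must be among `feature_ids`.")
    }
    if (length(planted_up) + length(planted_down) > n_genes) {
      abort("more planted features than genes.")
    }

    groups <- rep(names(group_sizes), times = group_sizes)
    sample_ids <- paste0(groups, "_", unlist(lapply(group_sizes, seq_len)))
    baseline <- stats::rnorm(n_genes, mean = 8, sd = 1.5)
    shift <- numeric(n_genes)
    shift[match(planted_up, feature_ids)] <- effect_log2
    shift[match(planted_down, feature_ids)] <- -effect_log2
    m <- matrix(baseline, nrow = n_genes, ncol = length(sample_ids))
    late <- groups == "late"
    m[, late] <- m[, late] + shift
    m <- m + matrix(stats::rnorm(length(m), sd = sd), nrow = n_genes)
    dimnames(m) <- list(feature_ids, sample_ids)

    expr <- expression_set(m, tibble(sample_id = sample_ids, group = groups))
    list(expr = expr,
         truth = list(planted_up = planted_up, planted_down = planted_down,
                      effect_log2 = effect_log2, group_sizes = group_sizes))
  })
}

#' Simulate a rank database with planted signature reversers
#'
#' Builds a CMAP-style rank database over a synthetic gene/probe universe:
#' genes `g00001..` each carry 1-3 probes (`<gene>_p1`, ...), assigned
#' cyclically so the probe universe has size `n_probes`. Decoy instances are
#' uniform random permutations. Reverser instances *reverse* the supplied
#' disease signature: every probe of a disease-up gene is placed uniformly at
#' random within the bottom `ceiling(strength * n_probes)` ranks, every probe
#' of a disease-down gene within the top `ceiling(strength * n_probes)` ranks,
#' and all remaining probes are shuffled over the remaining ranks. Smaller
#' `strength` therefore pins the planted probes tighter to the extremes;
#' `strength = (tag count)/n_probes` yields perfect reversal.
#'
#' @param n_probes Probe universe size.
#' @param n_instances Total instances (reversers + decoys).
#' @param probe_multiplicity Integer vector of probes-per-gene patterns,
#'   recycled over genes (default `c(1, 2, 3)`, i.e. mean 2 probes/gene).
#' @param disease_signature A gene-space [signature_set()] naming genes of
#'   this generator's universe (`g00001`, ...).
#' @param n_reversers Number of planted reverser instances (first
#'   `n_reversers` instance ids; each gets its own perturbagen name
#'   `reverser_drug_<i>`; decoys are named `decoy_drug_<j>`).
#' @param strength Window fraction in (0, 1]; see Description.
#' @param seed Integer seed; required.
#' @return List with `db` (a [rank_db()]), `map` (probe-to-gene tibble as
#'   from [read_probe_map()]), and `truth` (list: `reverser_instance_ids`,
#'   `decoy_instance_ids`, `strength`).
#' @export
simulate_rank_database <- function(n_probes, n_instances,
                                   probe_multiplicity = c(1, 2, 3),
                                   disease_signature,
                                   n_reversers = 0, strength = 0.2, seed) {
  if (missing(seed)) abort("`seed` is required: randomness is always explicit.")
  if (strength <= 0 || strength > 1) abort("`strength` must be in (0, 1].")
  if (n_reversers > n_instances) abort("more reversers than instances.")
  stopifnot(inherits(disease_signature, "signature_set"))
  if (disease_signature$space != "gene") {
    abort("`disease_signature` must be in gene space.")
  }

  # deterministic gene/probe universe: multiplicity pattern recycled until
  # exactly n_probes probes exist
  mult <- integer(0)
  while (sum(mult) < n_probes) {
    mult <- c(mult, probe_multiplicity)
  }
  mult <- mult[cumsum(mult) <= n_probes]
  if (sum(mult) < n_probes) mult <- c(mult, n_probes - sum(mult))
  genes <- sprintf("g%05d", seq_along(mult))
  map <- tibble(
    probe_id = unlist(purrr::map2(genes, mult,
                                  function(g, k) paste0(g, "_p", seq_len(k)))),
    gene_symbol = rep(genes, times = mult)
  )

  bad <- setdiff(c(disease_signature$up, disease_signature$down), genes)
  if (length(bad) > 0) {
    abort(paste0("signature genes absent from the simulated universe: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  up_probes <- map$probe_id[map$gene_symbol %in% disease_signature$up]
  down_probes <- map$probe_id[map$gene_symbol %in% disease_signature$down]
  w <- ceiling(strength * n_probes)
  if (length(up_probes) > w || length(down_probes) > w) {
    abort(paste0("signature probes (", length(up_probes), " up / ",
                 length(down_probes), " down) exceed the ", w,
                 "-rank placement window; increase `strength`."))
  }

  withr::with_seed(seed, {
    ranks <- matrix(0L, nrow = n_probes, ncol = n_instances,
                    dimnames = list(map$probe_id,
                                    sprintf("inst_%04d", seq_len(n_instances))))
    rev_ids <- colnames(ranks)[seq_len(n_reversers)]
    for (j in seq_len(n_instances)) {
      if (j <= n_reversers) {
        r <- integer(n_probes)
        top_slots <- sample.int(w, length(down_probes))
        bottom_pool <- setdiff(n_probes - w + seq_len(w), top_slots)
        if (length(bottom_pool) < length(up_probes)) {
          abort("placement windows overlap too much for this signature; increase `strength` or `n_probes`.")
        }
        bottom_slots <- bottom_pool[sample.int(length(bottom_pool),
                                               length(up_probes))]
        r[match(down_probes, map$probe_id)] <- top_slots
        r[match(up_probes, map$probe_id)] <- bottom_slots
        rest <- setdiff(seq_len(n_probes), c(top_slots, bottom_slots))
        r[r == 0L] <- rest[sample.int(length(rest))]
        ranks[, j] <- r
      } else {
        ranks[, j] <- sample.int(n_probes)
      }
    }
    meta <- tibble(
      instance_id = colnames(ranks),
      perturbagen = c(sprintf("reverser_drug_%02d", seq_len(n_reversers)),
                      sprintf("decoy_drug_%03d",
                              seq_len(n_instances - n_reversers))),
      dose = "10 uM",
      cell = "SYN1"
    )
    list(db = rank_db(ranks, meta), map = map,
         truth = list(reverser_instance_ids = rev_ids,
                      decoy_instance_ids = setdiff(colnames(ranks), rev_ids),
                      strength = strength))
  })
}
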