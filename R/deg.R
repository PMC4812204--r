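#' Moderated-t differential expression between two groups
#'
#' Fits the standard linear-model / empirical-Bayes moderated t-test
#' (via limma's `lmFit()`/`eBayes()`) contrasting `group_b` minus `group_a`,
#' so a positive `log2fc` means higher expression in `group_b`. Per-feature
#' variances are shrunk toward a common prior estimated by moment matching
#' on the observed variance distribution, p-values come from the t
#' distribution with prior-augmented degrees of freedom, and
#' Benjamini-Hochberg adjusted values are appended.
#'
#' With `shrink = FALSE` the ordinary pooled-variance two-sample t-test is
#' computed from the same fit (no prior), which is useful as a reference:
#' as the prior weight vanishes the moderated statistic reduces to it.
#'
#' @param expr An [expression_set()].
#' @param group_a,group_b Group labels; the contrast is `b - a`. Each group
#'   needs at least two samples.
#' @param shrink Use empirical-Bayes variance shrinkage (default `TRUE`).
#' @return A tibble of class `deg_table` with columns `feature_id`,
#'   `log2fc`, `t_stat`, `p_raw`, `fdr`, ordered as the input features.
#'   Attributes `contrast`, `df_prior` and `s2_prior` record the fit.
#' @examples
#' sim <- simulate_expression(100, n_up = 5, effect_log2 = 2, sd = 0.5, seed = 1)
#' tab <- moderated_t_table(sim$expr, "early", "late")
#' head(tab)
#' @export
moderated_t_table <- function(expr, group_a, group_b, shrink = TRUE) {
  stopifnot(inherits(expr, "expression_set"))
  sa <- samples_in_group(expr, group_a)
  sb <- samples_in_group(expr, group_b)
  if (length(sa) < 2 || length(sb) < 2) {
    abort("both groups need at least 2 samples.")
  }
  m <- expr$values[, c(sa, sb), drop = FALSE]
  grp <- factor(rep(c("a", "b"), c(length(sa), length(sb))), levels = c("a", "b"))
  design <- stats::model.matrix(~grp)
  fit <- limma::lmFit(m, design)
  if (shrink) {
    if (all(fit$sigma == 0)) {
      abort("all features have zero residual variance; nothing to shrink toward.")
    }
    eb <- limma::eBayes(fit)
    t_stat <- eb$t[, 2]
    p_raw <- eb$p.value[, 2]
    df_prior <- eb$df.prior
    s2_prior <- eb$s2.prior
  } else {
    se <- fit$stdev.unscaled[, 2] * fit$sigma
    t_stat <- ifelse(se == 0, ifelse(fit$coefficients[, 2] == 0, 0,
                                     sign(fit$coefficients[, 2]) * Inf),
                     fit$coefficients[, 2] / se)
    p_raw <- 2 * pt(-abs(t_stat), df = fit$df.residual)
    df_prior <- 0
    s2_prior <- NA_real_
  }
  out <- tibble(
    feature_id = rownames(m),
    log2fc = unname(fit$coefficients[, 2]),
    t_stat = unname(t_stat),
    p_raw = unname(p_raw),
    fdr = p.adjust(unname(p_raw), method = "BH")
  )
  structure(out,
            class = c("deg_table", class(out)),
            contrast = c(a = group_a, b = group_b),
            n_samples = c(a = length(sa), b = length(sb)),
            df_prior = unname(df_prior), s2_prior = unname(s2_prior))
}

#' @export
glance.deg_table <- function(x, fdr_max = 0.05, fc_min = 1.5, ...) {
  sig <- select_degs(x, fdr_max, fc_min)
  ctr <- attr(x, "contrast")
  tibble(
    n_features = nrow(x),
    n_up = length(sig$up),
    n_down = length(sig$down),
    fdr_max = fdr_max, fc_min = fc_min,
    contrast = paste(ctr["b"], "vs", ctr["a"]),
    df_prior = attr(x, "df_prior"),
    s2_prior = attr(x, "s2_prior")
  )
}

#' @export
tidy.deg_table <- function(x, ...) {
  as_tibble(unclass(x)[c("feature_id", "log2fc", "t_stat", "p_raw", "fdr")])
}

#' Threshold a DE table into an up/down signature
#'
#' Disease signature selection: features with `fdr < fdr_max` and fold
#' change strictly above `fc_min` (i.e. `|log2fc| > log2(fc_min)`), split by
#' the sign of `log2fc`. An empty signature is allowed here; queries that
#' require non-empty sets raise their own errors.
#'
#' @param table A `deg_table` (or any data frame with `feature_id`,
#'   `log2fc`, `fdr`).
#' @param fdr_max FDR cutoff (default 0.05, strict `<`).
#' @param fc_min Fold-change cutoff on the natural scale (default 1.5,
#'   strict `>`; must exceed 1).
#' @param space Feature space recorded on the signature (default "probe").
#' @return A [signature_set()].
#' @export
select_degs <- function(table, fdr_max = 0.05, fc_min = 1.5,
                        space = c("probe", "gene")) {
  space <- match.arg(space)
  if (fc_min <= 1) abort("`fc_min` must be > 1.")
  lfc <- log2(fc_min)
  keep <- table$fdr < fdr_max & abs(table$log2fc) > lfc
  keep[is.na(keep)] <- FALSE
  signature_set(up = table$feature_id[keep & table$log2fc > 0],
                down = table$feature_id[keep & table$log2fc < 0],
                space = space)
}

#' Largest-changing-feature query signature
#'
#' Takes the `n_total` features with the largest absolute moderated t
#' statistic and assigns each to the up or down set by the sign of its
#' log2 fold change — the construction of a fixed-size rank-database query
#' from a DE table. Ties in `|t_stat|` at the cutoff are broken by feature
#' id (lexicographic) so the selection is deterministic.
#'
#' @param table A `deg_table`.
#' @param n_total Total query size (default 1000); the table must contain
#'   at least this many features.
#' @param space Feature space recorded on the signature (default "probe").
#' @return A [signature_set()] with `length(up) + length(down) == n_total`.
#' @export
top_changing_probes <- function(table, n_total = 1000,
                                space = c("probe", "gene")) {
  space <- match.arg(space)
  if (nrow(table) < n_total) {
    abort(paste0("table has ", nrow(table), " features; need >= ", n_total, "."))
  }
  ord <- order(-abs(table$t_stat), table$feature_id)
  top <- table[ord[seq_len(n_total)], ]
  signature_set(up = top$feature_id[top$log2fc >= 0],
                down = top$feature_id[top$log2fc < 0],
                space = space)
}

#' Relative expression by the 2^-ddCt method
#'
#' Converts normalized qRT-PCR cycle-threshold differences into a relative
#' expression level: `2^-(dct_target - dct_reference)`. Vectorized.
#'
#' @param dct_target Delta-Ct of the target condition (Ct target gene minus
#'   Ct housekeeping gene).
#' @param dct_reference Delta-Ct of the reference condition.
#' @return Fold change of target relative to reference.
#' @examples
#' ddct_fold_change(5, 5)  # 1
#' ddct_fold_change(4, 5)  # 2
#' @export
ddct_fold_change <- function(dct_target, dct_reference) {
  stopifnot(is.numeric(dct_target), is.numeric(dct_reference))
  2^-(dct_target - dct_reference)
}
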