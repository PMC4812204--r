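# Independent oracles and small fixture builders shared across test files.
# Oracles implement definitions directly (enumeration / CDF evaluation) and
# never call the implementation they check.

options(sigreverse.quiet = TRUE)

# KS tag score oracle: signed supremum deviation between the tag empirical
# CDF and the uniform CDF, evaluated over all n positions, with the
# negative-side deviation taken as the left limit at jumps.
oracle_ks <- function(positions, n) {
  v <- sort(positions)
  t <- length(v)
  cdf <- function(i) sum(v <= i) / t
  a <- max(vapply(0:n, function(i) cdf(i) - i / n, numeric(1)))
  b <- max(vapply(1:n, function(i) i / n - cdf(i - 1), numeric(1)))
  if (a > b) a else -b
}

# Benjamini-Hochberg by its step-up definition: adj p_(i) is the minimum
# over j >= i of m * p_(j) / j, capped at 1, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Two-sided Fisher p by exhaustive enumeration of all tables with the
# observed margins: sum the hypergeometric probabilities of tables whose
# probability does not exceed the observed one (with a small tolerance).
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  if (n == 0) return(1)
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) dhyper(x, c1, n - c1, r1), numeric(1))
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Reversing-score oracle: classify every disease gene by direct membership
# tests, one gene at a time.
oracle_reversing <- function(disease, drug) {
  rev_ct <- 0L
  agg_ct <- 0L
  for (g in disease$up) {
    if (g %in% drug$down) rev_ct <- rev_ct + 1L
    if (g %in% drug$up) agg_ct <- agg_ct + 1L
  }
  for (g in disease$down) {
    if (g %in% drug$up) rev_ct <- rev_ct + 1L
    if (g %in% drug$down) agg_ct <- agg_ct + 1L
  }
  rev_ct - agg_ct
}

# Tiny rank database: explicit rank columns given as a named list of
# integer vectors over the supplied probe ids.
tiny_db <- function(probe_ids, columns, perturbagen = names(columns)) {
  m <- do.call(cbind, columns)
  rownames(m) <- probe_ids
  rank_db(m, tibble::tibble(instance_id = names(columns),
                            perturbagen = perturbagen,
                            dose = "1 uM", cell = "T1"))
}

# DE table built directly from columns (for threshold/selection tests).
tiny_deg_table <- function(feature_id, log2fc, t_stat = log2fc,
                           p_raw = rep(0.01, length(feature_id))) {
  structure(tibble::tibble(feature_id = feature_id, log2fc = log2fc,
                           t_stat = t_stat, p_raw = p_raw,
                           fdr = p.adjust(p_raw, "BH")),
            class = c("deg_table", class(tibble::tibble())))
}
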