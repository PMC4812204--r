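---
title: "Signature reversal screening: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature reversal screening: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigreverse)
options(sigreverse.quiet = TRUE)
```

## The screening model

`sigreverse` operationalizes one idea: a compound whose transcriptional
response *opposes* a disease signature is a repurposing candidate. The
disease side is summarized as two disjoint feature sets (up- and
down-regulated); the drug side is a database of instances, each a complete
permutation ranking of the platform's probes by treatment-induced
expression change, rank 1 being the most up-regulated probe. Two scores
quantify opposition, and the pipeline trusts only their agreement.

### Differential expression and signature construction

Disease signatures come from a moderated-t contrast between two sample
groups (e.g. late-stage minus early-stage disease), computed with the
standard linear-model / empirical-Bayes machinery: per-feature variances
are shrunk toward a moment-matched prior and the t statistic uses
prior-augmented degrees of freedom. This is the field's default for small
microarray cohorts (here typically 6 vs 12 samples), where per-gene
variance estimates are noisy and unshrunk t-tests overreward
low-variance noise. `moderated_t_table(..., shrink = FALSE)` exposes the
ordinary pooled t, which the test suite uses to confirm the zero-prior
limit.

Two different signatures feed the two screens, deliberately:

* the **KS query** takes the `n_top = 1000` features with largest
  |moderated t|, split by fold-change sign. "Largest changing" is
  ambiguous between effect size and statistic; we rank by |t| — the
  default ordering of the limma-style analysis that produces the table —
  and break cutoff ties lexicographically by feature id so the query is
  deterministic.
* the **matching screen** uses the full DEG set at `fdr_max = 0.05`
  (strict) and fold change strictly above `fc_min = 1.5`, thresholded on
  the log2 scale against `log2(1.5)`, then translated to gene symbols.
  Genes whose probes disagree in direction are dropped from both sets
  rather than arbitrated.

### The KS connectivity score

For tag positions `V(1) < ... < V(t)` in a ranking of `n`:
`a = max_j [j/t − V(j)/n]`, `b = max_j [V(j)/n − (j−1)/t]`; the score is
`a` if `a > b`, else `−b`. `a` and `b` are the suprema of the signed gap
between the tag empirical CDF and the uniform CDF (the negative side taken
as a left limit at jumps); the unit tests check this equivalence
exhaustively for every tag subset at `n ≤ 8`. Two discretization facts are
worth knowing: with every item tagged the score is `−1/n`, not 0; and
under list reversal the score flips only up to a `1/n` offset
(`a(rev) = b − 1/n`, `b(rev) = a + 1/n`), with near-ties scoring negative
in both orientations because ties resolve to `−b`. The score's sign
convention is tied to the pinned rank convention — rank 1 = most
up-regulated by treatment — which the readers enforce on every load.

Raw combination: `s = up − down` when the two tag scores disagree in
sign, else 0; a single zero score counts as disagreement so one-sided
signals still score. Normalization divides positive `s` by the largest
positive and negative `s` by |most negative|, guaranteeing that each
side's extreme instance scores exactly ±1 and making the output invariant
to positive rescaling. Reproducing all 20 rows of a published screen's
top-20 table at ±0.005 (the precision of its 3-decimal inputs) is the
evidence for this exact formula/normalization pairing.

### The set-overlap reversing score

Probe ranks are condensed per gene to the median probe rank (even counts:
mean of the central pair), then genes are densely re-ranked with
lexicographic tie-breaks; medians of different genes tie often, and
determinism requires a pinned rule. The drug signature is the top/bottom
`k = 500` genes of this order — the rank matrix carries no per-instance
inferential statistics, so rank extremes are the only available
definition of a drug's "DEGs". The reversing score is
`|reversed| − |aggravated|` with
`reversed = (up ∩ down_di) ∪ (down ∩ up_di)` and
`aggravated = (up ∩ up_di) ∪ (down ∩ down_di)`; it is antisymmetric under
swapping the disease sets and bounded by the disease signature size, both
of which are property-tested against a per-gene membership oracle.

### Consensus, clustering, enrichment

The two screens disagree on many instances (the KS score rewards extreme
*positions*, the matching score set *membership*), so the pipeline's
deliverable is their consensus: perturbagen names in the top `m` of both
rankings. Names, not instance ids, are intersected — the same compound
typically scores through different instances in the two screens. `m`
defaults to 20, the conventional depth of published top tables; the
synthetic benchmark below uses `m` = the number of planted reversers,
since with correlated decoy scores the deeper lists would share decoys by
chance and set equality would be uninformative.

Top candidates are clustered by the Jaccard distance between their
reversed gene sets (average linkage). The distance and linkage are the
natural choice for sparse binary set data; both are arguments. A drug
reversing nothing is defined to be at distance 1 from everything
(`stats::dist(method = "binary")` would return NaN there, so the small
distance matrix is computed directly). Enrichment of reversed genes uses
the hypergeometric upper tail (the over-representation convention),
reported alongside the two-sided Fisher p that matches printed clinical
contrasts, with BH adjustment of the one-sided values across sets within
one query; the default universe is all genes on the platform, the natural
background for array-derived DEGs.

## The synthetic-data generator

No patient microarrays or real rank database are required for validation:
the generator plants known truth at the study's own scale.

* **Expression**: per-feature baselines ~ Normal(8, 1.5) on the log2
  scale, planted features shifted by ±`effect_log2` in the "late" group,
  iid Gaussian noise (`sd`). Defaults mirror a three-group design with 6
  control / 6 early / 12 late samples. This emulates RMA-style log2 data
  well enough to exercise the inference; it deliberately omits batch
  effects, probe saturation, correlated genes and heavy-tailed noise, so
  passing recovery tests demonstrates algorithmic correctness, not
  robustness to real-array artifacts.
* **Rank database**: genes carry 1–3 probes (pattern recycled, so median
  condensation is exercised nontrivially), decoys are uniform random
  permutations, and a reverser places every probe of a disease-up gene
  uniformly within the bottom `ceiling(strength × n)` ranks and
  disease-down probes within the top window. Smaller `strength` pins
  probes tighter to the extremes; `strength = tags/n` yields perfect
  reversal, which the construction tests use.

Both generators take explicit seeds, restore the caller's RNG state, and
are bitwise deterministic per seed.

### Benchmark scales and what the tests show

The standing benchmark uses 2000 genes (100 up / 50 down planted at
|log2fc| = 2, sd 0.5, 6 vs 12 samples) for DE recovery — chosen as a
clearly detectable but not trivial effect (per-gene t ≈ 8) — and a rank
database of 5000 probes / ~3500 genes / 200 instances with 5 planted
reversers at `strength = 0.2`. At these settings DEG selection recovers
≥ 90% of planted genes with ≤ 5% wrong-direction calls, both screens place
all five reversers in their top 5, and the pipeline consensus equals the
planted perturbagen set; the whole suite runs in about a minute. Scaling
n_probes to the full 22k platform only stress-tests I/O (covered by a
round-trip test) — the scores themselves are scale-free.

## Numerical and degenerate-input conventions

* BH adjustment via `stats::p.adjust`; property-tested against the raw
  step-up definition.
* Zero residual variance: shrinkage keeps the moderated t finite; a fully
  degenerate matrix (all variances zero) is an error. In the unshrunk
  variant a zero-variance, zero-effect feature scores t = 0, p = 1.
* Two-sided Fisher p sums hypergeometric masses ≤ the observed table's
  (relative tolerance ~1e-7); an all-zero table returns p = 1.
* Empty structures: an empty DEG signature is legal (selection is a
  filter), but every query construction that needs tags errors on empty
  sets; empty GRP files are load errors.
* All result orderings carry deterministic tie-breaks (instance id, gene
  symbol, feature id).

## Known limitations

Single two-group contrast only (no covariates, pairing, or multi-factor
designs); no permutation p-values for connectivity scores; no
dose–response aggregation across instances of one perturbagen; gene-set
enrichment treats sets as flat (no GO graph or pathway topology); the
synthetic generator's independence assumptions understate the correlation
structure of real expression data.
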